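# Two-component univariate normal mixture fitted by expectation-maximisation
# over per-gene size-normalised edit distances. The lower-mean component is
# taken as the intact-gene distribution; the classification cutoff is three
# standard deviations above its mean.

#' Fit a two-component normal mixture to snLED values
#'
#' Expectation-maximisation for a mixture of two univariate normals, started
#' from means (0, 1), standard deviations (1, 1) and equal weights, so the
#' low component captures intact genes and the high component pseudogenes.
#' After convergence the components are relabelled so
#' `mean_intact <= mean_pseudo` and the cutoff is
#' `mean_intact + 3 * sd_intact`.
#'
#' @param x numeric vector of snLED values (>= 20 finite values with nonzero
#'   variance required).
#' @param tol convergence tolerance on the change in log-likelihood.
#' @param max_iter maximum number of E-M iterations.
#' @param init_means,init_sds,init_weights starting parameters.
#' @return an `erodeome_mixture`: list with `mean_intact`, `sd_intact`,
#'   `weight_intact`, `mean_pseudo`, `sd_pseudo`, `weight_pseudo`, `loglik`,
#'   `n_iter`, `converged`, `collapsed`, `cutoff`.
#' @details Degenerate input (all values identical) is an error of class
#'   `erodeome_degenerate_error`; callers such as [annotate_lineage()] fall
#'   back to a fixed cutoff in that case. If a component collapses during
#'   iteration (standard deviation underflowing toward zero), the fit stops
#'   and is returned with `collapsed = TRUE`.
#' @export
fit_mixture <- function(x, tol = 1e-8, max_iter = 1000L,
                        init_means = c(0, 1), init_sds = c(1, 1),
                        init_weights = c(0.5, 0.5)) {
  x <- x[is.finite(x)]
  if (length(x) < 20L) {
    stop("fit_mixture needs at least 20 finite values, got ", length(x))
  }
  if (sd(x) == 0) {
    stop(structure(
      list(message = paste0("degenerate input: all snLED values identical (",
                            format(x[1]), "); use a fixed cutoff instead"),
           call = sys.call(-1)),
      class = c("erodeome_degenerate_error", "error", "condition")))
  }
  mu <- init_means
  sigma <- init_sds
  w <- init_weights / sum(init_weights)
  ll_old <- -Inf
  converged <- FALSE
  collapsed <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    l1 <- log(w[1]) + dnorm(x, mu[1], sigma[1], log = TRUE)
    l2 <- log(w[2]) + dnorm(x, mu[2], sigma[2], log = TRUE)
    m <- pmax(l1, l2)
    den <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(den)
    r1 <- exp(l1 - den)
    r2 <- 1 - r1

    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 < 1e-10 || n2 < 1e-10) { collapsed <- TRUE; break }
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sigma <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2))
    w <- c(n1, n2) / length(x)
    if (any(sigma < 1e-8)) { collapsed <- TRUE; break }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }

  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]
  structure(list(mean_intact = mu[1], sd_intact = sigma[1], weight_intact = w[1],
                 mean_pseudo = mu[2], sd_pseudo = sigma[2], weight_pseudo = w[2],
                 loglik = if (exists("ll")) ll else NA_real_, n_iter = iter,
                 converged = converged, collapsed = collapsed,
                 cutoff = mu[1] + 3 * sigma[1]),
            class = "erodeome_mixture")
}

#' @export
print.erodeome_mixture <- function(x, ...) {
  cat(sprintf(paste0("<erodeome_mixture> intact: N(%.4f, %.4f) w=%.2f | ",
                     "pseudo: N(%.4f, %.4f) w=%.2f\n  cutoff=%.4f, loglik=%.2f, ",
                     "%d iter, converged=%s%s\n"),
              x$mean_intact, x$sd_intact, x$weight_intact,
              x$mean_pseudo, x$sd_pseudo, x$weight_pseudo,
              x$cutoff, x$loglik, x$n_iter, x$converged,
              if (x$collapsed) ", COLLAPSED" else ""))
  invisible(x)
}
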