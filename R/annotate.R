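# Reference-guided gene-status annotation: for each (gene, lineage) pair,
# enumerate candidate ORFs around the reference start, score them by
# Levenshtein edit distance to the reference CDS, size-normalise, fit the
# intact/pseudogene mixture per lineage, and classify each gene as intact,
# pseudogene, or missing.

DEFAULT_START_CODONS <- c("ATG", "GTG", "TTG")

#' Annotation configuration
#'
#' @param flank number of bases around the reference start/stop within which
#'   candidate starts are accepted (and included in the extracted region).
#' @param start_codons accepted (canonical plus alternative bacterial) start
#'   codons.
#' @param missing_threshold genes whose consensus covers less than this
#'   fraction of the reference CDS (non-gap, non-N) are called `missing`.
#' @param em_tol,em_max_iter E-M convergence controls for [fit_mixture()].
#' @param fallback_cutoff fixed snLED cutoff used when the mixture cannot be
#'   fitted (degenerate input or collapsed component), e.g. when annotating
#'   the reference against itself.
#' @param pooled if `TRUE`, [annotate_set()] fits one mixture over all
#'   lineages instead of one per lineage.
#' @return a named list of class `erodeome_annotate_config`.
#' @export
annotate_config <- function(flank = 25L, start_codons = DEFAULT_START_CODONS,
                            missing_threshold = 0.25, em_tol = 1e-8,
                            em_max_iter = 1000L, fallback_cutoff = 0.02,
                            pooled = FALSE) {
  structure(list(flank = as.integer(flank), start_codons = start_codons,
                 missing_threshold = missing_threshold, em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter),
                 fallback_cutoff = fallback_cutoff, pooled = pooled),
            class = "erodeome_annotate_config")
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (substitution, insertion, deletion)
#' between nucleotide strings.
#'
#' @param a character vector of strings.
#' @param b a single string each element of `a` is compared against.
#' @return integer vector of distances.
#' @export
led <- function(a, b) {
  stopifnot(length(b) == 1L)
  as.integer(adist(a, b))
}

#' Extract the consensus region of a gene, with flanks, gaps collapsed
#'
#' Slices the lineage consensus over `[start - flank, end + flank)` (clipped
#' at the replicon bounds), reverse-complements for `-` strand genes so the
#' region reads 5'->3', and removes `-` characters (deletions collapse; `N`
#' is retained). The returned string carries a `left_flank` attribute: the
#' number of flanking positions actually present 5' of the reference start
#' (before gap collapse), needed to anchor the start-codon search window.
#'
#' @param lineage an `erodeome_lineage`.
#' @param gene a single-row slice of the reference gene table.
#' @param flank flank width in nt.
#' @return character scalar with attribute `left_flank`.
#' @export
extract_gene_region <- function(lineage, gene, flank = 25L) {
  cons <- lineage$consensus[[gene$replicon_id]]
  if (is.null(cons)) stop("replicon not in lineage consensus: ", gene$replicon_id)
  rep_len <- nchar(cons)
  lo <- max(0L, gene$start - flank)
  hi <- min(rep_len, gene$end + flank)
  region <- substr(cons, lo + 1L, hi)
  if (gene$strand == "-") {
    region <- revcomp(region)
    left_flank <- hi - gene$end        # 5' flank in reading direction
  } else {
    left_flank <- gene$start - lo
  }
  region <- gsub("-", "", region, fixed = TRUE)
  structure(region, left_flank = as.integer(left_flank))
}

#' Enumerate candidate ORFs for a gene region
#'
#' Finds every occurrence of a start codon beginning within `flank` nt of
#' the (nominal) reference start position and extends it codon-wise to the
#' first in-frame stop within the region, or to the region end if none
#' occurs. The stop codon is excluded from the candidate sequence;
#' candidates shorter than two codons are discarded.
#'
#' @param region gap-collapsed gene region from [extract_gene_region()].
#' @param ref_gene single-row reference gene (unused by the scan itself;
#'   retained for interface symmetry and future frame-aware scans).
#' @param flank start-window half-width in nt.
#' @param start_codons accepted start codons.
#' @return data.frame with columns `start_offset` (nt relative to the
#'   reference CDS start), `start_codon`, `seq`; zero rows if no candidate.
#' @export
enumerate_orf_candidates <- function(region, ref_gene = NULL, flank = 25L,
                                     start_codons = DEFAULT_START_CODONS) {
  left_flank <- attr(region, "left_flank")
  if (is.null(left_flank)) left_flank <- flank
  region <- as.character(region)
  n <- nchar(region)
  empty <- data.frame(start_offset = integer(), start_codon = character(),
                      seq = character(), stringsAsFactors = FALSE)
  if (n < 6L) return(empty)

  window_end <- min(n - 2L, left_flank + flank + 1L)  # last allowed start (1-based)
  if (window_end < 1L) return(empty)
  head_seq <- substr(region, 1L, window_end + 2L)
  starts <- integer(0)
  for (sc in start_codons) {
    hits <- gregexpr(sc, head_seq, fixed = TRUE)[[1]]
    if (hits[1] != -1L) starts <- c(starts, hits[hits <= window_end])
  }
  starts <- sort(unique(starts))
  if (!length(starts)) return(empty)

  out <- lapply(starts, function(s) {
    tail_len <- n - s + 1L
    ncod <- tail_len %/% 3L
    if (ncod < 2L) return(NULL)
    codon_start <- s + 3L * (seq_len(ncod) - 1L)
    codons <- substring(region, codon_start, codon_start + 2L)
    stop_at <- which(codons %in% STOP_CODONS)
    seq_end <- if (length(stop_at)) codon_start[stop_at[1]] - 1L else s + 3L * ncod - 1L
    if (seq_end - s + 1L < 6L) return(NULL)
    data.frame(start_offset = s - 1L - left_flank,
               start_codon = substr(region, s, s + 2L),
               seq = substr(region, s, seq_end), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Pick the best-scoring candidate ORF
#'
#' Lowest LED wins; ties break to the longer sequence, then the start offset
#' closest to the reference start, then the leftmost.
#'
#' @param candidates data.frame from [enumerate_orf_candidates()] with an
#'   `led` column already filled in.
#' @return the winning row, or `NULL` if `candidates` is empty.
#' @export
best_candidate <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  ord <- order(candidates$led, -nchar(candidates$seq),
               abs(candidates$start_offset), candidates$start_offset)
  candidates[ord[1L], , drop = FALSE]
}

#' Size-normalised LED
#'
#' Divides an LED by the length of the reference CDS (stop codon excluded,
#' matching the stop-excluded LED comparison), making scores comparable
#' across lineages for the same gene; a fully deleted gene scores exactly 1.
#'
#' @param led_value integer LED.
#' @param ref_gene single-row reference gene.
#' @return numeric snLED.
#' @export
snled <- function(led_value, ref_gene) {
  led_value / (nchar(ref_gene$cds_seq) - 3L)
}

ref_core <- function(gene) substr(gene$cds_seq, 1L, nchar(gene$cds_seq) - 3L)

# coverage: fraction of reference CDS positions with A/C/G/T consensus
gene_coverage <- function(lineage, gene) {
  s <- substr(lineage$consensus[[gene$replicon_id]], gene$start + 1L, gene$end)
  nchar(gsub("[^ACGT]", "", s)) / (gene$end - gene$start)
}

# raw (unclassified) scores for every reference gene in one lineage
score_lineage <- function(lineage, reference, config = annotate_config()) {
  genes <- reference$genes
  n <- nrow(genes)
  out <- data.frame(lineage_id = rep(lineage$lineage_id, n),
                    gene_id = genes$gene_id, status = NA_character_,
                    snled = NA_real_, coverage = NA_real_,
                    led = NA_integer_, start_offset = NA_integer_,
                    candidate_length = NA_integer_, n_candidates = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    gene <- genes[i, ]
    out$coverage[i] <- gene_coverage(lineage, gene)
    region <- extract_gene_region(lineage, gene, config$flank)
    cand <- enumerate_orf_candidates(region, gene, config$flank, config$start_codons)
    rc <- ref_core(gene)
    if (nrow(cand)) {
      cand$led <- led(cand$seq, rc)
      best <- best_candidate(cand)
      out$led[i] <- best$led
      out$start_offset[i] <- best$start_offset
      out$candidate_length[i] <- nchar(best$seq)
      out$n_candidates[i] <- nrow(cand)
    } else {
      # no valid start in the window: score the bare gap-collapsed gene
      # region so the gene enters the mixture as a high-snLED point
      bare <- gsub("-", "", substr(lineage$consensus[[gene$replicon_id]],
                                   gene$start + 1L, gene$end), fixed = TRUE)
      if (gene$strand == "-") bare <- revcomp(bare)
      out$led[i] <- led(bare, rc)
    }
    out$snled[i] <- snled(out$led[i], gene)
  }
  out
}

#' Classify scored genes given a cutoff
#'
#' Coverage below `missing_threshold` means `missing`; otherwise
#' `snled <= cutoff` (inclusive) means `intact`, else `pseudogene`.
#'
#' @param calls data.frame with `snled` and `coverage` columns.
#' @param fit an `erodeome_mixture`, or a bare numeric cutoff.
#' @param missing_threshold coverage threshold for `missing`.
#' @return `calls` with `status` filled in.
#' @export
classify <- function(calls, fit, missing_threshold = 0.25) {
  cutoff <- if (inherits(fit, "erodeome_mixture")) fit$cutoff else as.numeric(fit)
  calls$status <- ifelse(calls$coverage < missing_threshold, "missing",
                         ifelse(calls$snled <= cutoff, "intact", "pseudogene"))
  calls
}

#' Annotate one lineage against the reference
#'
#' Runs the full per-lineage pipeline: region extraction, candidate ORF
#' enumeration, LED scoring, size normalisation, per-lineage mixture fit
#' (genes below the coverage threshold are excluded from the fit), and
#' classification against the three-standard-deviation cutoff. If the
#' mixture cannot be fitted -- degenerate snLEDs (e.g. annotating the
#' reference against itself) or a collapsed component -- the configured
#' fixed fallback cutoff is used and a message is emitted.
#'
#' @param lineage an `erodeome_lineage`.
#' @param reference an `erodeome_reference`.
#' @param config an [annotate_config()].
#' @return list with `calls` (one row per reference gene: `lineage_id`,
#'   `gene_id`, `status`, `snled`, `coverage` plus diagnostic columns),
#'   `fit` (`erodeome_mixture` or `NULL`), `cutoff` (the cutoff actually
#'   used) and `fallback` (logical).
#' @export
annotate_lineage <- function(lineage, reference, config = annotate_config()) {
  calls <- score_lineage(lineage, reference, config)
  fit_on <- calls$snled[calls$coverage >= config$missing_threshold]
  fit <- NULL
  fallback <- FALSE
  cutoff <- config$fallback_cutoff
  if (length(fit_on) >= 20L && sd(fit_on) > 0) {
    fit <- tryCatch(fit_mixture(fit_on, tol = config$em_tol,
                                max_iter = config$em_max_iter),
                    erodeome_degenerate_error = function(e) NULL)
    if (!is.null(fit) && !fit$collapsed) {
      cutoff <- fit$cutoff
    } else {
      fit <- NULL
      fallback <- TRUE
    }
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    message(sprintf("lineage %s: mixture not fitted, using fixed cutoff %.4f",
                    lineage$lineage_id, cutoff))
  }
  calls <- classify(calls, cutoff, config$missing_threshold)
  list(calls = calls, fit = fit, cutoff = cutoff, fallback = fallback)
}

#' Annotate a set of lineages
#'
#' Applies [annotate_lineage()] to every lineage. With `config$pooled =
#' TRUE` a single mixture is fitted over the pooled snLEDs of all lineages
#' instead of one per lineage.
#'
#' @param lineages named list of `erodeome_lineage`.
#' @param reference an `erodeome_reference`.
#' @param config an [annotate_config()].
#' @return list with `calls` (row-bound calls for all lineages) and `fits`
#'   (named list of per-lineage results: `fit`, `cutoff`, `fallback`).
#' @export
annotate_set <- function(lineages, reference, config = annotate_config()) {
  if (isTRUE(config$pooled)) {
    scored <- lapply(lineages, score_lineage, reference = reference, config = config)
    all_scores <- do.call(rbind, scored)
    fit_on <- all_scores$snled[all_scores$coverage >= config$missing_threshold]
    fit <- tryCatch(fit_mixture(fit_on, tol = config$em_tol,
                                max_iter = config$em_max_iter),
                    erodeome_degenerate_error = function(e) NULL)
    cutoff <- if (is.null(fit) || fit$collapsed) config$fallback_cutoff else fit$cutoff
    calls <- classify(all_scores, cutoff, config$missing_threshold)
    rownames(calls) <- NULL
    return(list(calls = calls,
                fits = list(pooled = list(fit = fit, cutoff = cutoff,
                                          fallback = is.null(fit) || fit$collapsed))))
  }
  res <- lapply(lineages, annotate_lineage, reference = reference, config = config)
  calls <- do.call(rbind, lapply(res, `[[`, "calls"))
  rownames(calls) <- NULL
  fits <- lapply(res, function(r) r[c("fit", "cutoff", "fallback")])
  names(fits) <- names(lineages)
  list(calls = calls, fits = fits)
}
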