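# Contingency analysis of retention strings: Shannon entropy filtering,
# exhaustive pairwise Hamming distances, the relationship-strength score,
# direct/reciprocal classification, and radius-bounded clustering of
# retention patterns (co-retained and reciprocally retained genes).

#' Shannon entropy of a binary retention string
#'
#' Base-2 entropy of the Bernoulli frequency of the string: with
#' `p = mean(bits)`, `E = -p log2 p - (1-p) log2 (1-p)`, and 0 when `p` is
#' 0 or 1. Full precision is kept internally; round only when reporting.
#'
#' @param bits 0/1 vector (logicals accepted).
#' @return entropy in bits, in `[0, 1]`.
#' @export
shannon_entropy <- function(bits) {
  stopifnot(length(bits) > 0, all(bits %in% c(0, 1)))
  p <- mean(bits)
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Entropy of a length-n string with k minority states
#'
#' Generalises the "at least k of n lineages differ" filter to any lineage
#' count: the entropy threshold for k minority states is the entropy of a
#' length-`n` string with exactly `k` ones. At `n = 34`, `k = 3` this is
#' 0.43 (2 dp), the default filter.
#'
#' @param n string length (number of included lineages).
#' @param k number of minority states.
#' @return entropy in bits.
#' @export
min_minority_entropy <- function(n, k) {
  stopifnot(n >= 1, k >= 0, k <= n)
  if (k == 0 || k == n) return(0)
  p <- k / n
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Hamming distance between two equal-length binary strings
#'
#' @param a,b 0/1 vectors of equal length.
#' @return integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  sum(a != b)
}

#' Relationship strength of a gene pair
#'
#' `strength = 0.5 * E + (0.5 / (n/2)) * |H - n/2|`, where `E` is the pair
#' entropy (the smaller of the two string entropies, so a near-constant
#' partner cannot inflate the score) and `H` the Hamming distance between
#' the strings. The score lies in `[0, 1]`: maximal for high-entropy pairs
#' that are identical (`H = 0`) or perfectly reciprocal (`H = n`), and
#' minimal-distance-term at the uninformative midpoint `H = n/2`.
#'
#' @param entropy_a,entropy_b string entropies of the two genes.
#' @param hamming Hamming distance between their strings.
#' @param n string length.
#' @return numeric strength in `[0, 1]`; vectorised over its arguments.
#' @export
relationship_strength <- function(entropy_a, entropy_b, hamming, n) {
  0.5 * pmin(entropy_a, entropy_b) + (0.5 / (n / 2)) * abs(hamming - n / 2)
}

#' All pairwise retention relationships among fractional genes
#'
#' Restricts a retention matrix to its fractionally retained genes, drops
#' genes whose string entropy falls below the filter threshold, and
#' computes the exhaustive pairwise table of Hamming distances, strengths,
#' and direct/reciprocal labels. By default a pair is `direct` when
#' `H < n/2` (co-retention), `reciprocal` when `H > n/2`, and `none` at the
#' uninformative midpoint `H = n/2`; pairs at the midpoint carry
#' `rendered = FALSE` (they are retained in the table but dropped from
#' rendering). Optional strict thresholds narrow the labels to
#' near-identical / near-complementary pairs only.
#'
#' @param x an `erodeome_retention`, or a 0/1 matrix (genes x lineages).
#' @param entropy_min `"auto"` (default) derives the threshold as
#'   [min_minority_entropy()] of `k_min` of `n`; or a numeric threshold.
#' @param k_min minority-lineage count behind the `"auto"` threshold.
#' @param direct_max if set, `direct` requires `H <= direct_max`.
#' @param reciprocal_min if set, `reciprocal` requires `H >= reciprocal_min`.
#' @return data.frame with `gene_a`, `gene_b`, `hamming`, `strength`,
#'   `relation`, `rendered`; attribute `entropy` carries the per-gene
#'   entropies of the genes passing the filter, and attribute `n` the
#'   lineage count.
#' @export
all_relations <- function(x, entropy_min = "auto", k_min = 3L,
                          direct_max = NULL, reciprocal_min = NULL) {
  B <- relation_input(x)
  n <- ncol(B)
  ent <- apply(B, 1L, shannon_entropy)
  thr <- if (identical(entropy_min, "auto")) {
    min_minority_entropy(n, k_min)
  } else as.numeric(entropy_min)
  B <- B[ent >= thr - 1e-12, , drop = FALSE]
  ent <- ent[ent >= thr - 1e-12]

  empty <- data.frame(gene_a = character(), gene_b = character(),
                      hamming = integer(), strength = numeric(),
                      relation = character(), rendered = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(B) < 2L) {
    return(structure(empty, entropy = ent, n = n))
  }

  r <- rowSums(B)
  H <- outer(r, r, "+") - 2 * tcrossprod(B)   # pairwise Hamming, binary identity
  idx <- which(upper.tri(H), arr.ind = TRUE)
  h <- H[idx]
  ea <- ent[idx[, 1]]
  eb <- ent[idx[, 2]]
  rel <- ifelse(h < n / 2, "direct", ifelse(h > n / 2, "reciprocal", "none"))
  if (!is.null(direct_max)) {
    rel[rel == "direct" & h > direct_max] <- "none"
  }
  if (!is.null(reciprocal_min)) {
    rel[rel == "reciprocal" & h < reciprocal_min] <- "none"
  }
  out <- data.frame(gene_a = rownames(B)[idx[, 1]],
                    gene_b = rownames(B)[idx[, 2]],
                    hamming = as.integer(h),
                    strength = relationship_strength(ea, eb, h, n),
                    relation = rel, rendered = h != n / 2,
                    stringsAsFactors = FALSE)
  structure(out[order(out$gene_a, out$gene_b), , drop = FALSE],
            entropy = ent, n = n)
}

relation_input <- function(x) {
  if (inherits(x, "erodeome_retention")) {
    x$binary[x$category == "fractional", , drop = FALSE]
  } else {
    B <- as.matrix(x)
    stopifnot(all(B %in% c(0, 1)))
    if (is.null(rownames(B))) rownames(B) <- sprintf("g%04d", seq_len(nrow(B)))
    B
  }
}

#' Export / read a relation edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `hamming`, `strength`, `relation`,
#' sorted ascending by strength (ties by gene ids) so that the strongest
#' relationships render last and on top.
#'
#' @param relations data.frame from [all_relations()].
#' @param path output/input path.
#' @param rendered_only if `TRUE` (default), drop pairs at the
#'   uninformative `H = n/2` midpoint, mirroring the rendering filter.
#' @return `export_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   the edge data.frame.
#' @export
export_edge_list <- function(relations, path, rendered_only = TRUE) {
  if (rendered_only && "rendered" %in% names(relations)) {
    relations <- relations[relations$rendered, , drop = FALSE]
  }
  ord <- order(relations$strength, relations$gene_a, relations$gene_b)
  cols <- c("gene_a", "gene_b", "hamming", "strength", "relation")
  write.table(relations[ord, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_edge_list
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(gene_a = "character", gene_b = "character",
                            hamming = "integer", strength = "numeric",
                            relation = "character"))
}

# orient rows toward a representative: complement a row when that halves
# its distance (ties keep the row as-is)
orient_rows <- function(B, rep_bits) {
  n <- ncol(B)
  d_as <- as.vector(B %*% (1 - 2 * rep_bits)) + sum(rep_bits)   # Hamming to rep
  comp <- d_as > n - d_as
  list(oriented = abs(B - ifelse(comp, 1L, 0L)),
       orientation = ifelse(comp, "complemented", "as-is"))
}

majority_bits <- function(B) {
  as.integer(colMeans(B) >= 0.5)   # ties resolve to 1 (retained)
}

#' Cluster retention patterns within a Hamming radius
#'
#' Recursive bisection in the spirit of pattern-compression algorithms for
#' binary matrices: each gene's string is first canonicalised to the
#' orientation (as-is or complemented) nearer the current majority-vote
#' representative, so co-retained and reciprocally retained genes land in
#' the same cluster with their orientation recorded; genes within
#' `max_radius` of the stabilised representative form a cluster and the
#' remainder is re-clustered. This is a simplified radius-bisection scheme,
#' not a line-for-line port of any published implementation.
#'
#' @param x an `erodeome_retention` (its fractional genes are clustered) or
#'   a 0/1 matrix.
#' @param max_radius maximum Hamming distance of any oriented member to its
#'   cluster representative.
#' @return list of clusters, each a list with `cluster_id`, `members`
#'   (data.frame `gene_id`, `orientation`, `dist`), `representative`
#'   (0/1 vector) and `radius`; empty input gives an empty list.
#' @export
cluster_patterns <- function(x, max_radius = 2L) {
  B <- relation_input(x)
  if (nrow(B) == 0L) return(list())
  clusters <- cluster_rec(B, max_radius)
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  clusters
}

cluster_rec <- function(B, max_radius) {
  if (nrow(B) == 0L) return(list())
  # canonical starting orientation: majority-ones (tie keeps as-is)
  start <- orient_rows(B, majority_bits(B))
  oriented <- start$oriented
  rep_bits <- majority_bits(oriented)
  for (it in seq_len(20L)) {
    o <- orient_rows(B, rep_bits)
    new_rep <- majority_bits(o$oriented)
    oriented <- o$oriented
    if (identical(new_rep, rep_bits)) break
    rep_bits <- new_rep
  }
  o <- orient_rows(B, rep_bits)
  d <- rowSums(abs(sweep(o$oriented, 2L, rep_bits)))
  inside <- d <= max_radius
  if (!any(inside)) {
    # no member near the majority representative: seed from the closest one
    rep_bits <- o$oriented[which.min(d), ]
    o <- orient_rows(B, rep_bits)
    d <- rowSums(abs(sweep(o$oriented, 2L, rep_bits)))
    inside <- d <= max_radius
  }
  cl <- list(cluster_id = NA_integer_,
             members = data.frame(gene_id = rownames(B)[inside],
                                  orientation = o$orientation[inside],
                                  dist = as.integer(d[inside]),
                                  stringsAsFactors = FALSE),
             representative = rep_bits,
             radius = as.integer(max(d[inside])))
  c(list(cl), cluster_rec(B[!inside, , drop = FALSE], max_radius))
}
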