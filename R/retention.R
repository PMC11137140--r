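# Genes-by-lineages retention matrix, per-gene categorisation, per-lineage
# genome-feature summaries, and pathway completeness with host
# complementation.

#' Build the genes x lineages retention matrix
#'
#' Assembles gene calls into a status matrix (`intact` / `pseudogene` /
#' `missing`) and the derived binary matrix (intact -> 1, else -> 0), after
#' dropping explicitly excluded lineages. Each gene is categorised as
#' `universal_intact` (intact in every included lineage), `universal_lost`
#' (intact in none), or `fractional`. Gene and lineage order is
#' canonicalised (sorted), so the result does not depend on input order.
#'
#' @param calls gene-call data.frame (`lineage_id`, `gene_id`, `status`).
#' @param exclude character vector of lineage ids to drop before
#'   categorisation (e.g. conspecific hosts or recent cospeciation events),
#'   or a data.frame with a `lineage_id` column.
#' @return an `erodeome_retention`: list with `gene_ids`, `lineage_ids`,
#'   `status` (character matrix), `binary` (0/1 integer matrix), `category`
#'   (named character vector) and `excluded`.
#' @export
build_matrix <- function(calls, exclude = character()) {
  if (is.data.frame(exclude)) exclude <- exclude$lineage_id
  lineage_ids <- sort(unique(calls$lineage_id))
  unknown <- setdiff(exclude, lineage_ids)
  if (length(unknown)) {
    stop("exclusion list names unknown lineage(s): ",
         paste(unknown, collapse = ", "))
  }
  keep <- setdiff(lineage_ids, exclude)
  calls <- calls[calls$lineage_id %in% keep, , drop = FALSE]
  gene_ids <- sort(unique(calls$gene_id))

  key <- paste(calls$gene_id, calls$lineage_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated (gene, lineage) pair(s): ",
         paste(head(gsub("\r", " / ", dup), 10L), collapse = ", "))
  }
  want <- as.vector(outer(gene_ids, keep, paste, sep = "\r"))
  miss <- setdiff(want, key)
  if (length(miss)) {
    stop("missing (gene, lineage) pair(s): ",
         paste(head(gsub("\r", " / ", miss), 10L), collapse = ", "))
  }
  bad <- !calls$status %in% STATUS_LEVELS
  if (any(bad)) {
    stop("invalid status value(s): ", paste(unique(calls$status[bad]), collapse = ", "))
  }

  status <- matrix(NA_character_, length(gene_ids), length(keep),
                   dimnames = list(gene_ids, keep))
  status[cbind(match(calls$gene_id, gene_ids),
               match(calls$lineage_id, keep))] <- calls$status
  binary <- (status == "intact") + 0L
  rs <- rowSums(binary)
  category <- ifelse(rs == length(keep), "universal_intact",
                     ifelse(rs == 0L, "universal_lost", "fractional"))
  names(category) <- gene_ids
  structure(list(gene_ids = gene_ids, lineage_ids = keep, status = status,
                 binary = binary, category = category, excluded = exclude),
            class = "erodeome_retention")
}

#' @export
print.erodeome_retention <- function(x, ...) {
  tab <- table(factor(x$category,
                      c("universal_intact", "fractional", "universal_lost")))
  cat(sprintf(paste0("<erodeome_retention> %d genes x %d lineages ",
                     "(universal intact %d, fractional %d, universal lost %d)\n"),
              length(x$gene_ids), length(x$lineage_ids),
              tab[["universal_intact"]], tab[["fractional"]],
              tab[["universal_lost"]]))
  invisible(x)
}

#' Write / read a retention matrix
#'
#' Status matrix as TSV with genes as rows and lineages as columns, cells in
#' `{I,P,M}`; a companion binary (0/1) matrix is written alongside with
#' suffix `.binary.tsv`.
#'
#' @param x an `erodeome_retention`.
#' @param path output/input path for the status matrix.
#' @return `write_retention_matrix()` returns `path` invisibly;
#'   `read_retention_matrix()` rebuilds the `erodeome_retention`.
#' @export
write_retention_matrix <- function(x, path) {
  abbr <- c(intact = "I", pseudogene = "P", missing = "M")
  m <- matrix(abbr[x$status], nrow = nrow(x$status), dimnames = dimnames(x$status))
  write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  bpath <- paste0(sub("\\.tsv$", "", path), ".binary.tsv")
  write.table(data.frame(gene_id = rownames(x$binary), x$binary,
                         check.names = FALSE),
              bpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_retention_matrix
#' @export
read_retention_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  full <- c(I = "intact", P = "pseudogene", M = "missing")
  bad <- !m %in% names(full)
  if (any(bad)) stop("invalid matrix cell value(s): ",
                     paste(unique(m[bad]), collapse = ", "))
  status <- matrix(full[m], nrow = nrow(m), dimnames = dimnames(m))
  calls <- data.frame(
    gene_id = rep(rownames(status), ncol(status)),
    lineage_id = rep(colnames(status), each = nrow(status)),
    status = as.vector(status), stringsAsFactors = FALSE)
  build_matrix(calls)
}

#' Per-lineage genome-feature summaries
#'
#' For each lineage: GC fraction over intact copies of a conserved ortholog
#' set, fraction of the reference recovered (non-gap, non-N consensus length
#' over reference length), intact/pseudogene/missing counts, and intact
#' counts per functional category. The recovered fraction is computed from
#' consensus coverage (an analogue of read-alignment recovery, which is out
#' of scope here).
#'
#' @param lineages named list of `erodeome_lineage`.
#' @param calls gene-call data.frame for those lineages.
#' @param reference an `erodeome_reference`.
#' @param conserved_set gene ids over which conserved-ortholog GC is
#'   computed; defaults to the universally intact set implied by `calls`.
#' @return data.frame, one row per lineage.
#' @export
genome_features <- function(lineages, calls, reference, conserved_set = NULL) {
  if (is.null(conserved_set)) {
    mat <- build_matrix(calls)
    conserved_set <- mat$gene_ids[mat$category == "universal_intact"]
  }
  genes <- reference$genes
  ref_len <- sum(nchar(reference$seqs))
  cats <- setdiff(unique(unlist(strsplit(genes$categories, ";"))), "")

  rows <- lapply(lineages, function(lin) {
    lc <- calls[calls$lineage_id == lin$lineage_id, , drop = FALSE]
    status <- setNames(lc$status, lc$gene_id)
    acgt <- sum(vapply(lin$consensus,
                       function(s) nchar(gsub("[^ACGT]", "", s)), numeric(1)))
    # GC over intact copies of the conserved set, pooled across genes
    gc_n <- 0; gc_tot <- 0
    for (gid in conserved_set) {
      if (!isTRUE(unname(status[gid]) == "intact")) next
      g <- genes[genes$gene_id == gid, ]
      s <- substr(lin$consensus[[g$replicon_id]], g$start + 1L, g$end)
      s <- gsub("[^ACGT]", "", s)
      gc_n <- gc_n + nchar(gsub("[AT]", "", s))
      gc_tot <- gc_tot + nchar(s)
    }
    row <- data.frame(
      lineage_id = lin$lineage_id,
      gc_conserved_orthologs = if (gc_tot > 0) gc_n / gc_tot else NA_real_,
      fraction_reference_recovered = acgt / ref_len,
      n_intact = sum(lc$status == "intact"),
      n_pseudo = sum(lc$status == "pseudogene"),
      n_missing = sum(lc$status == "missing"),
      stringsAsFactors = FALSE)
    for (ct in cats) {
      in_cat <- genes$gene_id[grepl(ct, genes$categories, fixed = TRUE)]
      row[[paste0("intact_", ct)]] <- sum(status[in_cat] == "intact", na.rm = TRUE)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Evaluate pathway completeness for one lineage
#'
#' A biosynthetic step is satisfied if any of its alternative genes is
#' called intact, or if any of them is host-complemented; the pathway is
#' intact only if every step is satisfied.
#'
#' @param pathway list with `pathway_id`, `required_steps` (named list of
#'   character vectors of alternative gene ids) and `host_complemented`
#'   (character vector).
#' @param calls gene calls for a single lineage.
#' @return list with `pathway_id`, `status` (`"intact"` or `"broken"`),
#'   `broken_steps` and a per-step detail data.frame (`step_id`,
#'   `satisfied`, `via` in `{gene, host, none}`).
#' @export
pathway_status <- function(pathway, calls) {
  stopifnot(length(unique(calls$lineage_id)) <= 1L)
  status <- setNames(calls$status, calls$gene_id)
  steps <- lapply(names(pathway$required_steps), function(sid) {
    alts <- pathway$required_steps[[sid]]
    by_gene <- any(vapply(alts, function(g) isTRUE(unname(status[g]) == "intact"),
                          logical(1)))
    by_host <- any(alts %in% pathway$host_complemented)
    data.frame(step_id = sid, satisfied = by_gene || by_host,
               via = if (by_gene) "gene" else if (by_host) "host" else "none",
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, steps)
  list(pathway_id = pathway$pathway_id,
       status = if (all(detail$satisfied)) "intact" else "broken",
       broken_steps = detail$step_id[!detail$satisfied],
       steps = detail)
}

#' Read pathway definitions from JSON or YAML
#'
#' Expected structure: a list of pathways, each with `pathway_id`,
#' `required_steps` (mapping step id -> vector of alternative gene ids) and
#' optional `host_complemented`.
#'
#' @param path JSON (`.json`) or YAML file.
#' @param reference optional `erodeome_reference`; if given, every
#'   referenced gene id must exist in it.
#' @return list of pathway definitions.
#' @export
read_pathways <- function(path, reference = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  pws <- lapply(raw, function(p) {
    if (is.null(p$pathway_id) || is.null(p$required_steps) ||
        !length(p$required_steps)) {
      stop("each pathway needs a pathway_id and non-empty required_steps")
    }
    p$required_steps <- lapply(p$required_steps, unlist)
    p$host_complemented <- as.character(unlist(p$host_complemented))
    p
  })
  if (!is.null(reference)) {
    used <- unique(unlist(lapply(pws, function(p) unlist(p$required_steps))))
    unknown <- setdiff(used, reference$genes$gene_id)
    if (length(unknown)) {
      stop("pathway gene id(s) not in reference: ",
           paste(unknown, collapse = ", "))
    }
  }
  pws
}

#' Feature trends versus patristic distance
#'
#' For every numeric feature column, an ordinary least-squares fit against
#' patristic distance plus the Spearman rank correlation. Constant features
#' get slope 0, R-squared 0 and rho 0.
#'
#' @param features data.frame from [genome_features()].
#' @param metadata data.frame with `lineage_id` and `patristic_distance`.
#' @return data.frame with `feature`, `slope`, `r_squared`, `spearman_rho`.
#' @export
feature_trends <- function(features, metadata) {
  merged <- merge(features, metadata[, c("lineage_id", "patristic_distance")],
                  by = "lineage_id")
  x <- merged$patristic_distance
  feats <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   "lineage_id")
  rows <- lapply(feats, function(f) {
    y <- merged[[f]]
    ok <- is.finite(y) & is.finite(x)
    y <- y[ok]; xv <- x[ok]
    if (length(y) < 3L || sd(y) == 0) {
      return(data.frame(feature = f, slope = 0, r_squared = 0, spearman_rho = 0))
    }
    fit <- lm(y ~ xv)
    # summary.lm warns on exact fits, which are legitimate here
    data.frame(feature = f, slope = unname(coef(fit)[2]),
               r_squared = suppressWarnings(summary(fit)$r.squared),
               spearman_rho = suppressWarnings(cor(xv, y, method = "spearman")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
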