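STATUS_LEVELS <- c("intact", "pseudogene", "missing")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that preserves the
#' gap (`-`) and ambiguity (`N`) characters used by reference-coordinate
#' consensus sequences.
#'
#' @param x a single nucleotide string over `{A,C,G,T,N,-}`.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- reference -------------------------------------------------------------

new_reference <- function(seqs, genes, rejected) {
  structure(list(seqs = seqs, genes = genes, rejected = rejected),
            class = "erodeome_reference")
}

#' @export
print.erodeome_reference <- function(x, ...) {
  cat(sprintf("<erodeome_reference> %d replicon(s), %d gene(s), %d rejected\n",
              length(x$seqs), nrow(x$genes), nrow(x$rejected)))
  invisible(x)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), replicon_id = character(),
             start = integer(), end = integer(), strand = character(),
             cds_seq = character(), product = character(),
             categories = character(), group_ids = character(),
             stringsAsFactors = FALSE)
}

#' Read a reference genome and its gene coordinates
#'
#' Loads replicon sequences from FASTA and protein-coding gene coordinates
#' from either GFF3 (1-based closed; `CDS` features) or a BED-like TSV with
#' columns `replicon`, `start`, `end`, `strand`, `gene_id` (0-based
#' half-open). Coordinates are held internally as 0-based half-open on the
#' forward strand; CDS sequences are extracted in reading direction
#' (reverse-complemented for `-` strand genes).
#'
#' Genes violating the coding invariants (length not a multiple of 3, or not
#' ending in a stop codon) are not dropped silently: they are returned in the
#' `rejected` table with a reason (`"frame"` or `"stop"`).
#'
#' @param fasta_path path to the replicon FASTA.
#' @param annotation_path path to a GFF3 (`.gff`/`.gff3`) or BED-like TSV.
#' @return an `erodeome_reference`: list with `seqs` (named character vector
#'   of replicon sequences), `genes` (data.frame of accepted genes with
#'   columns `gene_id`, `replicon_id`, `start`, `end`, `strand`, `cds_seq`,
#'   `product`, `categories`, `group_ids`) and `rejected` (data.frame
#'   `gene_id`, `reason`).
#' @export
read_reference <- function(fasta_path, annotation_path) {
  if (!file.exists(fasta_path)) stop("reference FASTA not found: ", fasta_path)
  if (!file.exists(annotation_path)) {
    stop("annotation file not found: ", annotation_path)
  }
  seqs <- read_fasta(fasta_path)
  ext <- tolower(tools::file_ext(annotation_path))
  coords <- if (ext %in% c("gff", "gff3")) {
    read_gff_cds(annotation_path)
  } else {
    read_bed_genes(annotation_path)
  }
  build_reference(seqs, coords)
}

read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  toupper(out)
}

# GFF3 CDS records -> 0-based half-open coordinate table
read_gff_cds <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  ids <- gr$ID
  if (is.null(ids)) ids <- gr$Name
  if (is.null(ids) || anyNA(ids)) stop("GFF3 CDS features need ID attributes")
  md <- S4Vectors::mcols(gr)
  data.frame(
    gene_id = as.character(ids),
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = if ("product" %in% names(md)) as.character(md$product) else "",
    categories = if ("categories" %in% names(md)) as.character(md$categories) else "",
    group_ids = if ("group_ids" %in% names(md)) as.character(md$group_ids) else "",
    stringsAsFactors = FALSE
  )
}

read_bed_genes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("replicon", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(tab))) {
    stop("BED-like TSV must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(
    gene_id = as.character(tab$gene_id),
    replicon_id = as.character(tab$replicon),
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    strand = as.character(tab$strand),
    product = if ("product" %in% names(tab)) tab$product else "",
    categories = if ("categories" %in% names(tab)) tab$categories else "",
    group_ids = if ("group_ids" %in% names(tab)) tab$group_ids else "",
    stringsAsFactors = FALSE
  )
}

build_reference <- function(seqs, coords) {
  if (anyDuplicated(coords$gene_id)) {
    stop("duplicated gene_ids: ",
         paste(unique(coords$gene_id[duplicated(coords$gene_id)]), collapse = ", "))
  }
  missing_rep <- setdiff(coords$replicon_id, names(seqs))
  if (length(missing_rep)) {
    stop("annotation references replicons absent from FASTA: ",
         paste(missing_rep, collapse = ", "))
  }
  bad_strand <- !coords$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("invalid strand for gene(s): ",
         paste(coords$gene_id[bad_strand], collapse = ", "))
  }
  rep_len <- nchar(seqs)[coords$replicon_id]
  oob <- coords$start < 0L | coords$end > rep_len | coords$start >= coords$end
  if (any(oob)) {
    stop("coordinates out of range for gene(s): ",
         paste(coords$gene_id[oob], collapse = ", "))
  }

  cds <- vapply(seq_len(nrow(coords)), function(i) {
    s <- substr(seqs[[coords$replicon_id[i]]], coords$start[i] + 1L, coords$end[i])
    if (coords$strand[i] == "-") revcomp(s) else s
  }, character(1))

  reason <- rep(NA_character_, nrow(coords))
  frame_bad <- nchar(cds) %% 3L != 0L
  reason[frame_bad] <- "frame"
  last_codon <- substr(cds, nchar(cds) - 2L, nchar(cds))
  stop_bad <- !frame_bad & !last_codon %in% STOP_CODONS
  reason[stop_bad] <- "stop"

  genes <- cbind(coords[is.na(reason), , drop = FALSE],
                 cds_seq = cds[is.na(reason)], stringsAsFactors = FALSE)
  genes <- genes[, c("gene_id", "replicon_id", "start", "end", "strand",
                     "cds_seq", "product", "categories", "group_ids")]
  rownames(genes) <- NULL
  rejected <- data.frame(gene_id = coords$gene_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  new_reference(seqs, genes, rejected)
}

# ---- lineage consensus -----------------------------------------------------

new_lineage <- function(lineage_id, consensus, metadata = list()) {
  structure(list(lineage_id = lineage_id, consensus = consensus,
                 metadata = metadata), class = "erodeome_lineage")
}

#' @export
print.erodeome_lineage <- function(x, ...) {
  cat(sprintf("<erodeome_lineage> %s: %d replicon(s), %s bp\n", x$lineage_id,
              length(x$consensus), format(sum(nchar(x$consensus)), big.mark = ",")))
  invisible(x)
}

#' Read a reference-aligned consensus genome for one lineage
#'
#' The consensus must be in reference coordinates: one FASTA record per
#' reference replicon, each of exactly the reference length, with `-` marking
#' deleted positions and `N` ambiguous ones.
#'
#' @param fasta_path path to the consensus FASTA.
#' @param reference an `erodeome_reference`.
#' @param lineage_id lineage identifier; defaults to the FASTA basename.
#' @param coerce_ambiguous if `TRUE`, IUPAC ambiguity codes other than `N`
#'   are coerced to `N`; if `FALSE` (default) they are an error, keeping the
#'   edit-distance semantics unambiguous.
#' @param metadata optional named list (e.g. `patristic_distance`, `excluded`).
#' @return an `erodeome_lineage`.
#' @export
read_lineage <- function(fasta_path, reference, lineage_id = NULL,
                         coerce_ambiguous = FALSE, metadata = list()) {
  if (!file.exists(fasta_path)) stop("consensus FASTA not found: ", fasta_path)
  if (is.null(lineage_id)) {
    lineage_id <- tools::file_path_sans_ext(basename(fasta_path))
  }
  cons <- read_fasta(fasta_path)
  unknown <- setdiff(names(cons), names(reference$seqs))
  if (length(unknown)) {
    stop("consensus records not in reference: ", paste(unknown, collapse = ", "))
  }
  for (rep_id in names(cons)) {
    want <- nchar(reference$seqs[[rep_id]])
    got <- nchar(cons[[rep_id]])
    if (got != want) {
      stop(sprintf("length mismatch on replicon %s: consensus %d vs reference %d",
                   rep_id, got, want))
    }
    bad <- gsub("[ACGTN-]", "", cons[[rep_id]])
    if (nzchar(bad)) {
      if (coerce_ambiguous) {
        cons[[rep_id]] <- gsub("[^ACGTN-]", "N", cons[[rep_id]])
      } else {
        stop(sprintf("replicon %s contains characters outside {A,C,G,T,N,-}: %s",
                     rep_id, paste(unique(strsplit(bad, "")[[1]]), collapse = "")))
      }
    }
  }
  new_lineage(lineage_id, cons, metadata)
}

# ---- gene-call table I/O ---------------------------------------------------

#' Write / read gene-call tables
#'
#' Tab-separated with columns `lineage_id`, `gene_id`, `status`, `snled`,
#' `coverage`; `read_gene_calls(write_gene_calls(x))` is the identity.
#'
#' @param calls data.frame of gene calls.
#' @param path output / input file path.
#' @return `write_gene_calls()` returns `path` invisibly; `read_gene_calls()`
#'   returns the calls data.frame.
#' @export
write_gene_calls <- function(calls, path) {
  cols <- c("lineage_id", "gene_id", "status", "snled", "coverage")
  stopifnot(all(cols %in% names(calls)))
  write.table(calls[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_calls
#' @export
read_gene_calls <- function(path) {
  if (!file.exists(path)) stop("gene-call file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(lineage_id = "character", gene_id = "character",
                                   status = "character", snled = "numeric",
                                   coverage = "numeric"))
  bad <- which(!tab$status %in% STATUS_LEVELS)
  if (length(bad)) {
    stop("invalid status at data line(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(tab$status[bad]), collapse = ", "))
  }
  tab
}

# plain 9-column GFF3 writer for our own gene tables
write_gff3 <- function(genes, path, source = "erodeome") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- sprintf("ID=%s", genes$gene_id)
  extra <- function(field) {
    ifelse(nzchar(genes[[field]]), sprintf(";%s=%s", field, genes[[field]]), "")
  }
  attrs <- paste0(attrs, extra("product"), extra("categories"), extra("group_ids"))
  lines <- sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                   genes$replicon_id, source, genes$start + 1L, genes$end,
                   genes$strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
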