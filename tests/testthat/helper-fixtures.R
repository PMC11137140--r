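# Fixtures are built in code at test time; nothing is read from disk that a
# test did not itself write to a tempdir.

# independent dynamic-programming Levenshtein oracle (full matrix)
led_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
    }
  }
  d[n + 1, m + 1]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# a CDS with a valid start/stop and no internal in-frame stops
make_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  internal <- character(n_codons - 2L)
  for (i in seq_along(internal)) {
    repeat {
      cd <- random_dna(3)
      if (!cd %in% stops) break
    }
    internal[i] <- cd
  }
  paste0("ATG", paste(internal, collapse = ""), "TAA")
}

# one-replicon toy reference: genes placed with 25+ nt spacers
toy_reference <- function(cds_list, strands = NULL, spacer = 30L) {
  n <- length(cds_list)
  if (is.null(strands)) strands <- rep("+", n)
  pieces <- random_dna(spacer)
  start <- integer(n); end <- integer(n)
  pos <- spacer
  for (i in seq_len(n)) {
    fwd <- if (strands[i] == "+") cds_list[[i]] else revcomp(cds_list[[i]])
    pieces <- paste0(pieces, fwd, random_dna(spacer))
    start[i] <- pos
    end[i] <- pos + nchar(fwd)
    pos <- end[i] + spacer
  }
  genes <- data.frame(
    gene_id = sprintf("t%03d", seq_len(n)), replicon_id = "chr",
    start = start, end = end, strand = strands,
    cds_seq = unlist(cds_list), product = "", categories = "", group_ids = "",
    stringsAsFactors = FALSE)
  structure(list(seqs = c(chr = pieces), genes = genes,
                 rejected = data.frame(gene_id = character(),
                                       reason = character())),
            class = "erodeome_reference")
}

# treat a reference as its own lineage consensus
as_lineage <- function(reference, lineage_id = "self") {
  structure(list(lineage_id = lineage_id, consensus = reference$seqs,
                 metadata = list()), class = "erodeome_lineage")
}

# replace a 0-based half-open slice of a lineage's replicon
edit_consensus <- function(lineage, replicon, at, replacement) {
  s <- lineage$consensus[[replicon]]
  lineage$consensus[[replicon]] <-
    paste0(substr(s, 1, at), replacement,
           substr(s, at + nchar(replacement) + 1L, nchar(s)))
  lineage
}

# minimal call table builder
calls_df <- function(lineage_id, gene_id, status, snled = 0, coverage = 1) {
  data.frame(lineage_id = lineage_id, gene_id = gene_id, status = status,
             snled = snled, coverage = coverage, stringsAsFactors = FALSE)
}

write_toy_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  path
}

write_toy_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                     genes$replicon_id, genes$start + 1L, genes$end,
                     genes$strand, genes$gene_id), con)
  path
}
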