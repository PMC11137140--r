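# Forward simulator of reductive genome evolution: substitutions with AT
# bias, gene inactivation (premature stop or frameshift), then erosion of
# pseudogenes by deletion, under essential / operon / redundant-set
# constraints. Produces reference-coordinate consensus genomes plus a ground
# truth table for every (gene, lineage).

BASES <- c("A", "C", "G", "T")

#' Simulation parameters for synthetic genome degeneration
#'
#' Bundles and validates all knobs of the degeneration simulator. The
#' defaults define the package's standard synthetic study: 34 independent
#' lineages diverging from one ancestor along a comb-like branch-length
#' gradient, AT-biased substitution, gene inactivation followed by deletion
#' of pseudogene sequence.
#'
#' @param n_genes number of protein-coding genes in the synthetic ancestor.
#' @param gene_length_range min/max gene length in codons (inclusive).
#' @param ancestor_gc target GC fraction of the ancestor.
#' @param n_lineages number of independent derived lineages.
#' @param branch_lengths per-lineage branch lengths (substitutions/site);
#'   default is an even gradient from 0.05 to 0.5.
#' @param at_bias probability that a substitution is forced toward A/T.
#' @param inactivation_hazard per-gene inactivation rate per unit branch
#'   length (probability `1 - exp(-hazard * branch)`).
#' @param erosion_rate expected fraction of a pseudogene deleted per unit of
#'   residual branch length after inactivation.
#' @param redundancy_hazard rate at which a redundant pair/set resolves
#'   (loses exactly one member) per unit branch length. Large by default:
#'   loss of one member of a redundant set is nearly neutral and fixes fast.
#' @param operon_multiplier hazard multiplier applied to surviving members of
#'   an operon once any member is inactivated ("loss of one gene makes
#'   another obsolete").
#' @param stop_fraction fraction of inactivating lesions that are premature
#'   stops; the rest are 1-2 bp frameshifting deletions.
#' @param lesion_window relative span of the CDS (fractions of its codon
#'   count) within which inactivating lesions are placed; lesions in the last
#'   few percent of a gene rarely abolish function, so the window excludes
#'   the termini.
#' @param missing_threshold a pseudogene whose deleted fraction reaches this
#'   value is recorded as truly missing (complements the annotation module's
#'   coverage rule).
#' @param deletion_block_mean mean length (nt) of the geometric deletion
#'   blocks eroding pseudogenes.
#' @param constraint_sets list of `list(type, gene_ids)` with
#'   `type` in `essential`, `operon`, `redundant_pair`, `redundant_set`;
#'   defaults to [default_constraints()].
#' @param seed master seed; per-lineage seeds are derived from it.
#' @return a validated `erodeome_sim_params` list.
#' @export
simulation_params <- function(n_genes = 500L,
                              gene_length_range = c(100L, 200L),
                              ancestor_gc = 0.55,
                              n_lineages = 34L,
                              branch_lengths = NULL,
                              at_bias = 0.7,
                              inactivation_hazard = 3,
                              erosion_rate = 1.5,
                              redundancy_hazard = 100,
                              operon_multiplier = 10,
                              stop_fraction = 0.5,
                              lesion_window = c(0.2, 0.7),
                              missing_threshold = 0.75,
                              deletion_block_mean = 50,
                              constraint_sets = NULL,
                              seed = 1L) {
  if (is.null(branch_lengths)) {
    branch_lengths <- seq(0.05, 0.5, length.out = n_lineages)
  }
  if (is.null(constraint_sets)) constraint_sets <- default_constraints(n_genes)
  p <- list(n_genes = as.integer(n_genes),
            gene_length_range = as.integer(gene_length_range),
            ancestor_gc = ancestor_gc, n_lineages = as.integer(n_lineages),
            branch_lengths = branch_lengths, at_bias = at_bias,
            inactivation_hazard = inactivation_hazard,
            erosion_rate = erosion_rate, redundancy_hazard = redundancy_hazard,
            operon_multiplier = operon_multiplier,
            stop_fraction = stop_fraction, lesion_window = lesion_window,
            missing_threshold = missing_threshold,
            deletion_block_mean = deletion_block_mean,
            constraint_sets = constraint_sets, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "erodeome_sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_genes >= 1L,
            length(p$gene_length_range) == 2L,
            p$gene_length_range[1] >= 3L,
            p$gene_length_range[1] <= p$gene_length_range[2],
            p$ancestor_gc > 0, p$ancestor_gc < 1,
            length(p$branch_lengths) == p$n_lineages,
            all(p$branch_lengths >= 0),
            p$at_bias >= 0, p$at_bias <= 1,
            p$inactivation_hazard >= 0, p$erosion_rate >= 0,
            p$redundancy_hazard >= 0, p$operon_multiplier >= 1,
            p$stop_fraction >= 0, p$stop_fraction <= 1,
            length(p$lesion_window) == 2L,
            p$lesion_window[1] > 0, p$lesion_window[2] <= 1,
            p$missing_threshold > 0, p$missing_threshold <= 1)
  ids <- unlist(lapply(p$constraint_sets, `[[`, "gene_ids"))
  if (anyDuplicated(ids)) {
    stop("a gene may belong to at most one constraint set; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  types <- vapply(p$constraint_sets, `[[`, "", "type")
  bad <- setdiff(types, c("essential", "operon", "redundant_pair", "redundant_set"))
  if (length(bad)) stop("unknown constraint type(s): ", paste(bad, collapse = ", "))
  invisible(p)
}

#' Default constraint sets for a synthetic ancestor
#'
#' Twenty essential genes, two four-gene operons, and three redundant pairs,
#' placed on the first 34 genes (gene ids `g0001`, `g0002`, ...). These seed
#' the direct (operon) and reciprocal (redundant pair) retention patterns the
#' contingency engine is designed to recover.
#'
#' @param n_genes number of genes in the ancestor (must be at least 34).
#' @return list of constraint descriptors.
#' @export
default_constraints <- function(n_genes) {
  if (n_genes < 34L) return(list())
  gid <- function(i) sprintf("g%04d", i)
  list(
    list(type = "essential", gene_ids = gid(1:20)),
    list(type = "operon", gene_ids = gid(21:24)),
    list(type = "operon", gene_ids = gid(25:28)),
    list(type = "redundant_pair", gene_ids = gid(29:30)),
    list(type = "redundant_pair", gene_ids = gid(31:32)),
    list(type = "redundant_pair", gene_ids = gid(33:34))
  )
}

# ---- ancestor --------------------------------------------------------------

sample_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# random CDS: ATG + internal non-stop codons at target GC + sampled stop
random_cds <- function(n_codons, gc) {
  internal <- n_codons - 2L
  codons <- character(internal)
  need <- seq_len(internal)
  while (length(need)) {
    mat <- matrix(sample_bases(3L * length(need), gc), ncol = 3L)
    cand <- paste0(mat[, 1], mat[, 2], mat[, 3])
    ok <- !cand %in% STOP_CODONS
    codons[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a synthetic ancestor genome
#'
#' Packs `n_genes` non-overlapping CDSs (valid start/stop, no in-frame
#' internal stops, strands alternating at random) separated by intergenic
#' spacers onto a single replicon at the target GC.
#'
#' The first 20 genes are tagged with category `RRR` and the next 30 with
#' `translation` so category summaries are exercised downstream; constraint
#' memberships are recorded in `group_ids`.
#'
#' @param params an `erodeome_sim_params`.
#' @return an `erodeome_reference` with ground-truth annotation.
#' @export
generate_ancestor <- function(params) {
  set.seed(params$seed)
  n <- params$n_genes
  lens <- sample(seq(params$gene_length_range[1], params$gene_length_range[2]),
                 n, replace = TRUE)
  cds <- vapply(lens, random_cds, character(1), gc = params$ancestor_gc)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  spacers <- vapply(sample(20:100, n + 1L, replace = TRUE),
                    function(k) paste(sample_bases(k, params$ancestor_gc), collapse = ""),
                    character(1))

  group_of <- rep("", n)
  for (ci in seq_along(params$constraint_sets)) {
    cs <- params$constraint_sets[[ci]]
    idx <- as.integer(sub("^g", "", cs$gene_ids))
    if (any(idx > n)) stop("constraint set references gene beyond n_genes")
    tag <- sprintf("%s%02d", switch(cs$type, essential = "ess", operon = "op",
                                    redundant_pair = "rp", redundant_set = "rs"), ci)
    group_of[idx] <- tag
  }
  categories <- rep("", n)
  categories[seq_len(min(20L, n))] <- "RRR"
  if (n > 20L) categories[21:min(50L, n)] <- "translation"

  pieces <- character(2L * n + 1L)
  pieces[1L] <- spacers[1L]
  start <- integer(n)
  end <- integer(n)
  pos <- nchar(spacers[1L])
  for (i in seq_len(n)) {
    fwd <- if (strand[i] == "+") cds[i] else revcomp(cds[i])
    pieces[2L * i] <- fwd
    pieces[2L * i + 1L] <- spacers[i + 1L]
    start[i] <- pos
    end[i] <- pos + nchar(fwd)
    pos <- end[i] + nchar(spacers[i + 1L])
  }
  seqs <- c(chr1 = paste(pieces, collapse = ""))

  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n)), replicon_id = "chr1",
    start = start, end = end, strand = strand, cds_seq = cds,
    product = sprintf("synthetic protein %d", seq_len(n)),
    categories = categories, group_ids = group_of,
    stringsAsFactors = FALSE
  )
  new_reference(seqs, genes, data.frame(gene_id = character(),
                                        reason = character(),
                                        stringsAsFactors = FALSE))
}

# ---- lineage evolution -----------------------------------------------------

ALT_BASES <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))

substitute_base <- function(cur, at_bias) {
  n <- length(cur)
  use_at <- runif(n) < at_bias
  # uniform over the 3 alternatives ...
  out <- ALT_BASES[cbind(match(cur, BASES), sample.int(3L, n, replace = TRUE))]
  # ... unless forced toward A/T: A<->T, and C/G go to A or T at random
  at_pick <- sample(c("A", "T"), n, replace = TRUE)
  forced <- ifelse(cur == "A", "T", ifelse(cur == "T", "A", at_pick))
  out[use_at] <- forced[use_at]
  out
}

# sample which genes are inactivated given constraints; returns logical vector
sample_inactivations <- function(genes, branch, params) {
  n <- nrow(genes)
  hazard <- rep(params$inactivation_hazard, n)
  inact <- rep(FALSE, n)
  constrained <- rep(FALSE, n)
  idx_of <- function(ids) match(ids, genes$gene_id)

  for (cs in params$constraint_sets) {
    idx <- idx_of(cs$gene_ids)
    constrained[idx] <- TRUE
    if (cs$type == "essential") {
      hazard[idx] <- 0
    } else if (cs$type %in% c("redundant_pair", "redundant_set")) {
      # redundancy resolves fast and loses exactly one member
      if (runif(1) < 1 - exp(-params$redundancy_hazard * branch)) {
        inact[idx[sample.int(length(idx), 1L)]] <- TRUE
      }
    }
  }

  free <- which(!constrained)
  inact[free] <- runif(length(free)) < 1 - exp(-hazard[free] * branch)

  # operons: first pass independent, then accelerated hazard for co-members
  for (cs in params$constraint_sets) {
    if (cs$type != "operon") next
    idx <- idx_of(cs$gene_ids)
    inact[idx] <- runif(length(idx)) < 1 - exp(-hazard[idx] * branch)
    if (any(inact[idx])) {
      rest <- idx[!inact[idx]]
      extra <- 1 - exp(-hazard[rest] * (params$operon_multiplier - 1) * branch)
      inact[rest] <- runif(length(rest)) < extra
    }
  }
  inact
}

# apply premature stop / frameshift and erosion to one CDS (reading strand);
# returns list(seq, event, fraction_deleted)
degrade_cds <- function(cds_chars, branch, params) {
  ncod <- length(cds_chars) %/% 3L
  lo <- max(2L, ceiling(params$lesion_window[1] * ncod))
  hi <- min(ncod - 1L, floor(params$lesion_window[2] * ncod))
  if (hi < lo) hi <- lo
  k <- sample(lo:hi, 1L)
  if (runif(1) < params$stop_fraction) {
    event <- "substitution-to-stop"
    cds_chars[(3L * (k - 1L) + 1L):(3L * k)] <- strsplit(sample(STOP_CODONS, 1L), "")[[1]]
  } else {
    event <- "frameshift"
    w <- sample(1:2, 1L)
    pos <- 3L * (k - 1L) + 1L
    cds_chars[pos:(pos + w - 1L)] <- "-"
  }
  # erosion: geometric deletion blocks over the residual branch
  t_inact <- runif(1, 0, branch)
  target <- min(1, params$erosion_rate * (branch - t_inact))
  L <- length(cds_chars)
  guard <- 0L
  while (mean(cds_chars == "-") < target && guard < 200L) {
    bl <- rgeom(1L, 1 / params$deletion_block_mean) + 1L
    at <- sample.int(L, 1L)
    cds_chars[at:min(L, at + bl - 1L)] <- "-"
    guard <- guard + 1L
  }
  list(seq = cds_chars, event = event, fraction_deleted = mean(cds_chars == "-"))
}

# revert substitutions that would inactivate an intact gene: premature
# in-frame stops, and changes to the start or stop codon
repair_intact <- function(cds_chars, anc_chars) {
  ncod <- length(cds_chars) %/% 3L
  m <- matrix(cds_chars, nrow = 3L)
  codons <- paste0(m[1, ], m[2, ], m[3, ])
  bad <- which(codons %in% STOP_CODONS)
  bad <- bad[bad < ncod]                      # internal stops only
  fix <- unique(c(1L, ncod, bad))             # keep start + stop codons ancestral
  for (k in fix) {
    rng <- (3L * (k - 1L) + 1L):(3L * k)
    cds_chars[rng] <- anc_chars[rng]
  }
  cds_chars
}

#' Evolve one lineage from the ancestor
#'
#' Applies AT-biased per-site substitutions at rate `branch_length`, samples
#' gene inactivations under the constraint sets, introduces the inactivating
#' lesion (premature stop or frameshifting deletion), and erodes pseudogenes
#' by geometric deletion blocks over the residual branch. Intact genes are
#' kept translatable: substitutions creating in-frame stops or altering the
#' start/stop codon are reverted.
#'
#' @param reference an `erodeome_reference` (typically from
#'   [generate_ancestor()]).
#' @param branch_length branch length in substitutions/site.
#' @param params an `erodeome_sim_params`.
#' @param lineage_id identifier for the new lineage.
#' @param lineage_seed RNG seed for this lineage.
#' @return list with `lineage` (an `erodeome_lineage` whose metadata carries
#'   `patristic_distance = branch_length`) and `truth` (data.frame
#'   `gene_id`, `lineage_id`, `true_status`, `event`, `fraction_deleted`).
#' @export
evolve_lineage <- function(reference, branch_length, params,
                           lineage_id = "lineage", lineage_seed = params$seed + 1L) {
  stopifnot(branch_length >= 0)
  set.seed(lineage_seed)
  genes <- reference$genes
  cons <- lapply(reference$seqs, function(s) strsplit(s, "")[[1]])

  # genome-wide substitutions
  if (branch_length > 0) {
    for (rep_id in names(cons)) {
      x <- cons[[rep_id]]
      hit <- which(runif(length(x)) < branch_length)
      if (length(hit)) x[hit] <- substitute_base(x[hit], params$at_bias)
      cons[[rep_id]] <- x
    }
  }

  inact <- if (branch_length > 0) {
    sample_inactivations(genes, branch_length, params)
  } else rep(FALSE, nrow(genes))

  truth <- data.frame(gene_id = genes$gene_id, lineage_id = lineage_id,
                      true_status = "intact", event = "none",
                      fraction_deleted = 0, stringsAsFactors = FALSE)

  anc <- lapply(reference$seqs, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(nrow(genes))) {
    rng <- (genes$start[i] + 1L):genes$end[i]
    fwd <- cons[[genes$replicon_id[i]]][rng]
    anc_fwd <- anc[[genes$replicon_id[i]]][rng]
    if (genes$strand[i] == "-") {
      cur <- rev(chartr("ACGT", "TGCA", fwd))
      anc_cds <- rev(chartr("ACGT", "TGCA", anc_fwd))
    } else {
      cur <- fwd
      anc_cds <- anc_fwd
    }
    if (inact[i]) {
      d <- degrade_cds(cur, branch_length, params)
      cur <- d$seq
      truth$event[i] <- d$event
      truth$fraction_deleted[i] <- d$fraction_deleted
      truth$true_status[i] <- if (d$fraction_deleted >= params$missing_threshold)
        "missing" else "pseudogene"
    } else {
      cur <- repair_intact(cur, anc_cds)
    }
    back <- if (genes$strand[i] == "-") rev(chartr("ACGT", "TGCA", cur)) else cur
    cons[[genes$replicon_id[i]]][rng] <- back
  }

  consensus <- vapply(cons, paste, character(1), collapse = "")
  lineage <- new_lineage(lineage_id, consensus,
                         metadata = list(patristic_distance = branch_length))
  list(lineage = lineage, truth = truth)
}

#' Simulate a full replicate set in memory
#'
#' Generates the ancestor and all lineages of `params`, with per-lineage
#' seeds derived from the master seed so lineages are independent and
#' order-insensitive.
#'
#' @param params an `erodeome_sim_params`.
#' @return list with `reference`, `lineages` (named list of
#'   `erodeome_lineage`), `truth` (row-bound truth table) and `metadata`
#'   (data.frame `lineage_id`, `patristic_distance`, `excluded`).
#' @export
simulate_genomes <- function(params) {
  reference <- generate_ancestor(params)
  ids <- sprintf("L%02d", seq_len(params$n_lineages))
  seeds <- lineage_seeds(params$seed, params$n_lineages)
  res <- lapply(seq_len(params$n_lineages), function(i) {
    evolve_lineage(reference, params$branch_lengths[i], params,
                   lineage_id = ids[i], lineage_seed = seeds[i])
  })
  lineages <- setNames(lapply(res, `[[`, "lineage"), ids)
  truth <- do.call(rbind, lapply(res, `[[`, "truth"))
  rownames(truth) <- NULL
  metadata <- data.frame(lineage_id = ids,
                         patristic_distance = params$branch_lengths,
                         excluded = FALSE, stringsAsFactors = FALSE)
  list(reference = reference, lineages = lineages, truth = truth,
       metadata = metadata)
}

lineage_seeds <- function(master, n) {
  as.integer((as.double(master) * 1009 + 7919 * seq_len(n)) %% 2147483647)
}

#' Write a simulated replicate set to disk
#'
#' Materialises [simulate_genomes()] as files: `ancestor.fasta`,
#' `ancestor.gff3`, one consensus FASTA per lineage under `lineages/`,
#' `truth.tsv` and `metadata.tsv` (the realised branch length standing in
#' for patristic distance). Deterministic given `params$seed`.
#'
#' @param params an `erodeome_sim_params`.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the [simulate_genomes()] result, with a `paths`
#'   element added.
#' @export
make_replicate_set <- function(params, out_dir) {
  sim <- simulate_genomes(params)
  dir.create(file.path(out_dir, "lineages"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    ancestor_fasta = file.path(out_dir, "ancestor.fasta"),
    ancestor_gff = file.path(out_dir, "ancestor.gff3"),
    truth = file.path(out_dir, "truth.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    lineages = setNames(file.path(out_dir, "lineages",
                                  paste0(names(sim$lineages), ".fasta")),
                        names(sim$lineages))
  )
  write_fasta(sim$reference$seqs, paths$ancestor_fasta)
  write_gff3(sim$reference$genes, paths$ancestor_gff)
  for (id in names(sim$lineages)) {
    write_fasta(sim$lineages[[id]]$consensus, paths$lineages[[id]])
  }
  write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$metadata, paths$metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sim$paths <- paths
  invisible(sim)
}
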