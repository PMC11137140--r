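# ORF enumeration, Levenshtein scoring, size normalisation, and gene-status
# classification against the mixture cutoff.

test_that("led matches textbook cases and an independent DP oracle", {
  expect_identical(led("ACGT", "ACGT"), 0L)
  expect_identical(led("", paste(rep("A", 30), collapse = "")), 30L)
  expect_identical(led("kitten", "sitting"), 3L)
  set.seed(42)
  for (i in 1:300) {
    a <- random_dna(sample(0:8, 1))
    b <- random_dna(sample(0:8, 1))
    expect_identical(led(a, b), led_oracle(a, b))
  }
})

test_that("adding one substitution changes led by at most one", {
  set.seed(43)
  for (i in 1:50) {
    ref <- random_dna(60)
    x <- random_dna(60)
    pos <- sample(60, 1)
    y <- x
    substr(y, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(x, pos, pos))[sample(3, 1)]
    expect_lte(abs(led(y, ref) - led(x, ref)), 1L)
  }
})

test_that("extract_gene_region slices, clips, collapses gaps and honours strand", {
  set.seed(21)
  cds <- make_cds(20)  # 60 nt
  ref <- toy_reference(list(cds), spacer = 100L)
  g <- ref$genes[1, ]   # [100, 160)
  lin <- as_lineage(ref)

  region <- extract_gene_region(lin, g, flank = 25L)
  expect_equal(nchar(region), 60L + 50L)
  expect_equal(attr(region, "left_flank"), 25L)
  expect_identical(as.vector(substr(region, 26, 85)), cds)

  # a 6-nt deletion inside the gene shortens the collapsed region by 6
  lin_gap <- edit_consensus(lin, "chr", g$start + 12L, paste(rep("-", 6), collapse = ""))
  region_gap <- extract_gene_region(lin_gap, g, flank = 25L)
  expect_equal(nchar(region_gap), nchar(region) - 6L)

  # gene near the replicon start: left flank clipped, no error
  ref2 <- toy_reference(list(make_cds(10)), spacer = 10L)
  r2 <- extract_gene_region(as_lineage(ref2), ref2$genes[1, ], flank = 25L)
  expect_equal(attr(r2, "left_flank"), 10L)
  expect_equal(nchar(r2), 10L + 30L + 10L)

  # minus strand: the region reads 5'->3' in the gene's direction
  ref3 <- toy_reference(list(cds), strands = "-", spacer = 60L)
  r3 <- extract_gene_region(as_lineage(ref3), ref3$genes[1, ], flank = 25L)
  expect_identical(as.vector(substr(r3, 26, 85)), cds)
})

test_that("enumerate_orf_candidates reproduces the reference ORF and scan rules", {
  set.seed(22)
  cds <- make_cds(60)  # 180 nt
  ref <- toy_reference(list(cds), spacer = 40L)
  g <- ref$genes[1, ]
  region <- extract_gene_region(as_lineage(ref), g, flank = 25L)
  cand <- enumerate_orf_candidates(region, g, flank = 25L)
  expect_gt(nrow(cand), 0L)
  ref_core <- substr(cds, 1, nchar(cds) - 3)
  hit <- cand[cand$start_offset == 0L, ]
  expect_equal(nrow(hit), 1L)
  expect_identical(hit$seq, ref_core)
  expect_identical(hit$start_codon, "ATG")
  expect_true(all(abs(cand$start_offset) <= 25L))

  # in-frame premature stop at codon 10: candidate at the reference start
  # keeps codons 1..9 (stop excluded), i.e. 27 nt
  mut <- cds
  substr(mut, 28, 30) <- "TAA"
  ref_m <- toy_reference(list(mut), spacer = 40L)
  # the fixture rebuilds spacers, so re-derive the region from its own gene
  region_m <- extract_gene_region(as_lineage(ref_m), ref_m$genes[1, ], flank = 25L)
  cand_m <- enumerate_orf_candidates(region_m, ref_m$genes[1, ], flank = 25L)
  expect_equal(nchar(cand_m$seq[cand_m$start_offset == 0L]), 27L)

  # reference start mutated away with no alternative start in the window:
  # the first 60 nt contain no ATG/GTG/TTG, so no candidate can anchor
  region_dead <- structure(paste0(strrep("CCA", 20), substr(cds, 61, nchar(cds))),
                           left_flank = 0L)
  cand_dead <- enumerate_orf_candidates(region_dead, g, flank = 25L)
  expect_equal(nrow(cand_dead), 0L)
})

test_that("candidates without an in-frame stop run to the region end", {
  region <- structure(paste0("ATG", paste(rep("GCC", 30), collapse = "")),
                      left_flank = 0L)
  cand <- enumerate_orf_candidates(region, flank = 25L)
  expect_equal(nchar(cand$seq[cand$start_offset == 0L]), 93L)
})

test_that("best_candidate applies the stated tie-breaks", {
  base <- data.frame(start_offset = c(0L, 3L), start_codon = "ATG",
                     seq = c(strrep("A", 300), strrep("A", 297)),
                     stringsAsFactors = FALSE)
  base$led <- c(4L, 9L)
  expect_equal(best_candidate(base)$led, 4L)
  base$led <- c(5L, 5L)
  expect_equal(nchar(best_candidate(base)$seq), 300L)
  tie <- data.frame(start_offset = c(-6L, 3L), start_codon = "ATG",
                    seq = c(strrep("C", 60), strrep("C", 60)),
                    led = c(7L, 7L), stringsAsFactors = FALSE)
  expect_equal(best_candidate(tie)$start_offset, 3L)  # closest to 0 wins
  expect_null(best_candidate(base[0, ]))
})

test_that("snled normalises by the stop-less reference length", {
  gene <- data.frame(cds_seq = strrep("ATG", 201), stringsAsFactors = FALSE)
  expect_equal(snled(0L, gene), 0)
  expect_equal(snled(30L, gene), 0.05)         # 30 / 600
  expect_equal(snled(600L, gene), 1.0)         # fully deleted gene
})

test_that("a fully deleted gene scores snled 1 and is called missing", {
  set.seed(24)
  cds <- make_cds(30)
  ref <- toy_reference(list(make_cds(30), cds, make_cds(30)), spacer = 40L)
  lin <- as_lineage(ref)
  g <- ref$genes[2, ]
  lin <- edit_consensus(lin, "chr", g$start - 30L,
                        paste(rep("-", g$end - g$start + 60L), collapse = ""))
  res <- suppressMessages(annotate_lineage(lin, ref))
  row <- res$calls[res$calls$gene_id == g$gene_id, ]
  expect_equal(row$snled, 1.0)
  expect_equal(row$coverage, 0)
  expect_identical(row$status, "missing")
})

test_that("classification rules: coverage gate, inclusive cutoff", {
  calls <- data.frame(snled = c(0, 0.5, 0.1, 0.1000000), coverage = c(1, 0, 1, 1))
  fit <- structure(list(cutoff = 0.1), class = "erodeome_mixture")
  out <- classify(calls, fit, missing_threshold = 0.25)
  expect_identical(out$status, c("intact", "missing", "intact", "intact"))
  out2 <- classify(data.frame(snled = 0.1001, coverage = 1), fit)
  expect_identical(out2$status, "pseudogene")
})

test_that("self-annotation of the reference yields 100% intact via the fallback", {
  set.seed(25)
  ref <- toy_reference(lapply(rep(40, 25), make_cds), spacer = 40L)
  res <- suppressMessages(annotate_lineage(as_lineage(ref), ref))
  expect_true(res$fallback)
  expect_true(all(res$calls$status == "intact"))
  expect_true(all(res$calls$snled == 0))
})

test_that("genes with no candidate start enter the mixture as high-snLED points", {
  set.seed(26)
  cds_list <- lapply(rep(40, 24), make_cds)
  ref <- toy_reference(cds_list, spacer = 40L)
  lin <- as_lineage(ref)
  g <- ref$genes[5, ]
  # obliterate the gene body with an unrelated start-free sequence
  repl <- gsub("ATG|GTG|TTG", "CCC", random_dna(g$end - g$start + 60L))
  lin <- edit_consensus(lin, "chr", g$start - 30L,
                        substr(repl, 1, g$end - g$start + 60L))
  res <- suppressMessages(annotate_lineage(lin, ref))
  row <- res$calls[res$calls$gene_id == g$gene_id, ]
  expect_equal(row$n_candidates, 0L)
  expect_gt(row$snled, 0.3)
  expect_identical(row$status, "pseudogene")
})

test_that("truth agreement on a simulated lineage is high at moderate branch length", {
  p <- simulation_params(n_genes = 150L, n_lineages = 1L, branch_lengths = 0.2,
                         constraint_sets = default_constraints(150L), seed = 11L)
  ref <- generate_ancestor(p)
  ev <- evolve_lineage(ref, 0.2, p, "L1", 2024L)
  res <- suppressMessages(annotate_lineage(ev$lineage, ref))
  merged <- merge(res$calls, ev$truth, by = "gene_id")
  agree <- mean((merged$status == "intact") == (merged$true_status == "intact"))
  expect_gte(agree, 0.95)
})

test_that("pseudogene snLED grows with branch length across a gradient", {
  p <- simulation_params(n_genes = 120L, n_lineages = 6L,
                         branch_lengths = seq(0.1, 0.5, length.out = 6),
                         constraint_sets = list(), seed = 91L)
  sim <- simulate_genomes(p)
  ann <- suppressMessages(annotate_set(sim$lineages, sim$reference))
  calls <- ann$calls[ann$calls$status == "pseudogene", ]
  mean_snled <- tapply(calls$snled, calls$lineage_id, mean)
  branches <- sim$metadata$patristic_distance[
    match(names(mean_snled), sim$metadata$lineage_id)]
  expect_gt(cor(branches, mean_snled, method = "spearman"), 0.7)
})
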