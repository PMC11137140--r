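# String entropy, Hamming distances, relationship strength, relation
# classification and pattern clustering.

bits_of <- function(k, n) c(rep(1L, k), rep(0L, n - k))

test_that("shannon_entropy matches the Bernoulli formula and its landmarks", {
  expect_equal(round(shannon_entropy(bits_of(3, 34)), 2), 0.43)
  expect_equal(shannon_entropy(bits_of(0, 34)), 0)
  expect_equal(shannon_entropy(bits_of(34, 34)), 0)
  expect_equal(shannon_entropy(bits_of(17, 34)), 1)
  # independent arithmetic check at an arbitrary frequency
  p <- 5 / 12
  expect_equal(shannon_entropy(bits_of(5, 12)),
               -p * log2(p) - (1 - p) * log2(1 - p))
})

test_that("entropy is invariant under complementation", {
  set.seed(51)
  for (n in c(4L, 7L, 12L)) {
    for (i in 1:200) {
      b <- sample(0:1, n, TRUE)
      expect_equal(shannon_entropy(b), shannon_entropy(1L - b))
    }
  }
})

test_that("min_minority_entropy generalises the 3-of-34 threshold", {
  expect_equal(round(min_minority_entropy(34, 3), 2), 0.43)
  expect_equal(min_minority_entropy(34, 3), shannon_entropy(bits_of(3, 34)))
  expect_equal(min_minority_entropy(20, 0), 0)
  p <- 3 / 20
  expect_equal(min_minority_entropy(20, 3), -p * log2(p) - (1 - p) * log2(1 - p))
})

test_that("hamming distance counts differing positions and checks lengths", {
  expect_equal(hamming(bits_of(5, 10), bits_of(5, 10)), 0L)
  expect_equal(hamming(c(0L, 1L, 0L, 1L), c(1L, 0L, 1L, 0L)), 4L)
  expect_error(hamming(bits_of(2, 5), bits_of(2, 6)), "length mismatch")
})

test_that("hamming is a metric and complement-reflexive", {
  set.seed(52)
  n <- 20L
  for (i in 1:100) {
    a <- sample(0:1, n, TRUE); b <- sample(0:1, n, TRUE); c <- sample(0:1, n, TRUE)
    expect_equal(hamming(a, b), hamming(b, a))
    expect_equal(hamming(a, a), 0L)
    expect_lte(hamming(a, c), hamming(a, b) + hamming(b, c))
    expect_equal(hamming(a, 1L - b), n - hamming(a, b))
  }
})

test_that("relationship strength follows the entropy + midpoint-distance form", {
  expect_equal(relationship_strength(1, 1, 0, 34), 1.0)
  expect_equal(relationship_strength(1, 1, 34, 34), 1.0)
  expect_equal(relationship_strength(1, 1, 17, 34), 0.5)
  expect_equal(relationship_strength(0.43, 0.43, 34, 34), 0.715)
  # the pair entropy is the smaller of the two
  expect_equal(relationship_strength(0.2, 1, 0, 34),
               relationship_strength(1, 0.2, 0, 34))
  expect_equal(relationship_strength(0.2, 1, 0, 34), 0.5 * 0.2 + 0.5)
  # bounded and monotone on a grid
  grid <- expand.grid(E = seq(0, 1, 0.1), H = 0:34)
  s <- relationship_strength(grid$E, grid$E, grid$H, 34)
  expect_true(all(s >= 0 & s <= 1))
  for (E in c(0, 0.5, 1)) {
    sh <- relationship_strength(E, E, 0:34, 34)
    expect_true(all(diff(sh[1:18]) <= 1e-12))      # decreasing toward H = 17
    expect_true(all(diff(sh[18:35]) >= -1e-12))    # increasing beyond it
  }
})

test_that("all_relations matches a brute-force double-loop oracle", {
  set.seed(53)
  for (rep in 1:5) {
    n_genes <- sample(10:50, 1)
    n <- 12L
    B <- matrix(sample(0:1, n_genes * n, TRUE), n_genes, n,
                dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
    rel <- all_relations(B, entropy_min = "auto", k_min = 3L)

    ent <- apply(B, 1, shannon_entropy)
    thr <- min_minority_entropy(n, 3)
    keep <- which(ent >= thr - 1e-12)
    oracle <- list()
    for (i in keep) for (j in keep) {
      if (i >= j) next
      h <- sum(B[i, ] != B[j, ])
      e <- min(ent[i], ent[j])
      oracle[[length(oracle) + 1L]] <- data.frame(
        gene_a = rownames(B)[i], gene_b = rownames(B)[j], hamming = h,
        strength = 0.5 * e + (0.5 / (n / 2)) * abs(h - n / 2),
        relation = if (h < n / 2) "direct" else if (h > n / 2) "reciprocal" else "none",
        stringsAsFactors = FALSE)
    }
    oracle <- do.call(rbind, oracle)
    if (is.null(oracle)) {
      expect_equal(nrow(rel), 0L)
    } else {
      oracle <- oracle[order(oracle$gene_a, oracle$gene_b), ]
      expect_equal(nrow(rel), nrow(oracle))
      expect_identical(rel$gene_a, oracle$gene_a)
      expect_identical(rel$gene_b, oracle$gene_b)
      expect_equal(rel$hamming, oracle$hamming)
      expect_equal(rel$strength, oracle$strength)
      expect_identical(rel$relation, oracle$relation)
    }
  }
})

test_that("relation classification, midpoint drop, and entropy filter", {
  n <- 34L
  a <- bits_of(10, n)
  B <- rbind(g1 = a, g2 = a, g3 = 1L - a,
             g4 = bits_of(2, n),                       # below entropy filter
             g5 = c(rep(1L, 10), bits_of(7, 24)))
  rel <- all_relations(B)
  expect_false("g4" %in% c(rel$gene_a, rel$gene_b))
  r12 <- rel[rel$gene_a == "g1" & rel$gene_b == "g2", ]
  expect_identical(r12$relation, "direct")
  expect_equal(r12$hamming, 0L)
  expect_equal(r12$strength,
               relationship_strength(shannon_entropy(a), shannon_entropy(a), 0, n))
  r13 <- rel[rel$gene_a == "g1" & rel$gene_b == "g3", ]
  expect_identical(r13$relation, "reciprocal")
  expect_equal(r13$hamming, 34L)
  # a pair at exactly H = n/2 is kept in the table but not rendered
  h1 <- bits_of(17, n)
  h2 <- h1
  h2[1:8] <- 0L
  h2[18:26] <- 1L   # 8 + 9 = 17 flips, both strings high-entropy
  relh <- all_relations(rbind(g1 = h1, g2 = h2))
  expect_identical(relh$relation, "none")
  expect_false(relh$rendered)
  # strict thresholds narrow the labels
  rel_strict <- all_relations(B, direct_max = 0L, reciprocal_min = 34L)
  expect_identical(rel_strict$relation[rel_strict$gene_a == "g1" &
                                         rel_strict$gene_b == "g5"], "none")
})

test_that("edge list export sorts by strength and round-trips", {
  n <- 34L
  B <- rbind(g1 = bits_of(10, n), g2 = bits_of(10, n), g3 = 1L - bits_of(10, n),
             g4 = c(rep(1L, 5), bits_of(6, 29)))
  rel <- all_relations(B)
  path <- tempfile(fileext = ".tsv")
  export_edge_list(rel, path)
  back <- read_edge_list(path)
  expect_true(all(diff(back$strength) >= 0))
  expect_setequal(paste(back$gene_a, back$gene_b),
                  paste(rel$gene_a, rel$gene_b)[rel$rendered])
  merged <- merge(back, rel, by = c("gene_a", "gene_b"))
  expect_equal(merged$strength.x, merged$strength.y, tolerance = 1e-12)
  # stable tie order by gene ids on exactly equal strengths
  relx <- data.frame(gene_a = c("b", "a", "c"), gene_b = c("d", "b", "d"),
                     hamming = 0L, strength = c(0.5, 0.5, 0.2),
                     relation = "direct", rendered = TRUE,
                     stringsAsFactors = FALSE)
  export_edge_list(relx, path)
  backx <- read_edge_list(path)
  expect_identical(backx$gene_a, c("c", "a", "b"))
  # empty relations -> header only
  export_edge_list(rel[0, ], path)
  expect_identical(readLines(path),
                   "gene_a\tgene_b\thamming\tstrength\trelation")
})

test_that("complementary copies collapse into one cluster with recorded orientation", {
  n <- 20L
  set.seed(54)
  pat <- sample(0:1, n, TRUE)
  B <- rbind(matrix(rep(pat, 10), 10, byrow = TRUE),
             matrix(rep(1L - pat, 10), 10, byrow = TRUE))
  rownames(B) <- sprintf("g%02d", 1:20)
  cl <- cluster_patterns(B, max_radius = 0L)
  expect_equal(length(cl), 1L)
  expect_equal(nrow(cl[[1]]$members), 20L)
  expect_equal(sum(cl[[1]]$members$orientation == "complemented"), 10L)
  expect_equal(cl[[1]]$radius, 0L)
})

test_that("patterns farther apart than twice the radius split into clusters", {
  n <- 24L
  a <- c(rep(1L, 12), rep(0L, 12))
  b <- c(rep(1L, 4), rep(0L, 12), rep(1L, 8))   # far from a and its complement
  B <- rbind(a1 = a, a2 = a, b1 = b, b2 = b)
  expect_gt(min(hamming(a, b), n - hamming(a, b)), 2L * 2L)
  cl <- cluster_patterns(B, max_radius = 2L)
  expect_equal(length(cl), 2L)
  groups <- lapply(cl, function(c) sort(c$members$gene_id))
  expect_setequal(vapply(groups, paste, "", collapse = ","),
                  c("a1,a2", "b1,b2"))
  for (c in cl) expect_lte(c$radius, 2L)
  expect_equal(length(cluster_patterns(B[0, , drop = FALSE])), 0L)
})

test_that("planted redundant pairs and operons are recovered from simulation", {
  p <- simulation_params(n_genes = 60L, n_lineages = 20L,
                         branch_lengths = seq(0.1, 0.5, length.out = 20),
                         constraint_sets = default_constraints(60L), seed = 13L)
  sim <- simulate_genomes(p)
  truth_calls <- data.frame(lineage_id = sim$truth$lineage_id,
                            gene_id = sim$truth$gene_id,
                            status = sim$truth$true_status,
                            stringsAsFactors = FALSE)
  m <- build_matrix(truth_calls)
  rel <- all_relations(m)
  cl <- cluster_patterns(m, max_radius = 2L)
  cluster_of <- function(gid) {
    for (i in seq_along(cl)) if (gid %in% cl[[i]]$members$gene_id) return(i)
    NA_integer_
  }
  for (pr in list(c("g0029", "g0030"), c("g0031", "g0032"), c("g0033", "g0034"))) {
    losses <- rowSums(1L - m$binary[pr, , drop = FALSE])
    if (any(losses < 3)) next   # below the entropy filter by construction
    row <- rel[rel$gene_a == pr[1] & rel$gene_b == pr[2], ]
    expect_equal(nrow(row), 1L)
    expect_identical(row$relation, "reciprocal")
    ca <- cluster_of(pr[1]); cb <- cluster_of(pr[2])
    expect_equal(ca, cb)
    ors <- cl[[ca]]$members$orientation[cl[[ca]]$members$gene_id %in% pr]
    expect_setequal(ors, c("as-is", "complemented"))
  }
  # operon members co-retained: pairwise direct relations with small H
  for (op in list(sprintf("g%04d", 21:24), sprintf("g%04d", 25:28))) {
    sub <- rel[rel$gene_a %in% op & rel$gene_b %in% op, ]
    if (nrow(sub)) expect_true(all(sub$relation == "direct"))
  }
})
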