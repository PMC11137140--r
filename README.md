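# erodeome

Reference-guided quantification of genome degeneration in endosymbiotic
bacteria.

When insect lineages independently domesticate close relatives of the same
free-living bacterium, each endosymbiont genome decays along its own path:
genes pick up inactivating mutations (premature stops, frameshifts), the
resulting pseudogenes are eroded away by deletion, and base composition
drifts toward A+T. `erodeome` is for comparative genomicists who have a
well-annotated free-living reference plus reference-aligned consensus
genomes for many derived lineages, and who want to ask, per gene and per
lineage: *intact, pseudogene, or missing?* — and then, across lineages:
*which genes are lost together, and which are never lost together?*

## What it computes

**Gene status.** For each reference gene, candidate ORFs are enumerated from
every start codon (ATG/GTG/TTG) within ±25 nt of the reference start, each
extended to its first in-frame stop. Candidates are scored by Levenshtein
edit distance (LED) to the reference CDS; the minimum-LED candidate is
size-normalised to

&nbsp;&nbsp;&nbsp;&nbsp;snLED = LED / L_ref.

Per lineage, the snLED distribution is decomposed by E-M into a
two-component normal mixture (intact genes near 0, pseudogenes high), with
starting means (0, 1) and standard deviations (1, 1), and the cutoff

&nbsp;&nbsp;&nbsp;&nbsp;c = μ_intact + 3 σ_intact.

Genes with snLED ≤ c are intact, above it pseudogenes; genes whose consensus
covers < 25% of the reference CDS are missing.

**Retention and contingency.** Calls become a genes × lineages binary
retention matrix (intact → 1). Fractionally retained genes — intact in some
lineages, lost in others — are filtered by Shannon string entropy
(E ≥ entropy of 3 minority lineages; 0.43 bits at n = 34), then compared by
exhaustive pairwise Hamming distance H, with relationship strength

&nbsp;&nbsp;&nbsp;&nbsp;s = 0.5 E + (0.5 / (n/2)) · |H − n/2|.

H < n/2 marks co-retention (direct dependence, e.g. operons), H > n/2
reciprocal retention (functional redundancy: one or the other, never both).
A radius-bounded pattern clustering groups co- and reciprocally retained
genes, recording each member's orientation. Pathway completeness (with
host-complemented steps) and per-lineage genome features (conserved-ortholog
GC, reference recovery, status counts, category retention) round out the
reporting layer.

**Ground truth on demand.** A forward simulator generates a synthetic
ancestor and degenerate lineages under the assumed process — AT-biased
substitution, inactivation then deletion-erosion, essential/operon/redundant
constraints — with a truth table, so the whole pipeline is testable without
any external download.

## Worked example

Simulate a small radiation, annotate it, and look for reciprocal retention:

```r
library(erodeome)

params <- simulation_params(n_genes = 60, n_lineages = 8,
                            branch_lengths = seq(0.05, 0.4, length.out = 8),
                            constraint_sets = default_constraints(60), seed = 42)
sim <- simulate_genomes(params)
ann <- annotate_set(sim$lineages, sim$reference)

ann$fits[["L08"]]$fit
#> <erodeome_mixture> intact: N(0.3582, 0.0248) w=0.55 | pseudo: N(0.8454, 0.1108) w=0.45
#>   cutoff=0.4326, loglik=54.98, 20 iter, converged=TRUE
```

The most diverged lineage (branch 0.4) has its intact mode at snLED ≈ 0.36
(≈ one substitution per 2.8 sites accumulated along the branch) and its
pseudogene mode at ≈ 0.85; the 3-SD cutoff 0.43 separates them.

```r
mat <- build_matrix(ann$calls)
mat
#> <erodeome_retention> 60 genes x 8 lineages (universal intact 20, fractional 38, universal lost 2)

trends <- feature_trends(genome_features(sim$lineages, ann$calls, sim$reference),
                         sim$metadata)
trends[trends$feature %in% c("gc_conserved_orthologs", "n_intact"), ]
#>                  feature       slope r_squared spearman_rho
#> 1 gc_conserved_orthologs  -0.3865485 0.9890633   -1.0000000
#> 3               n_intact -53.0952381 0.7917244   -0.9047619
```

GC of the conserved orthologs and the intact-gene count both fall with
branch length — the classic degeneration gradient. The contingency stage
recovers the redundant pairs planted by `default_constraints()` (gene pairs
g0029/g0030, g0031/g0032, g0033/g0034) as reciprocal relations:

```r
rel <- all_relations(mat)
rec <- rel[rel$relation == "reciprocal", ]
head(rec[order(-rec$strength), ], 4)
#>     gene_a gene_b hamming strength   relation rendered
#> 3    g0033  g0034       8 0.977217 reciprocal     TRUE
#> 156  g0034  g0053       7 0.852217 reciprocal     TRUE
#> 124  g0037  g0051       7 0.852217 reciprocal     TRUE
#> 127  g0040  g0051       6 0.750000 reciprocal     TRUE
```

The planted pair g0033/g0034 tops the list at H = 8 of n = 8 lineages —
perfect reciprocality — with strength 0.98. (With only 8 lineages the other
planted pairs sit below the entropy filter in this draw; at the package's
standard 34-lineage scale all planted pairs are recovered, which is what the
acceptance suite asserts.)

`run_pipeline(pipeline_config(...), out_dir)` composes all stages and writes
`gene_calls.tsv`, `mixture_fits.tsv`, `retention_matrix.tsv` (+ binary
companion), `genome_features.tsv`, `feature_trends.tsv`, `relations.tsv`,
`clusters.tsv` and a provenance `manifest.json`. Existing data can be
supplied instead of a simulation via `inputs = list(reference_fasta = ...,
reference_annotation = ..., lineage_fastas = ...)`.

## Documentation

The methods vignette (`vignettes/genome-degeneration.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the simulator does and does not emulate, and known
limitations.
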