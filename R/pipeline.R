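# End-to-end composition of the pipeline stages (simulate -> annotate ->
# retention -> contingency) with a config object, per-stage summaries, and a
# provenance manifest.

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Defaults reproduce the
#' pipeline's standard constants: +/-25 nt start window, E-M starting
#' parameters (means 0 and 1, standard deviations 1 and 1), the
#' three-standard-deviation cutoff, the three-minority-lineage entropy
#' filter, and the H != n/2 rendering drop.
#'
#' @param simulate an [simulation_params()] object, or `NULL` when
#'   annotating existing files.
#' @param annotate an [annotate_config()].
#' @param exclude lineage ids excluded from the comparative stage.
#' @param k_min minority-lineage count behind the entropy filter.
#' @param max_radius Hamming radius for pattern clustering.
#' @param seed global seed (overrides `simulate$seed` when given).
#' @return nested configuration list.
#' @export
pipeline_config <- function(simulate = simulation_params(),
                            annotate = annotate_config(),
                            exclude = character(),
                            k_min = 3L, max_radius = 2L, seed = NULL) {
  if (!is.null(seed) && !is.null(simulate)) simulate$seed <- as.integer(seed)
  list(simulate = simulate, annotate = annotate, exclude = exclude,
       k_min = k_min, max_radius = max_radius, seed = seed)
}

#' Run the full degeneration-analysis pipeline
#'
#' Simulates (or loads) a replicate set, annotates every lineage against
#' the reference, assembles the retention matrix and genome features, and
#' runs the contingency stage (relations edge list and pattern clusters).
#' All tabular outputs are written as TSV under `out_dir`, together with a
#' `manifest.json` recording the configuration, package version, and MD5
#' hashes of the inputs. Deterministic for a fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param inputs optional list with pre-existing inputs instead of
#'   simulation: `reference_fasta`, `reference_annotation`,
#'   `lineage_fastas` (named character vector), optional `metadata` path.
#' @return (invisibly) list with `reference`, `lineages`, `calls`, `fits`,
#'   `matrix`, `features`, `trends`, `relations`, `clusters`, `truth`
#'   (simulated runs only) and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         inputs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_hashes <- list()

  if (is.null(inputs)) {
    sim <- make_replicate_set(config$simulate, file.path(out_dir, "simulated"))
    reference <- sim$reference
    lineages <- sim$lineages
    metadata <- sim$metadata
    truth <- sim$truth
  } else {
    for (p in c(inputs$reference_fasta, inputs$reference_annotation,
                inputs$lineage_fastas)) {
      if (!file.exists(p)) stop("input file not found: ", p)
    }
    reference <- read_reference(inputs$reference_fasta,
                                inputs$reference_annotation)
    lineages <- lapply(names(inputs$lineage_fastas), function(id) {
      read_lineage(inputs$lineage_fastas[[id]], reference, lineage_id = id)
    })
    names(lineages) <- names(inputs$lineage_fastas)
    metadata <- if (!is.null(inputs$metadata)) {
      read.delim(inputs$metadata, stringsAsFactors = FALSE)
    } else {
      data.frame(lineage_id = names(lineages),
                 patristic_distance = NA_real_, stringsAsFactors = FALSE)
    }
    truth <- NULL
    input_hashes <- as.list(tools::md5sum(unlist(inputs[c(
      "reference_fasta", "reference_annotation", "lineage_fastas")])))
  }

  ann <- annotate_set(lineages, reference, config$annotate)
  write_gene_calls(ann$calls, file.path(out_dir, "gene_calls.tsv"))
  fit_summary <- do.call(rbind, lapply(names(ann$fits), function(id) {
    f <- ann$fits[[id]]
    data.frame(lineage_id = id, cutoff = f$cutoff, fallback = f$fallback,
               mean_intact = if (is.null(f$fit)) NA else f$fit$mean_intact,
               sd_intact = if (is.null(f$fit)) NA else f$fit$sd_intact,
               mean_pseudo = if (is.null(f$fit)) NA else f$fit$mean_pseudo,
               sd_pseudo = if (is.null(f$fit)) NA else f$fit$sd_pseudo,
               stringsAsFactors = FALSE)
  }))
  write.table(fit_summary, file.path(out_dir, "mixture_fits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  mat <- build_matrix(ann$calls, exclude = config$exclude)
  write_retention_matrix(mat, file.path(out_dir, "retention_matrix.tsv"))

  features <- genome_features(lineages, ann$calls, reference)
  write.table(features, file.path(out_dir, "genome_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  trends <- feature_trends(features, metadata)
  write.table(trends, file.path(out_dir, "feature_trends.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  relations <- all_relations(mat, k_min = config$k_min)
  export_edge_list(relations, file.path(out_dir, "relations.tsv"))
  clusters <- cluster_patterns(mat, max_radius = config$max_radius)
  cl_tab <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, gene_id = cl$members$gene_id,
               orientation = cl$members$orientation, dist = cl$members$dist,
               radius = cl$radius, stringsAsFactors = FALSE)
  }))
  if (is.null(cl_tab)) {
    cl_tab <- data.frame(cluster_id = integer(), gene_id = character(),
                         orientation = character(), dist = integer(),
                         radius = integer())
  }
  write.table(cl_tab, file.path(out_dir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "erodeome",
    version = as.character(utils::packageVersion("erodeome")),
    config = serialize_config(config),
    input_hashes = input_hashes,
    n_genes = nrow(reference$genes),
    n_lineages = length(lineages),
    n_included = length(mat$lineage_ids),
    category_counts = as.list(table(mat$category)),
    n_relations = nrow(relations),
    n_clusters = length(clusters))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(reference = reference, lineages = lineages,
                 calls = ann$calls, fits = ann$fits, matrix = mat,
                 features = features, trends = trends,
                 relations = relations, clusters = clusters,
                 truth = truth, out_dir = out_dir))
}

serialize_config <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(config)
}
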