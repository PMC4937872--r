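#' Pipeline stage runners
#'
#' `run_invivo()`, `run_invitro()` and `run_network()` orchestrate the
#' three analysis stages end-to-end over flat-file (or in-memory) inputs,
#' write every stage artifact as CSV/JSON/Newick/GraphML/GEXF into
#' `out_dir`, and drop a `manifest.json` recording the configuration,
#' seeds, input checksums and output row counts needed to reproduce the
#' run. `run_all()` chains them on a simulated universe.
#'
#' @param records Endpoint record tibble or path to its CSV.
#' @param out_dir Output directory (created if needed).
#' @param vocabulary Vocabulary tibble or path to its CSV.
#' @param literature Optional literature MRDT flag table (tibble or CSV
#'   path with columns `chemical_id`, `is_mrdt`).
#' @param cluster Cluster the effect-score matrix? (needs >= 2 chemicals).
#' @return `run_invivo()` invisibly returns a list with the cLEL matrix,
#'   effect scores, MRDT flags, co-occurrence summary, clustering and
#'   manifest.
#' @name pipeline
NULL

read_if_path <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

input_hash <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(x, tf, version = 2)
    unname(tools::md5sum(tf))
  }
}

write_manifest <- function(out_dir, stage, config, inputs, counts) {
  manifest <- list(
    package = "repromine",
    version = as.character(utils::packageVersion("repromine")),
    stage = stage,
    config = config,
    input_md5 = inputs,
    row_counts = counts
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' @rdname pipeline
#' @export
run_invivo <- function(records, out_dir, vocabulary = NULL,
                       literature = NULL, cluster = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_hash <- list(records = input_hash(records))
  vocab <- if (is.null(vocabulary)) default_endpoint_vocabulary() else
    read_if_path(vocabulary, read_endpoint_vocabulary)
  records <- read_if_path(records, function(p) read_endpoint_records(p, vocab))
  records <- validate_endpoint_records(records, vocab)
  if (nrow(records) == 0L) stop("no endpoint records to analyze", call. = FALSE)

  clel <- aggregate_clel(records, vocab)
  clel_imp <- impute_missing_clel(clel)
  scores <- compute_effect_scores(clel_imp)
  flags <- flag_mrdt(records, vocab)
  if (!is.null(literature)) {
    literature <- read_if_path(literature, function(p)
      readr::read_csv(p, show_col_types = FALSE))
    flags <- merge_literature_flags(flags, literature)
  }
  cooc <- cooccurrence_summary(records, vocabulary = vocab)

  write_matrix_csv <- function(m, path) {
    df <- data.frame(chemical_id = rownames(m), m, check.names = FALSE)
    readr::write_csv(tibble::as_tibble(df), path)
  }
  write_matrix_csv(clel_imp$clel, file.path(out_dir, "clel_matrix.csv"))
  write_matrix_csv(clel_imp$imputed * 1L, file.path(out_dir, "clel_imputed_mask.csv"))
  write_matrix_csv(scores, file.path(out_dir, "effect_scores.csv"))
  readr::write_csv(flags, file.path(out_dir, "mrdt_flags.csv"))
  readr::write_csv(cooc$counts, file.path(out_dir, "cooccurrence_counts.csv"))
  readr::write_csv(cooc$chemical_order, file.path(out_dir, "cooccurrence_order.csv"))
  jsonlite::write_json(
    list(n_universe = cooc$n_universe, n_positive = cooc$n_positive,
         pct_positive_of_universe = cooc$pct_positive_of_universe,
         counts = cooc$counts, pairwise = as.data.frame(cooc$pairwise)),
    file.path(out_dir, "cooccurrence.json"), auto_unbox = TRUE, digits = NA)

  clustering <- NULL
  if (cluster && nrow(scores) >= 2L) {
    clustering <- hierarchical_cluster(scores, axis = "both")
    writeLines(clustering$rows$newick, file.path(out_dir, "cluster_rows.nwk"))
    writeLines(clustering$columns$newick, file.path(out_dir, "cluster_columns.nwk"))
    readr::write_csv(tibble::tibble(leaf = clustering$rows$order),
                     file.path(out_dir, "cluster_rows_order.csv"))
  }

  manifest <- write_manifest(out_dir, "invivo",
    config = list(cluster = cluster, literature = !is.null(literature)),
    inputs = in_hash,
    counts = list(records = nrow(records), chemicals = nrow(clel$clel),
                  mrdt = sum(flags$is_mrdt)))
  invisible(list(clel = clel_imp, effect_scores = scores, mrdt_flags = flags,
                 cooccurrence = cooc, clustering = clustering,
                 manifest = manifest))
}

#' @rdname pipeline
#' @param series Long concentration-response tibble (`chemical_id`,
#'   `assay_id`, `conc`, `response`) or path to its CSV.
#' @param assay_map Assay metadata tibble (`assay_id`, `gene_symbol`,
#'   `is_cytotox`) or path to its CSV.
#' @param threshold Critical response threshold for hit calls.
#' @param aggregation Gene-score aggregation, `"max"` or `"mean"`.
#' @export
run_invitro <- function(series, assay_map, out_dir, threshold = 20,
                        aggregation = "max") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_hash <- list(series = input_hash(series), assay_map = input_hash(assay_map))
  series <- read_if_path(series, function(p) readr::read_csv(p, show_col_types = FALSE))
  assay_map <- read_if_path(assay_map, function(p)
    readr::read_csv(p, show_col_types = FALSE,
                    col_types = readr::cols(is_cytotox = readr::col_logical(),
                                            .default = readr::col_character())))
  if (threshold > max(series$response)) {
    warning("response threshold exceeds every observed response; no hits possible",
            call. = FALSE)
  }
  hits <- call_hits_table(series, threshold = threshold)
  summaries <- cytotox_summaries(hits, assay_map)
  m_glob <- tryCatch(global_mad(summaries), error = function(e) NA_real_)
  if (!is.na(m_glob) && any(hits$is_hit)) {
    gs <- gene_scores(hits, summaries, m_glob, assay_map,
                      aggregation = aggregation)
  } else {
    warning("gene scores unavailable: no hits or undefined cytotoxicity scale",
            call. = FALSE)
    gs <- list(
      scores = tibble::tibble(chemical_id = character(),
                              gene_symbol = character(), G = numeric(),
                              n_hit_assays = integer(), n_assay = integer()),
      provenance = tibble::tibble(chemical_id = character(),
                                  gene_symbol = character(),
                                  assay_id = character(),
                                  log10_ac50 = numeric(), Z = numeric()))
  }
  gs$scores$G_modified_uM <- modified_gene_score(gs$scores$G)

  readr::write_csv(hits, file.path(out_dir, "hit_calls.csv"))
  readr::write_csv(summaries, file.path(out_dir, "cytotox_summary.csv"))
  readr::write_csv(gs$scores, file.path(out_dir, "gene_scores.csv"))
  readr::write_csv(gs$provenance, file.path(out_dir, "gene_score_provenance.csv"))
  wide <- gene_score_matrix(gs$scores)
  readr::write_csv(tibble::as_tibble(
    data.frame(chemical_id = rownames(wide), wide, check.names = FALSE)),
    file.path(out_dir, "gene_scores_wide.csv"))

  manifest <- write_manifest(out_dir, "invitro",
    config = list(threshold = threshold, aggregation = aggregation,
                  m_global = m_glob),
    inputs = in_hash,
    counts = list(series_points = nrow(series), fits = nrow(hits),
                  hits = sum(hits$is_hit), scored_pairs = nrow(gs$scores)))
  invisible(list(hits = hits, cytotox = summaries, m_global = m_glob,
                 gene_scores = gs, manifest = manifest))
}

#' @rdname pipeline
#' @param scores Long gene-score tibble or path to `gene_scores.csv`.
#' @param annotation Optional gene annotation (tibble or CSV path with
#'   columns `gene_symbol`, `class_label`).
#' @param mrdt_flags Optional MRDT flag tibble (or CSV path) for chemical
#'   node provenance.
#' @param z_threshold Minimum gene score for an edge.
#' @param formats Export formats, subset of `c("graphml", "gexf")`.
#' @param layout_seed,layout_iterations Force-layout determinism controls.
#' @export
run_network <- function(scores, out_dir, annotation = NULL, mrdt_flags = NULL,
                        z_threshold = 0, formats = c("graphml", "gexf"),
                        layout_seed = 1L, layout_iterations = 500L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  in_hash <- list(scores = input_hash(scores))
  scores <- read_if_path(scores, function(p) readr::read_csv(p, show_col_types = FALSE))
  annotation <- read_if_path(annotation, function(p)
    readr::read_csv(p, show_col_types = FALSE))
  mrdt_flags <- read_if_path(mrdt_flags, function(p)
    readr::read_csv(p, show_col_types = FALSE))

  net <- build_network(scores, z_threshold = z_threshold)
  net <- annotate_nodes(net, annotation, mrdt_flags)
  stats_tbl <- degree_stats(net)
  layout <- if (igraph::vcount(net) > 0) {
    force_layout(net, seed = layout_seed, iterations = layout_iterations)
  } else NULL

  for (fmt in formats) {
    export_graph(net, file.path(out_dir, paste0("network.", fmt)),
                 layout = layout, format = fmt)
  }
  readr::write_csv(stats_tbl, file.path(out_dir, "degree_summary.csv"))
  summ <- attr(stats_tbl, "summary")

  manifest <- write_manifest(out_dir, "network",
    config = list(z_threshold = z_threshold, formats = formats,
                  layout_seed = layout_seed,
                  layout_iterations = layout_iterations),
    inputs = in_hash,
    counts = list(nodes = igraph::vcount(net), edges = igraph::ecount(net),
                  unmapped_genes = length(igraph::graph_attr(net, "unmapped_genes"))))
  invisible(list(network = net, layout = layout, degree = stats_tbl,
                 degree_summary = summ, manifest = manifest))
}

#' @rdname pipeline
#' @param invivo_config A [syndrome_sim_config()].
#' @param assay_config An [assay_sim_config()].
#' @param seed Overrides both simulator seeds when not NULL.
#' @export
run_all <- function(out_dir, invivo_config = syndrome_sim_config(),
                    assay_config = assay_sim_config(), seed = NULL,
                    threshold = 20, aggregation = "max", z_threshold = 0) {
  if (!is.null(seed)) {
    invivo_config$seed <- as.integer(seed)
    assay_config$seed <- as.integer(seed) + 1L
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_vivo <- simulate_invivo(invivo_config)
  sim_vitro <- simulate_assays(assay_config)

  vivo <- run_invivo(sim_vivo$records, file.path(out_dir, "invivo"))
  vitro <- run_invitro(sim_vitro$series, sim_vitro$assay_map,
                       file.path(out_dir, "invitro"),
                       threshold = threshold, aggregation = aggregation)
  net <- run_network(vitro$gene_scores$scores, file.path(out_dir, "network"),
                     mrdt_flags = vivo$mrdt_flags, z_threshold = z_threshold)

  recovery <- list(
    invivo = evaluate_recovery(sim_vivo$truth, mrdt_flags = vivo$mrdt_flags,
                               cooccurrence = vivo$cooccurrence),
    invitro = evaluate_recovery(sim_vitro$truth,
                                scores = vitro$gene_scores$scores,
                                hits = vitro$hits)
  )
  invisible(list(sim_invivo = sim_vivo, sim_assays = sim_vitro, invivo = vivo,
                 invitro = vitro, network = net, recovery = recovery))
}

#' Write a simulated universe to disk in the reader schemas
#'
#' Emits the synthetic endpoint records, concentration-response series,
#' assay map and planted-truth tables as CSV, plus the configs (with
#' embedded seeds) as JSON.
#'
#' @param out_dir Output directory.
#' @param invivo_config,assay_config Simulator configurations.
#' @return Invisibly, the two simulation objects.
#' @export
write_simulated_universe <- function(out_dir,
                                     invivo_config = syndrome_sim_config(),
                                     assay_config = assay_sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sv <- simulate_invivo(invivo_config)
  sa <- simulate_assays(assay_config)
  readr::write_csv(sv$records, file.path(out_dir, "endpoint_records.csv"))
  readr::write_csv(sv$truth, file.path(out_dir, "invivo_truth.csv"))
  readr::write_csv(sa$series, file.path(out_dir, "assay_series.csv"))
  readr::write_csv(sa$assay_map, file.path(out_dir, "assay_map.csv"))
  readr::write_csv(sa$truth$pairs, file.path(out_dir, "assay_pair_truth.csv"))
  readr::write_csv(sa$truth$assays, file.path(out_dir, "assay_series_truth.csv"))
  readr::write_csv(sa$truth$chemicals, file.path(out_dir, "assay_chemical_truth.csv"))
  jsonlite::write_json(list(invivo = unclass(invivo_config),
                            assays = unclass(assay_config)),
                       file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(invivo = sv, assays = sa))
}
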