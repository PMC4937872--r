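#' Summarize a chemical's cytotoxicity burst
#'
#' For one chemical, over the cytotoxicity assay panel: the number of
#' cytotoxicity hits, the median `m` of their log10 AC50 values, and the
#' median absolute deviation (raw MAD, no consistency constant) of that
#' set. With fewer than two cytotoxicity hits the burst location is
#' undefined and `m` defaults to 3 (cytotoxicity assumed at 1000 uM, the
#' conventional "not cytotoxic in the tested range" anchor); the MAD is
#' then absent.
#'
#' @param log10_ac50 Numeric vector of log10 AC50 values (log10 uM) of the
#'   chemical's cytotoxicity-panel hits (may be empty).
#' @return A one-row tibble: `n_cytotox_hits`, `m`, `mad`.
#' @export
cytotox_summary <- function(log10_ac50) {
  x <- log10_ac50[!is.na(log10_ac50)]
  n <- length(x)
  if (n < 2L) {
    tibble::tibble(n_cytotox_hits = n, m = 3, mad = NA_real_)
  } else {
    med <- stats::median(x)
    tibble::tibble(n_cytotox_hits = n, m = med,
                   mad = stats::median(abs(x - med)))
  }
}

#' Cytotoxicity summaries for every chemical of a hit table
#'
#' @param hits Hit-call tibble (see [call_hits_table()]).
#' @param assay_map Tibble with columns `assay_id`, `gene_symbol`,
#'   `is_cytotox` flagging the cytotoxicity panel.
#' @param chemicals Chemicals to summarize; defaults to those in `hits`.
#' @return A tibble with one row per chemical: `chemical_id`,
#'   `n_cytotox_hits`, `m`, `mad`.
#' @export
cytotox_summaries <- function(hits, assay_map, chemicals = NULL) {
  stopifnot(all(c("assay_id", "is_cytotox") %in% names(assay_map)))
  if (is.null(chemicals)) chemicals <- sort(unique(hits$chemical_id))
  panel <- assay_map$assay_id[assay_map$is_cytotox]
  ctx <- hits[hits$assay_id %in% panel & hits$is_hit, ]
  rows <- lapply(chemicals, function(ch) {
    s <- cytotox_summary(ctx$log10_ac50[ctx$chemical_id == ch])
    s$chemical_id <- ch
    s
  })
  dplyr::bind_rows(rows)[, c("chemical_id", "n_cytotox_hits", "m", "mad")]
}

#' Population scale of cytotoxicity-burst spread
#'
#' `M_global` is the median of the per-chemical MADs, taken over the
#' chemicals that have a defined MAD (at least two cytotoxicity hits). It
#' sets the unit in which a hit's distance below the cytotoxicity burst is
#' expressed.
#'
#' @param summaries Tibble from [cytotox_summaries()] (or any tibble with a
#'   `mad` column).
#' @return The scalar `M_global` (log10 uM units).
#' @export
global_mad <- function(summaries) {
  mads <- summaries$mad[!is.na(summaries$mad)]
  if (length(mads) == 0L) {
    stop("M_global undefined: no chemical has two or more cytotoxicity hits",
         call. = FALSE)
  }
  stats::median(mads)
}

#' Cytotoxicity-adjusted standardized score of a hit
#'
#' For a hit of chemical X in assay A,
#' `Z = (m(X) - log10 AC50(X, A)) / M_global`:
#' the number of population-scale MAD units by which the hit's potency lies
#' below the chemical's cytotoxicity burst. Large Z means activity at
#' concentrations well below cytotoxicity, i.e. selective bioactivity;
#' Z near 0 marks hits riding the cytotoxicity burst.
#'
#' @param log10_ac50 The hit's log10 AC50 (log10 uM); NA (non-hit) is an
#'   error.
#' @param m The chemical's cytotoxicity-burst median (see
#'   [cytotox_summary()]).
#' @param m_global The population scale from [global_mad()] (> 0).
#' @return The standardized score Z (vectorized).
#' @export
z_score <- function(log10_ac50, m, m_global) {
  if (any(is.na(log10_ac50))) {
    stop("Z-score requires a hit AC50; got NA", call. = FALSE)
  }
  if (!is.finite(m_global) || m_global <= 0) {
    stop("M_global must be a positive finite scale", call. = FALSE)
  }
  (m - log10_ac50) / m_global
}

#' Gene scores: per-gene summaries of selective bioactivity
#'
#' The gene score G(X, g) condenses the hit Z-scores of the assays mapped
#' to gene g. Under the default `"max"` aggregation, G is the largest Z
#' among the hit assays of that gene (conservative and
#' provenance-preserving); `"mean"` averages the hit-assay Z values. A
#' chemical x gene pair with no hit among its mapped assays has no score.
#' Cytotoxicity-panel assays never contribute.
#'
#' @param hits Hit-call tibble (see [call_hits_table()]).
#' @param summaries Per-chemical cytotoxicity summaries
#'   ([cytotox_summaries()]).
#' @param m_global Population scale from [global_mad()].
#' @param assay_map Tibble `assay_id`, `gene_symbol`, `is_cytotox`.
#' @param aggregation `"max"` (default) or `"mean"`.
#' @return A list with `scores` (tibble `chemical_id`, `gene_symbol`, `G`,
#'   `n_hit_assays`, `n_assay` = assays mapped to the gene) and
#'   `provenance` (long tibble of contributing hits with per-assay `Z`).
#' @export
gene_scores <- function(hits, summaries, m_global, assay_map,
                        aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  map <- assay_map[!assay_map$is_cytotox & !is.na(assay_map$gene_symbol), ]
  if (nrow(map) == 0L) stop("assay map contains no gene-mapped assays", call. = FALSE)
  n_assay <- dplyr::count(map, .data$gene_symbol, name = "n_assay")

  h <- dplyr::inner_join(hits[hits$is_hit, ], map[, c("assay_id", "gene_symbol")],
                         by = "assay_id")
  h <- dplyr::inner_join(h, summaries[, c("chemical_id", "m")], by = "chemical_id")
  h$Z <- z_score(h$log10_ac50, h$m, m_global)

  agg_fn <- if (aggregation == "max") max else mean
  scores <- dplyr::summarise(
    dplyr::group_by(h, .data$chemical_id, .data$gene_symbol),
    G = agg_fn(.data$Z), n_hit_assays = dplyr::n(), .groups = "drop")
  scores <- dplyr::left_join(scores, n_assay, by = "gene_symbol")
  provenance <- dplyr::arrange(
    h[, c("chemical_id", "gene_symbol", "assay_id", "log10_ac50", "Z")],
    .data$chemical_id, .data$gene_symbol, .data$assay_id)
  list(scores = dplyr::arrange(scores, .data$chemical_id, .data$gene_symbol),
       provenance = provenance)
}

#' Look up a single gene score
#'
#' @param scores The `scores` tibble from [gene_scores()].
#' @param chemical,gene Identifiers of the pair.
#' @param assay_map The assay map used to build the scores; a gene with no
#'   mapped assay is an error, a mapped gene with no hit returns NA.
#' @return The score G, or NA when no mapped assay of the gene is a hit.
#' @export
gene_score <- function(scores, chemical, gene, assay_map) {
  mapped <- assay_map$gene_symbol[!assay_map$is_cytotox]
  if (!gene %in% mapped) {
    stop("gene has no mapped assay: ", gene, call. = FALSE)
  }
  g <- scores$G[scores$chemical_id == chemical & scores$gene_symbol == gene]
  if (length(g) == 0L) NA_real_ else g
}

#' Modified gene score as a micromolar-equivalent potency
#'
#' Re-expresses the dimensionless gene score on a concentration-like scale:
#' `G' = 10^(-G)` uM-equivalents, so larger (more selective) scores map to
#' lower micromolar values. Absent scores stay absent.
#'
#' @param G Gene score(s); NA propagates.
#' @return `10^(-G)` in uM-equivalent units.
#' @export
modified_gene_score <- function(G) 10^(-G)

#' Widen a long gene-score table into a chemical x gene matrix
#'
#' @param scores The `scores` tibble from [gene_scores()].
#' @param fill Value for absent pairs (default NA).
#' @return Numeric matrix, chemicals in rows, genes in columns.
#' @export
gene_score_matrix <- function(scores, fill = NA_real_) {
  chems <- sort(unique(scores$chemical_id))
  genes <- sort(unique(scores$gene_symbol))
  m <- matrix(fill, length(chems), length(genes),
              dimnames = list(chems, genes))
  m[cbind(scores$chemical_id, scores$gene_symbol)] <- scores$G
  m
}
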