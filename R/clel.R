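#' Aggregate endpoint LELs into a category cLEL matrix
#'
#' For each chemical and effect category, the category LEL (cLEL) is the
#' minimum lowest-effect-level over every record of that chemical whose
#' endpoint maps into the category, across all studies and subendpoints.
#' Cells with no dosed record are missing. By default only the four MRDT
#' categories (malformation, sperm, histology, weight) form the matrix;
#' testicular tumors are excluded from potency profiling.
#'
#' @param records Endpoint record tibble (see [read_endpoint_records()]).
#' @param vocabulary Vocabulary tibble mapping terms to categories.
#' @param categories Categories forming the matrix columns.
#' @return A `clel_matrix`: list with `clel` (chemicals x categories numeric
#'   matrix, NA = missing) and `imputed` (logical mask, all FALSE here).
#' @export
aggregate_clel <- function(records, vocabulary = default_endpoint_vocabulary(),
                           categories = mrdt_categories()) {
  records <- validate_endpoint_records(records, vocabulary)
  dosed <- records[!is.na(records$lel_mg_kg_day), ]
  if (nrow(dosed) && any(dosed$lel_mg_kg_day <= 0)) {
    stop("nonpositive LEL encountered", call. = FALSE)
  }
  cls <- classify_endpoint(dosed$endpoint_term, dosed$study_type,
                           dosed$generation, vocabulary)
  dosed$category <- cls$category
  dosed <- dosed[dosed$category %in% categories, ]

  # chemicals enter the potency matrix only with >=1 dosed record in an
  # included category (e.g. tumor-only chemicals have no cLEL row)
  chemicals <- sort(unique(dosed$chemical_id))
  clel <- matrix(NA_real_, nrow = length(chemicals), ncol = length(categories),
                 dimnames = list(chemicals, categories))
  if (nrow(dosed)) {
    mins <- dplyr::summarise(
      dplyr::group_by(dosed, .data$chemical_id, .data$category),
      clel = min(.data$lel_mg_kg_day), .groups = "drop")
    clel[cbind(mins$chemical_id, mins$category)] <- mins$clel
  }
  new_clel_matrix(clel, imputed = array(FALSE, dim(clel), dimnames(clel)))
}

new_clel_matrix <- function(clel, imputed) {
  structure(list(clel = clel, imputed = imputed), class = "clel_matrix")
}

#' @export
print.clel_matrix <- function(x, ...) {
  cat(sprintf("<clel_matrix> %d chemicals x %d categories (%d observed, %d imputed)\n",
              nrow(x$clel), ncol(x$clel),
              sum(!is.na(x$clel) & !x$imputed), sum(x$imputed)))
  invisible(x)
}

#' Impute missing cLEL cells at 10x the chemical's maximum observed cLEL
#'
#' A chemical missing a category is assigned ten times its highest observed
#' cLEL in that cell, completing the matrix for clustering across a
#' hypothetical syndrome. The imputed value does not assert a predicted
#' effect; it encodes "might be observed had a high enough dose been
#' tested". Observed cells are never altered.
#'
#' @param x A `clel_matrix` from [aggregate_clel()].
#' @return A complete `clel_matrix` with the `imputed` mask set.
#' @export
impute_missing_clel <- function(x) {
  stopifnot(inherits(x, "clel_matrix"))
  clel <- x$clel
  imputed <- x$imputed
  n_obs <- rowSums(!is.na(clel))
  if (any(n_obs == 0L)) {
    stop("cannot impute: chemical(s) with no observed category cLEL: ",
         paste(head(rownames(clel)[n_obs == 0L], 5), collapse = ", "),
         call. = FALSE)
  }
  row_max <- apply(clel, 1L, max, na.rm = TRUE)
  for (i in seq_len(nrow(clel))) {
    gap <- is.na(clel[i, ])
    if (any(gap)) {
      clel[i, gap] <- 10 * row_max[i]
      imputed[i, gap] <- TRUE
    }
  }
  new_clel_matrix(clel, imputed)
}

#' Compute effect scores from a complete cLEL matrix
#'
#' The effect score expresses relative potency: each cell's cLEL is
#' transformed to -log10(cLEL mg/kg/day) and the whole matrix is min-max
#' normalized to 0-100. A score of 100 marks the most potent chemical x
#' category pair in the matrix (lowest cLEL), 0 the least potent. By
#' default the normalization range includes imputed cells, since the
#' completed matrix is what gets clustered; set `include_imputed = FALSE`
#' to anchor the range on observed cells only.
#'
#' @param x A complete `clel_matrix` (run [impute_missing_clel()] first).
#' @param include_imputed Should imputed cells enter the min/max range?
#' @return Numeric matrix of scores in \[0, 100\] with attribute `imputed`.
#' @export
compute_effect_scores <- function(x, include_imputed = TRUE) {
  stopifnot(inherits(x, "clel_matrix"))
  if (anyNA(x$clel)) {
    stop("cLEL matrix has missing cells; impute before scoring", call. = FALSE)
  }
  v <- -log10(x$clel)
  rng <- if (include_imputed) range(v) else range(v[!x$imputed])
  scores <- v
  if (diff(rng) == 0) {
    warning("degenerate cLEL matrix (all values equal); all effect scores set to 0",
            call. = FALSE)
    scores[] <- 0
  } else {
    scores[] <- 100 * (v - rng[1]) / (rng[2] - rng[1])
    if (!include_imputed) {
      # imputed cLELs can fall outside the observed range; keep the scale's bounds
      scores[] <- pmin(pmax(scores, 0), 100)
    }
  }
  attr(scores, "imputed") <- x$imputed
  scores
}
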