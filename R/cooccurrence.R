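#' Round a percentage the way co-occurrence ladders are reported
#'
#' Percentages of a chemical universe are conventionally printed to two
#' significant figures (36, 81, 45, 21, 11, 6.4), so 281/774 reports as 36
#' and 18/281 as 6.4.
#'
#' @param count Numerator count(s).
#' @param total Denominator (universe size).
#' @param digits Significant digits (default 2).
#' @return Numeric percentage(s) rounded to `digits` significant figures.
#' @export
signif_percent <- function(count, total, digits = 2) {
  stopifnot(total > 0)
  signif(100 * count / total, digits)
}

#' Summarize co-occurrence of male reproductive effect categories
#'
#' Counts, for each of the five effect categories, the chemicals positive
#' for that category (dose-independent, set semantics on chemical x
#' category), reports each count as a percentage of the positive universe
#' (chemicals positive for at least one category), tallies pairwise
#' co-occurrence, and ranks chemicals by association with the least common
#' category first, then the next, and so on -- the ordering used to display
#' the phenotypic hierarchy.
#'
#' @param records Endpoint record tibble.
#' @param universe Character vector of all screened chemicals; defaults to
#'   the chemicals present in `records`. Positivity percentages are always
#'   relative to the positive subset; `pct_positive_of_universe` relates the
#'   positive subset to this universe.
#' @param vocabulary Vocabulary tibble.
#' @return A list of class `cooccurrence_summary`: `counts` (tibble with
#'   `category`, `n_positive`, `pct_of_positive`), `pairwise` (category x
#'   category co-occurrence counts), `chemical_order` (tibble `chemical_id`,
#'   `rank`, per-category logicals), `n_universe`, `n_positive`,
#'   `pct_positive_of_universe`.
#' @export
cooccurrence_summary <- function(records, universe = NULL,
                                 vocabulary = default_endpoint_vocabulary()) {
  records <- validate_endpoint_records(records, vocabulary)
  if (is.null(universe)) universe <- unique(records$chemical_id)
  stopifnot(length(universe) > 0)
  cats <- all_categories()

  if (nrow(records)) {
    cls <- classify_endpoint(records$endpoint_term, records$study_type,
                             records$generation, vocabulary)
    pos_pairs <- dplyr::distinct(tibble::tibble(
      chemical_id = records$chemical_id, category = cls$category))
  } else {
    pos_pairs <- tibble::tibble(chemical_id = character(), category = character())
  }

  pos_chems <- sort(unique(pos_pairs$chemical_id))
  n_pos <- length(pos_chems)
  pos <- matrix(FALSE, nrow = n_pos, ncol = length(cats),
                dimnames = list(pos_chems, cats))
  if (nrow(pos_pairs)) pos[cbind(pos_pairs$chemical_id, pos_pairs$category)] <- TRUE

  counts <- colSums(pos)
  counts_tbl <- tibble::tibble(
    category = cats,
    n_positive = as.integer(counts[cats]),
    pct_of_positive = if (n_pos > 0) signif_percent(counts[cats], n_pos) else 0
  )

  pairwise <- if (n_pos > 0) crossprod(pos) else
    matrix(0L, length(cats), length(cats), dimnames = list(cats, cats))

  # least common category first; ties by the fixed category order
  cat_order <- cats[order(counts, seq_along(cats))]
  if (n_pos > 0) {
    keys <- lapply(cat_order, function(cc) -pos[, cc])
    ord <- do.call(order, c(keys, list(pos_chems)))
    chem_order <- tibble::tibble(chemical_id = pos_chems[ord],
                                 rank = seq_len(n_pos))
    chem_order <- dplyr::bind_cols(
      chem_order, tibble::as_tibble(pos[chem_order$chemical_id, , drop = FALSE]))
  } else {
    chem_order <- tibble::tibble(chemical_id = character(), rank = integer())
  }

  structure(list(
    counts = counts_tbl,
    pairwise = pairwise,
    chemical_order = chem_order,
    category_order = cat_order,
    n_universe = length(universe),
    n_positive = n_pos,
    pct_positive_of_universe = signif_percent(n_pos, length(universe))
  ), class = "cooccurrence_summary")
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat(sprintf("<cooccurrence_summary> %d of %d chemicals positive (%s%%)\n",
              x$n_positive, x$n_universe, format(x$pct_positive_of_universe)))
  print(x$counts)
  invisible(x)
}

#' Pearson concordance between two positive-chemical count profiles
#'
#' Measures agreement of per-subendpoint positive-chemical counts between
#' two strata (e.g. mouse vs rat test species, or parental P1 vs filial F1
#' generations) as the Pearson product-moment correlation.
#'
#' @param counts_a,counts_b Equal-length numeric vectors (length >= 3) of
#'   per-subendpoint positive counts.
#' @return The Pearson correlation coefficient.
#' @export
concordance_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("count vectors must have equal length", call. = FALSE)
  }
  if (length(counts_a) < 3) {
    stop("need at least 3 subendpoints for a concordance correlation", call. = FALSE)
  }
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) {
    stop("correlation undefined for a constant count vector", call. = FALSE)
  }
  stats::cor(counts_a, counts_b, method = "pearson")
}
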