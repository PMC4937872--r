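#' Published ToxRefDB positive-chemical counts for male reproductive effects
#'
#' The published summary table of positive-chemical counts (and mean cLELs,
#' mg/kg/day, where reported) per male reproductive subendpoint, stratified
#' by test species (rabbit, mouse, rat) and by generation evaluated (P1
#' parental, F1 filial), for the 248 chemicals with dosage information.
#' Shipped with the package as the input for cross-species and
#' cross-generation concordance statistics.
#'
#' @return A tibble; `level` distinguishes category summary rows,
#'   subendpoint rows and the grand total.
#' @export
#' @examples
#' counts <- toxref_effect_counts()
#' sub <- subset(counts, level == "subendpoint" &
#'                 category %in% c("sperm", "histology", "weight"))
#' concordance_correlation(sub$mouse, sub$rat)
toxref_effect_counts <- function() {
  path <- system.file("extdata", "toxref_male_repro_counts.csv",
                      package = "repromine", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}

#' Published co-occurrence counts of male reproductive effect categories
#'
#' Per-category positive-chemical counts underlying the co-occurrence
#' hierarchy: of 774 screened chemicals, 281 were positive for any male
#' reproductive effect; the ladder descends from relative weight change
#' (227) through histological effects (126), sperm effects (58), testicular
#' tumors (31) to malformations (18).
#'
#' @return A tibble with columns `category` and `n_positive`, including the
#'   `universe` and `any_male_repro_effect` rows.
#' @export
toxref_cooccurrence_counts <- function() {
  path <- system.file("extdata", "toxref_cooccurrence_counts.csv",
                      package = "repromine", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
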