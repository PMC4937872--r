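#' Read and validate animal-study endpoint records
#'
#' Reads a long-format endpoint table (one row per chemical x study x
#' endpoint observation) in the schema `chemical_id, study_id, study_type,
#' species, generation, endpoint_term, lel_mg_kg_day`. The LEL (lowest
#' effect level, mg/kg/day) may be missing when only presence/absence of the
#' effect is known. Validation failures report offending row numbers.
#'
#' @param path Path to a CSV or TSV file (delimiter inferred from extension).
#' @param vocabulary Optional vocabulary tibble used to check that every
#'   endpoint term resolves.
#' @return A validated tibble of endpoint records.
#' @export
read_endpoint_records <- function(path, vocabulary = NULL) {
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  records <- reader(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      chemical_id = readr::col_character(),
                      study_id = readr::col_character(),
                      study_type = readr::col_character(),
                      species = readr::col_character(),
                      generation = readr::col_character(),
                      endpoint_term = readr::col_character(),
                      lel_mg_kg_day = readr::col_double()
                    ))
  validate_endpoint_records(records, vocabulary)
}

#' Validate an endpoint record table
#'
#' Checks the schema, the controlled study-type/species/generation values,
#' positivity of LELs, and the prenatal-study generation constraint
#' (a prenatal developmental study evaluates fetuses, so its generation must
#' be F1 or none). Errors name the failing rows.
#'
#' @param records Tibble of endpoint records.
#' @param vocabulary Optional vocabulary tibble; when supplied, every
#'   `endpoint_term` must resolve in it.
#' @return The records, invisibly validated, as a tibble.
#' @export
validate_endpoint_records <- function(records, vocabulary = NULL) {
  need <- c("chemical_id", "study_id", "study_type", "species", "generation",
            "endpoint_term", "lel_mg_kg_day")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("endpoint records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) return(records)

  fail <- function(what, rows) {
    stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                 paste(head(rows, 10), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!records$study_type %in% STUDY_TYPES)
  if (length(bad)) fail("invalid study_type", bad)
  bad <- which(!records$species %in% SPECIES)
  if (length(bad)) fail("invalid species", bad)
  bad <- which(!records$generation %in% GENERATIONS)
  if (length(bad)) fail("invalid generation", bad)
  bad <- which(!is.na(records$lel_mg_kg_day) & records$lel_mg_kg_day <= 0)
  if (length(bad)) fail("LEL must be positive (mg/kg/day)", bad)
  bad <- which(records$study_type == "prenatal_developmental" &
                 !records$generation %in% c("F1", "none"))
  if (length(bad)) fail("prenatal developmental study with non-fetal generation", bad)
  if (!is.null(vocabulary)) {
    bad <- which(!records$endpoint_term %in% vocabulary$endpoint_term)
    if (length(bad)) fail("endpoint term not in vocabulary", bad)
  }
  records
}
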