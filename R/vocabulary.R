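#' Built-in male reproductive endpoint vocabulary
#'
#' The 23 controlled endpoint terms used to mine animal-study tables for
#' male reproductive effects, classified into five categories:
#' malformations (hypospadias, nipple retention, decreased anogenital
#' distance, cryptorchidism), testicular tumors (mesothelioma, adenoma,
#' interstitial cell tumor, other), sperm effects (morphology, motility,
#' testicular spermatid count, epididymal sperm count, semen sperm count),
#' histological effects (prostate, seminal vesicle, epididymis and testis,
#' the latter two split into general and spermatogenesis-specific findings),
#' and relative weight change in male reproductive organs.
#'
#' @return A tibble with columns `endpoint_term`, `category`, `subendpoint`.
#' @export
default_endpoint_vocabulary <- function() {
  vocab <- tibble::tribble(
    ~endpoint_term,                           ~category,      ~subendpoint,
    "hypospadias",                            "malformation", "hypospadias",
    "nipple retention",                       "malformation", "nipple retention",
    "decreased anogenital distance",          "malformation", "decreased anogenital distance",
    "cryptorchidism",                         "malformation", "cryptorchidism",
    "testicular mesothelioma",                "tumor",        "mesothelioma",
    "testicular adenoma",                     "tumor",        "adenoma",
    "interstitial cell tumor",                "tumor",        "interstitial cell tumor",
    "testicular tumor other",                 "tumor",        "other",
    "sperm morphology",                       "sperm",        "morphology",
    "sperm motility",                         "sperm",        "motility",
    "testicular spermatid count",             "sperm",        "testicular spermatid count",
    "epididymal sperm count",                 "sperm",        "epididymal sperm count",
    "semen sperm count",                      "sperm",        "semen sperm count",
    "prostate histology",                     "histology",    "prostate",
    "seminal vesicle histology",              "histology",    "seminal vesicle",
    "epididymis histology",                   "histology",    "epididymis",
    "epididymis spermatogenic histology",     "histology",    "epididymis (spermatogenesis-specific)",
    "testis histology",                       "histology",    "testis",
    "testis spermatogenic histology",         "histology",    "testis (spermatogenesis-specific)",
    "prostate relative weight",               "weight",       "prostate",
    "seminal vesicle relative weight",        "weight",       "seminal vesicle",
    "epididymis relative weight",             "weight",       "epididymis",
    "testis relative weight",                 "weight",       "testis"
  )
  validate_endpoint_vocabulary(vocab)
}

#' Read an endpoint vocabulary from CSV
#'
#' Expects columns `endpoint_term`, `category`, `subendpoint`; categories
#' must be among [all_categories()] and terms must be unique.
#'
#' @param path Path to a CSV file.
#' @return A validated vocabulary tibble.
#' @export
read_endpoint_vocabulary <- function(path) {
  vocab <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  validate_endpoint_vocabulary(vocab)
}

validate_endpoint_vocabulary <- function(vocab) {
  need <- c("endpoint_term", "category", "subendpoint")
  miss <- setdiff(need, names(vocab))
  if (length(miss)) {
    stop("endpoint vocabulary is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(vocab$category), ALL_CATEGORIES)
  if (length(bad)) {
    stop("unknown endpoint categories: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(vocab$endpoint_term)) {
    stop("duplicated endpoint terms in vocabulary", call. = FALSE)
  }
  # subendpoints are identified within their category (organ names like
  # "prostate" recur under histology and weight); the pair must be unique
  amb <- paste(vocab$category, vocab$subendpoint, sep = "\r")
  if (anyDuplicated(amb)) {
    stop("duplicated (category, subendpoint) pair in vocabulary", call. = FALSE)
  }
  tibble::as_tibble(vocab[, need])
}

#' Classify endpoint terms and their exposure context
#'
#' Resolves each endpoint term to its effect category and decides whether
#' the observation arises from a developmental exposure context: a prenatal
#' developmental or generational (one- or multigeneration) study type, or an
#' F-generation evaluation. Sperm, histology and weight findings from
#' adult-only subchronic/chronic studies are nondevelopmental and therefore
#' never confer MRDT credit.
#'
#' @param term Character vector of endpoint terms.
#' @param study_type Character vector (recycled) of study types, one of
#'   prenatal_developmental, one_generation, multigeneration, subchronic,
#'   chronic.
#' @param generation Character vector (recycled); one of P1, F1, F2, F3, none.
#' @param vocabulary Vocabulary tibble; defaults to the built-in 23 terms.
#' @return A tibble with columns `category`, `subendpoint`,
#'   `is_developmental`.
#' @export
#' @examples
#' classify_endpoint("hypospadias", "prenatal_developmental", "F1")
#' classify_endpoint("testis relative weight", "chronic", "none")
classify_endpoint <- function(term, study_type, generation = "none",
                              vocabulary = default_endpoint_vocabulary()) {
  n <- max(length(term), length(study_type), length(generation))
  term <- rep_len(term, n)
  study_type <- rep_len(study_type, n)
  generation <- rep_len(generation, n)

  idx <- match(term, vocabulary$endpoint_term)
  if (anyNA(idx)) {
    bad <- unique(term[is.na(idx)])
    stop("endpoint term(s) not in vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad_st <- setdiff(unique(study_type), STUDY_TYPES)
  if (length(bad_st)) {
    stop("unknown study type(s): ", paste(bad_st, collapse = ", "), call. = FALSE)
  }
  bad_gen <- setdiff(unique(generation), GENERATIONS)
  if (length(bad_gen)) {
    stop("unknown generation(s): ", paste(bad_gen, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    category = vocabulary$category[idx],
    subendpoint = vocabulary$subendpoint[idx],
    is_developmental = study_type %in% DEV_STUDY_TYPES |
      generation %in% c("F1", "F2", "F3")
  )
}
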