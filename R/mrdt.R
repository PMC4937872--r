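#' Flag chemicals for male reproductive developmental toxicity (MRDT)
#'
#' A chemical is MRDT when it produces any male reproductive malformation,
#' or when a sperm, histological, or tissue-weight effect is reported
#' exclusively in developmental studies: an effect seen in a developmental
#' context (prenatal/generational study type or F-generation evaluation)
#' that is also seen in a nondevelopmental study for the same chemical does
#' not count. Testicular tumors never confer MRDT. Positivity is
#' dose-independent.
#'
#' @param records Endpoint record tibble.
#' @param vocabulary Vocabulary tibble.
#' @return A tibble with one row per chemical: `chemical_id`, `is_mrdt`,
#'   `via_malformation`, per-category developmental-exclusivity flags
#'   (`sperm_dev_only`, `histology_dev_only`, `weight_dev_only`) and
#'   `source` (`"toxref"`).
#' @export
flag_mrdt <- function(records, vocabulary = default_endpoint_vocabulary()) {
  records <- validate_endpoint_records(records, vocabulary)
  chemicals <- sort(unique(records$chemical_id))
  if (length(chemicals) == 0L) {
    return(tibble::tibble(chemical_id = character(), is_mrdt = logical(),
                          via_malformation = logical(), sperm_dev_only = logical(),
                          histology_dev_only = logical(), weight_dev_only = logical(),
                          source = character()))
  }
  cls <- classify_endpoint(records$endpoint_term, records$study_type,
                           records$generation, vocabulary)
  obs <- dplyr::distinct(tibble::tibble(
    chemical_id = records$chemical_id,
    category = cls$category,
    is_developmental = cls$is_developmental
  ))

  seen <- function(cat, dev) {
    chemicals %in% obs$chemical_id[obs$category == cat & obs$is_developmental == dev]
  }
  dev_only <- function(cat) seen(cat, TRUE) & !seen(cat, FALSE)

  malform <- chemicals %in% obs$chemical_id[obs$category == "malformation"]
  sperm_x <- dev_only("sperm")
  histo_x <- dev_only("histology")
  weight_x <- dev_only("weight")

  tibble::tibble(
    chemical_id = chemicals,
    is_mrdt = malform | sperm_x | histo_x | weight_x,
    via_malformation = malform,
    sperm_dev_only = sperm_x,
    histology_dev_only = histo_x,
    weight_dev_only = weight_x,
    source = "toxref"
  )
}

#' Merge literature-derived MRDT flags into database-derived flags
#'
#' Literature curation (e.g. a PubMed/MeSH search for cryptorchidism,
#' hypospadias, urogenital abnormalities) can identify developmental
#' toxicants missed by the animal-study database. The merge takes the union
#' of flags and records each positive chemical's provenance as `"toxref"`,
#' `"literature"`, or `"both"`. Literature chemicals outside the supplied
#' chemical universe raise a warning (not an error) and are appended.
#'
#' @param flags MRDT flag tibble from [flag_mrdt()].
#' @param literature Tibble with columns `chemical_id` and logical `is_mrdt`
#'   (rows with `is_mrdt = FALSE` are ignored), or a character vector of
#'   flagged chemical identifiers.
#' @param universe Character vector of known chemicals; defaults to the
#'   chemicals in `flags`.
#' @return The merged flag tibble, with attributes `n_before` (positives in
#'   `flags`), `n_added` (novel literature positives) and `n_after`.
#' @export
merge_literature_flags <- function(flags, literature,
                                   universe = flags$chemical_id) {
  if (is.character(literature)) {
    literature <- tibble::tibble(chemical_id = literature, is_mrdt = TRUE)
  }
  lit_pos <- unique(literature$chemical_id[literature$is_mrdt])
  unknown <- setdiff(lit_pos, universe)
  if (length(unknown)) {
    warning("literature chemical(s) not in the chemical universe: ",
            paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  out <- flags
  missing_rows <- setdiff(lit_pos, out$chemical_id)
  if (length(missing_rows)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      chemical_id = missing_rows, is_mrdt = FALSE, via_malformation = FALSE,
      sperm_dev_only = FALSE, histology_dev_only = FALSE,
      weight_dev_only = FALSE, source = NA_character_))
  }
  was_mrdt <- out$is_mrdt
  in_lit <- out$chemical_id %in% lit_pos
  out$is_mrdt <- was_mrdt | in_lit
  out$source <- dplyr::case_when(
    was_mrdt & in_lit ~ "both",
    was_mrdt ~ "toxref",
    in_lit ~ "literature",
    TRUE ~ NA_character_
  )
  attr(out, "n_before") <- sum(was_mrdt)
  attr(out, "n_added") <- sum(in_lit & !was_mrdt)
  attr(out, "n_after") <- sum(out$is_mrdt)
  out
}
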