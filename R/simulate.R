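#' Configuration for the in vivo syndrome simulator
#'
#' Describes the generative model for synthetic animal-study endpoint
#' tables: a positivity ladder over the five effect categories (defaults
#' mimic the observed co-occurrence hierarchy, where relative weight change
#' is the broadest response at ~80% of positive chemicals and malformations
#' the narrowest at ~6%), a nesting coefficient (the probability that a
#' chemical's category positives form a perfect hierarchy, so a rarer
#' effect implies all commoner ones), per-category log-normal LEL
#' distributions (log10 mg/kg/day), species LEL multipliers, and the
#' developmental/nondevelopmental exposure-context mix that determines
#' which chemicals are true MRDT.
#'
#' @param n_chemicals Number of chemicals to simulate.
#' @param positivity Named probabilities for weight, histology, sperm,
#'   tumor, malformation; must be weakly decreasing in that order.
#' @param nesting Nesting coefficient in \[0, 1\].
#' @param lel_log10_mean,lel_log10_sd Per-category log10-normal LEL
#'   parameters (sd recycled).
#' @param species_multiplier LEL multipliers for non-defining records by
#'   species (>= 1 keeps the defining record the category minimum).
#' @param context_probs Probabilities that a positive sperm/histology/
#'   weight category is observed in developmental studies only, in
#'   nondevelopmental studies only, or in both. Malformations are always
#'   developmental; tumors always nondevelopmental.
#' @param seed Integer seed embedded in the config.
#' @return A list of class `syndrome_sim_config`.
#' @export
syndrome_sim_config <- function(
    n_chemicals = 500L,
    positivity = c(weight = 0.8, histology = 0.45, sperm = 0.2,
                   tumor = 0.1, malformation = 0.06),
    nesting = 0.9,
    lel_log10_mean = c(malformation = 2.0, tumor = 1.5, sperm = 1.7,
                       histology = 1.6, weight = 1.7),
    lel_log10_sd = 0.5,
    species_multiplier = c(rat = 1, mouse = 2.4, rabbit = 1.6),
    context_probs = c(dev_only = 0.3, nondev_only = 0.5, both = 0.2),
    seed = 1L) {
  need <- c("weight", "histology", "sperm", "tumor", "malformation")
  if (!all(need %in% names(positivity))) {
    stop("positivity must name all five categories", call. = FALSE)
  }
  p <- positivity[need]
  if (any(p < 0 | p > 1)) stop("positivity probabilities must lie in [0,1]", call. = FALSE)
  if (is.unsorted(rev(p))) {
    stop("positivity must be weakly decreasing: weight >= histology >= sperm >= tumor >= malformation",
         call. = FALSE)
  }
  if (nesting < 0 || nesting > 1) stop("nesting must lie in [0,1]", call. = FALSE)
  if (any(species_multiplier <= 0)) stop("species multipliers must be positive", call. = FALSE)
  cp <- context_probs / sum(context_probs)
  structure(list(
    n_chemicals = as.integer(n_chemicals), positivity = p, nesting = nesting,
    lel_log10_mean = lel_log10_mean,
    lel_log10_sd = rep_len(lel_log10_sd, length(lel_log10_mean)),
    species_multiplier = species_multiplier, context_probs = cp,
    seed = as.integer(seed)), class = "syndrome_sim_config")
}

#' Simulate an animal-study endpoint table with planted truth
#'
#' Draws each chemical's category positives either from a single shared
#' uniform (perfectly nested under the ladder probabilities) with
#' probability equal to the nesting coefficient, or independently per
#' category -- so the marginal positivity of every category equals the
#' configured ladder exactly, while the fraction of perfectly hierarchical
#' chemicals is tunable. Each positive category receives a true cLEL drawn
#' log-normally and an exposure context (developmental-only,
#' nondevelopmental-only, or both); endpoint records realize these
#' assignments, with the defining record carrying the true cLEL exactly
#' and satellite records at equal or higher doses. A chemical is true MRDT
#' when it has a malformation or a developmental-only sperm/histology/
#' weight category.
#'
#' @param config A [syndrome_sim_config()].
#' @return A list: `records` (endpoint record tibble in the reader schema),
#'   `truth` (tibble with one row per chemical: per-category positivity,
#'   context, true cLELs and `is_mrdt`), `config`.
#' @export
simulate_invivo <- function(config = syndrome_sim_config()) {
  stopifnot(inherits(config, "syndrome_sim_config"))
  n <- config$n_chemicals
  cats_rare_first <- c("malformation", "tumor", "sperm", "histology", "weight")
  p <- config$positivity[cats_rare_first]

  with_preserved_seed(config$seed, {
    chem <- sprintf("chem_%04d", seq_len(n))
    nested <- runif(n) < config$nesting
    u_shared <- runif(n)
    pos <- matrix(FALSE, n, 5, dimnames = list(chem, cats_rare_first))
    for (j in seq_len(5)) {
      u <- ifelse(nested, u_shared, runif(n))
      pos[, j] <- u < p[j]
    }

    ctx <- matrix(NA_character_, n, 5, dimnames = list(chem, cats_rare_first))
    ctx[pos[, "malformation"], "malformation"] <- "dev_only"
    ctx[pos[, "tumor"], "tumor"] <- "nondev_only"
    for (cc in c("sperm", "histology", "weight")) {
      k <- sum(pos[, cc])
      if (k) ctx[pos[, cc], cc] <- sample(names(config$context_probs), k,
                                          replace = TRUE,
                                          prob = config$context_probs)
    }

    clel <- matrix(NA_real_, n, 5, dimnames = list(chem, cats_rare_first))
    for (cc in cats_rare_first) {
      k <- sum(pos[, cc])
      if (k) clel[pos[, cc], cc] <-
          10^rnorm(k, config$lel_log10_mean[[cc]],
                   config$lel_log10_sd[[match(cc, names(config$lel_log10_mean))]])
    }

    vocab <- default_endpoint_vocabulary()
    recs <- vector("list", 0L)
    for (i in seq_len(n)) {
      for (cc in cats_rare_first) {
        if (!pos[i, cc]) next
        context <- ctx[i, cc]
        terms <- vocab$endpoint_term[vocab$category == cc]
        term1 <- sample(terms, 1L)
        dev_rec <- function(term, lel, species = "rat") {
          st <- if (cc == "malformation") "prenatal_developmental" else "multigeneration"
          tibble::tibble(chemical_id = chem[i],
                         study_id = paste(chem[i], st, sep = "-"),
                         study_type = st, species = species, generation = "F1",
                         endpoint_term = term, lel_mg_kg_day = lel)
        }
        nondev_rec <- function(term, lel, species = "rat") {
          tibble::tibble(chemical_id = chem[i],
                         study_id = paste(chem[i], "chronic", sep = "-"),
                         study_type = "chronic", species = species,
                         generation = "none", endpoint_term = term,
                         lel_mg_kg_day = lel)
        }
        base <- clel[i, cc]
        primary <- if (context %in% c("dev_only", "both")) dev_rec else nondev_rec
        out <- list(primary(term1, base))
        if (context == "both") {
          # realize the nondevelopmental observation as well, at >= the cLEL
          lel_nd <- base * 10^abs(rnorm(1, 0, 0.3))
          out[[length(out) + 1L]] <- nondev_rec(sample(terms, 1L), lel_nd)
        }
        # satellite record at an equal-or-higher dose, possibly another species
        if (runif(1) < 0.5) {
          sp <- sample(names(config$species_multiplier), 1L,
                       prob = c(0.7, 0.25, 0.05))
          lel2 <- base * config$species_multiplier[[sp]] * 10^abs(rnorm(1, 0, 0.3))
          secondary <- if (context == "dev_only") dev_rec else nondev_rec
          out[[length(out) + 1L]] <- secondary(sample(terms, 1L), lel2, sp)
        }
        recs[[length(recs) + 1L]] <- dplyr::bind_rows(out)
      }
    }
    records <- if (length(recs)) dplyr::bind_rows(recs) else
      tibble::tibble(chemical_id = character(), study_id = character(),
                     study_type = character(), species = character(),
                     generation = character(), endpoint_term = character(),
                     lel_mg_kg_day = numeric())

    dev_excl <- matrix(FALSE, n, 3,
                       dimnames = list(chem, c("sperm", "histology", "weight")))
    for (cc in colnames(dev_excl)) dev_excl[, cc] <-
      pos[, cc] & !is.na(ctx[, cc]) & ctx[, cc] == "dev_only"
    col <- function(m, cc) unname(m[, cc])
    truth <- tibble::tibble(
      chemical_id = chem,
      malformation = col(pos, "malformation"), tumor = col(pos, "tumor"),
      sperm = col(pos, "sperm"), histology = col(pos, "histology"),
      weight = col(pos, "weight"),
      sperm_context = col(ctx, "sperm"),
      histology_context = col(ctx, "histology"),
      weight_context = col(ctx, "weight"),
      clel_malformation = col(clel, "malformation"),
      clel_tumor = col(clel, "tumor"), clel_sperm = col(clel, "sperm"),
      clel_histology = col(clel, "histology"),
      clel_weight = col(clel, "weight"),
      is_mrdt = col(pos, "malformation") | unname(rowSums(dev_excl) > 0)
    )
    list(records = records, truth = truth, config = config)
  })
}

#' Configuration for the in vitro assay-universe simulator
#'
#' Describes a synthetic high-throughput screening universe: target assays
#' mapped to genes plus a cytotoxicity panel (default 37 assays, matching
#' the size of the cytotoxicity/cell-loss feature collection used to locate
#' the burst). Each cytotoxic chemical gets a log-normal cytotoxicity AC50
#' around which its cytotoxicity-panel responses and any burst-driven
#' target responses cluster; planted selective chemical-gene pairs respond
#' at AC50s a fixed log10 offset (default 2 decades) below the chemical's
#' cytotoxicity. All series share one ascending half-log concentration
#' grid.
#'
#' @param n_chemicals,n_genes,assays_per_gene Universe dimensions.
#' @param n_cytotox_assays Cytotoxicity-panel size (default 37).
#' @param frac_selective Fraction of chemical x gene pairs planted as
#'   selectively bioactive.
#' @param selective_offset log10 decades separating selective AC50s from
#'   the chemical's cytotoxicity AC50 (default 2).
#' @param selective_jitter log10 SD of per-assay jitter on selective AC50s.
#' @param cytotox_log10ac50_mean,cytotox_log10ac50_sd Population
#'   distribution of chemical cytotoxicity AC50s (log10 uM).
#' @param cytotox_spread Within-chemical log10 SD of cytotoxicity-panel
#'   AC50s around the chemical's burst location.
#' @param frac_noncytotox Fraction of chemicals with no cytotoxicity in the
#'   tested range (their cytotoxicity panel stays flat).
#' @param burst_fraction Fraction of non-selective chemical x gene pairs
#'   that respond nonspecifically at the cytotoxicity AC50.
#' @param top_mean,top_sd Response amplitude distribution (0-100 scale).
#' @param hill_slope True Hill slope of planted curves.
#' @param response_sd Gaussian response noise SD (response units).
#' @param conc_grid Shared ascending concentration grid (uM); default 8
#'   half-log steps 0.01-31.6 uM.
#' @param seed Integer seed embedded in the config.
#' @return A list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(
    n_chemicals = 50L, n_genes = 20L, assays_per_gene = 2L,
    n_cytotox_assays = 37L,
    frac_selective = 0.1, selective_offset = 2, selective_jitter = 0.1,
    cytotox_log10ac50_mean = 1.0, cytotox_log10ac50_sd = 0.3,
    cytotox_spread = 0.2, frac_noncytotox = 0.1, burst_fraction = 0.2,
    top_mean = 80, top_sd = 10, hill_slope = 1, response_sd = 5,
    conc_grid = 10^seq(-2, 1.5, by = 0.5), seed = 1L) {
  if (is.unsorted(conc_grid, strictly = TRUE) || any(conc_grid <= 0)) {
    stop("conc_grid must be strictly ascending and positive", call. = FALSE)
  }
  if (selective_offset < 0 || response_sd < 0) {
    stop("selective_offset and response_sd must be >= 0", call. = FALSE)
  }
  structure(list(
    n_chemicals = as.integer(n_chemicals), n_genes = as.integer(n_genes),
    assays_per_gene = as.integer(assays_per_gene),
    n_cytotox_assays = as.integer(n_cytotox_assays),
    frac_selective = frac_selective, selective_offset = selective_offset,
    selective_jitter = selective_jitter,
    cytotox_log10ac50_mean = cytotox_log10ac50_mean,
    cytotox_log10ac50_sd = cytotox_log10ac50_sd,
    cytotox_spread = cytotox_spread, frac_noncytotox = frac_noncytotox,
    burst_fraction = burst_fraction, top_mean = top_mean, top_sd = top_sd,
    hill_slope = hill_slope, response_sd = response_sd,
    conc_grid = conc_grid, seed = as.integer(seed)),
    class = "assay_sim_config")
}

#' Simulate a concentration-response assay universe with planted truth
#'
#' @param config An [assay_sim_config()].
#' @return A list: `series` (long tibble `chemical_id`, `assay_id`, `conc`,
#'   `response`), `assay_map` (`assay_id`, `gene_symbol`, `is_cytotox`),
#'   `truth` (list of `chemicals`: per-chemical cytotoxicity AC50 and flag;
#'   `pairs`: per chemical x gene selectivity/burst labels; `assays`: per
#'   chemical x assay true kind, AC50 and amplitude), `config`.
#' @export
simulate_assays <- function(config = assay_sim_config()) {
  stopifnot(inherits(config, "assay_sim_config"))
  with_preserved_seed(config$seed, {
    chem <- sprintf("chem_%04d", seq_len(config$n_chemicals))
    genes <- sprintf("GENE%02d", seq_len(config$n_genes))
    target_assays <- tibble::tibble(
      assay_id = unlist(lapply(genes, function(g)
        sprintf("ATG_%s_%d", g, seq_len(config$assays_per_gene)))),
      gene_symbol = rep(genes, each = config$assays_per_gene),
      is_cytotox = FALSE)
    ctx_assays <- tibble::tibble(
      assay_id = sprintf("CTX_%03d", seq_len(config$n_cytotox_assays)),
      gene_symbol = NA_character_, is_cytotox = TRUE)
    assay_map <- dplyr::bind_rows(target_assays, ctx_assays)

    chem_truth <- tibble::tibble(
      chemical_id = chem,
      log10_cytotox_ac50 = rnorm(length(chem), config$cytotox_log10ac50_mean,
                                 config$cytotox_log10ac50_sd),
      is_cytotoxic = runif(length(chem)) >= config$frac_noncytotox)

    pairs <- tidyr::expand_grid(chemical_id = chem, gene_symbol = genes)
    pairs$is_selective <- runif(nrow(pairs)) < config$frac_selective
    pairs$is_burst <- !pairs$is_selective &
      runif(nrow(pairs)) < config$burst_fraction
    # burst responses require actual cytotoxicity in range
    pairs$is_burst <- pairs$is_burst &
      chem_truth$is_cytotoxic[match(pairs$chemical_id, chem_truth$chemical_id)]

    draw_top <- function(k) pmin(pmax(rnorm(k, config$top_mean, config$top_sd), 30), 100)

    all_assay <- tidyr::expand_grid(chemical_id = chem,
                                    assay_id = assay_map$assay_id)
    all_assay <- dplyr::left_join(all_assay, assay_map, by = "assay_id")
    all_assay <- dplyr::left_join(all_assay, chem_truth, by = "chemical_id")
    all_assay <- dplyr::left_join(
      all_assay, pairs, by = c("chemical_id", "gene_symbol"))

    kind <- ifelse(all_assay$is_cytotox & all_assay$is_cytotoxic, "cytotox",
            ifelse(!all_assay$is_cytotox & !is.na(all_assay$is_selective) &
                     all_assay$is_selective, "selective",
            ifelse(!all_assay$is_cytotox & !is.na(all_assay$is_burst) &
                     all_assay$is_burst, "burst", "flat")))
    n_a <- nrow(all_assay)
    la <- rep(NA_real_, n_a)
    la[kind == "cytotox"] <- all_assay$log10_cytotox_ac50[kind == "cytotox"] +
      rnorm(sum(kind == "cytotox"), 0, config$cytotox_spread)
    la[kind == "selective"] <- all_assay$log10_cytotox_ac50[kind == "selective"] -
      config$selective_offset +
      rnorm(sum(kind == "selective"), 0, config$selective_jitter)
    la[kind == "burst"] <- all_assay$log10_cytotox_ac50[kind == "burst"] +
      rnorm(sum(kind == "burst"), 0, config$cytotox_spread)
    top <- rep(0, n_a)
    top[kind != "flat"] <- draw_top(sum(kind != "flat"))

    assays_truth <- tibble::tibble(
      chemical_id = all_assay$chemical_id, assay_id = all_assay$assay_id,
      kind = kind, true_log10_ac50 = la, true_top = top)

    nc <- length(config$conc_grid)
    series <- tidyr::expand_grid(
      idx = seq_len(n_a), conc_i = seq_len(nc))
    series$chemical_id <- assays_truth$chemical_id[series$idx]
    series$assay_id <- assays_truth$assay_id[series$idx]
    series$conc <- config$conc_grid[series$conc_i]
    mu <- numeric(nrow(series))
    active <- kind[series$idx] != "flat"
    mu[active] <- hill_response(series$conc[active], top[series$idx][active],
                                la[series$idx][active], config$hill_slope)
    series$response <- mu + rnorm(nrow(series), 0, config$response_sd)
    series <- series[, c("chemical_id", "assay_id", "conc", "response")]

    list(series = series, assay_map = assay_map,
         truth = list(chemicals = chem_truth, pairs = pairs,
                      assays = assays_truth),
         config = config)
  })
}
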