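test_that("perfect nesting makes rarer effects imply all commoner effects", {
  sv <- simulate_invivo(syndrome_sim_config(n_chemicals = 400, nesting = 1,
                                            seed = 19))
  tr <- sv$truth
  malform <- tr[tr$malformation, ]
  expect_gt(nrow(malform), 0)
  expect_true(all(malform$tumor & malform$sperm & malform$histology &
                    malform$weight))
  # the hierarchy holds at every rung under full nesting
  expect_true(all(!tr$tumor | tr$sperm))
  expect_true(all(!tr$sperm | tr$histology))
  expect_true(all(!tr$histology | tr$weight))
})

test_that("category frequencies track the configured ladder", {
  cfg <- syndrome_sim_config(n_chemicals = 1000, seed = 77)
  sv <- simulate_invivo(cfg)
  p <- cfg$positivity
  freq <- colMeans(sv$truth[, names(p)])
  se <- sqrt(p * (1 - p) / cfg$n_chemicals)
  expect_true(all(abs(freq - p) <= 3 * se),
              info = paste(round(freq, 3), collapse = ", "))
})

test_that("the in vivo generator is reproducible and schema-valid", {
  cfg <- syndrome_sim_config(n_chemicals = 60, seed = 5)
  a <- simulate_invivo(cfg)
  b <- simulate_invivo(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  # generated tables pass the same validation the readers enforce
  expect_silent(validate_endpoint_records(a$records,
                                          default_endpoint_vocabulary()))
  # planted cLELs are exactly recoverable: the defining record is the minimum
  m <- aggregate_clel(a$records)
  tr <- a$truth
  for (cc in mrdt_categories()) {
    planted <- tr[[paste0("clel_", cc)]]
    idx <- tr$chemical_id %in% rownames(m$clel) & !is.na(planted)
    got <- m$clel[tr$chemical_id[idx], cc]
    expect_equal(unname(got), planted[idx], tolerance = 1e-12)
  }
})

test_that("invalid ladder configurations are rejected", {
  expect_error(syndrome_sim_config(positivity = c(weight = 0.2, histology = 0.45,
                                                  sperm = 0.2, tumor = 0.1,
                                                  malformation = 0.06)),
               "decreasing")
  expect_error(syndrome_sim_config(nesting = 1.2), "nesting")
})

test_that("noiseless selective pairs are recovered to within 1% in AC50", {
  cfg <- assay_sim_config(n_chemicals = 5, n_genes = 3, assays_per_gene = 1,
                          n_cytotox_assays = 5, frac_selective = 0.4,
                          response_sd = 0, frac_noncytotox = 0, seed = 101)
  sa <- simulate_assays(cfg)
  hits <- call_hits_table(sa$series)
  active <- sa$truth$assays[sa$truth$assays$kind != "flat", ]
  j <- dplyr::inner_join(hits, active, by = c("chemical_id", "assay_id"))
  # curves must reach their plateau inside the tested range to be fully
  # identifiable (the amplitude bound is 1.2x the observed maximum);
  # boundary curves may legitimately miss the threshold or carry AC50 bias
  in_range <- j$true_log10_ac50 > log10(min(cfg$conc_grid)) + 0.5 &
    j$true_log10_ac50 < log10(max(cfg$conc_grid)) - 0.8
  expect_gt(sum(in_range), 0)
  expect_true(all(j$is_hit[in_range]))
  rel <- abs(10^j$log10_ac50 - 10^j$true_log10_ac50) / 10^j$true_log10_ac50
  expect_lt(max(rel[in_range]), 0.01)
})

test_that("removing the selectivity offset centers selective Z near zero", {
  cfg <- assay_sim_config(n_chemicals = 12, n_genes = 4, assays_per_gene = 1,
                          n_cytotox_assays = 12, frac_selective = 0.3,
                          selective_offset = 0, response_sd = 1,
                          frac_noncytotox = 0, seed = 55)
  sa <- simulate_assays(cfg)
  hits <- call_hits_table(sa$series)
  summ <- cytotox_summaries(hits, sa$assay_map)
  gs <- gene_scores(hits, summ, global_mad(summ), sa$assay_map)$scores
  sel <- dplyr::semi_join(gs,
                          sa$truth$pairs[sa$truth$pairs$is_selective, ],
                          by = c("chemical_id", "gene_symbol"))
  expect_gt(nrow(sel), 0)
  # potency at the cytotoxic concentration: Z in MAD units stays small
  expect_true(abs(median(sel$G)) <= 1)
})

test_that("the assay generator is reproducible and grid-consistent", {
  cfg <- assay_sim_config(n_chemicals = 4, n_genes = 2, seed = 9)
  a <- simulate_assays(cfg)
  b <- simulate_assays(cfg)
  expect_identical(a$series, b$series)
  expect_equal(nrow(a$assay_map),
               cfg$n_genes * cfg$assays_per_gene + cfg$n_cytotox_assays)
  expect_equal(sum(a$assay_map$is_cytotox), cfg$n_cytotox_assays)
  one <- a$series[a$series$assay_id == a$assay_map$assay_id[1] &
                    a$series$chemical_id == "chem_0001", ]
  expect_equal(one$conc, cfg$conc_grid)
})

test_that("recovery metrics behave at the extremes", {
  labels <- c(rep(TRUE, 20), rep(FALSE, 80))
  perfect <- c(runif(20, 1, 2), runif(80, -2, 0))
  expect_equal(auroc(perfect, labels), 1.0)

  set.seed(33)
  n1 <- 200; n0 <- 800
  rnd <- auroc(rnorm(n1 + n0), sample(c(rep(TRUE, n1), rep(FALSE, n0))))
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(rnd - 0.5), 3 * se)

  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("evaluate_recovery rejects mismatched identifiers", {
  sa <- simulate_assays(assay_sim_config(n_chemicals = 3, n_genes = 2,
                                         n_cytotox_assays = 4, seed = 2))
  bogus <- tibble::tibble(chemical_id = "nope", gene_symbol = "nope", G = 1)
  expect_error(evaluate_recovery(sa$truth, scores = bogus), "match")
})
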