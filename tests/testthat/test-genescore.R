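test_that("cytotoxicity summaries follow the median/MAD definitions", {
  s <- cytotox_summary(numeric(0))
  expect_equal(s$m, 3)
  expect_true(is.na(s$mad))
  s1 <- cytotox_summary(1.7)
  expect_equal(s1$m, 3)
  expect_true(is.na(s1$mad))

  s2 <- cytotox_summary(c(0, 1, 2))
  expect_equal(s2$m, 1)
  expect_equal(s2$mad, 1)

  # even-sized set: median of the two middle values, raw MAD
  x <- c(0.5, 1.0, 1.1, 3.0)
  s3 <- cytotox_summary(x)
  expect_equal(s3$m, 1.05)
  expect_equal(s3$mad, median(abs(x - 1.05)))
  expect_equal(s3$mad, 0.3)
})

test_that("M_global is the median over chemicals with a defined MAD", {
  tb <- tibble::tibble(mad = c(0.2, 0.5, 0.9))
  expect_equal(global_mad(tb), 0.5)
  expect_equal(global_mad(tibble::tibble(mad = 0.3)), 0.3)
  mixed <- tibble::tibble(mad = c(NA, 0.2, NA, 0.8, 0.4))
  expect_equal(global_mad(mixed), median(c(0.2, 0.8, 0.4)))
  expect_error(global_mad(tibble::tibble(mad = NA_real_)), "undefined")
})

test_that("the Z-score measures distance below the cytotoxicity burst", {
  expect_equal(z_score(0, m = 3, m_global = 0.5), 6)
  expect_equal(z_score(2.2, m = 2.2, m_global = 0.7), 0)
  expect_error(z_score(NA_real_, 3, 0.5), "hit")
  expect_error(z_score(1, 3, 0), "positive")

  # vectorized evaluation matches the scalar formula elementwise
  set.seed(8)
  la <- rnorm(50); m <- rnorm(50, 2); mg <- 0.4
  zv <- z_score(la, m, mg)
  for (i in seq_along(la)) expect_equal(zv[i], (m[i] - la[i]) / mg)
})

test_that("Z is invariant under a potency shift of the whole chemical", {
  set.seed(12)
  for (k in 1:25) {
    ctx <- rnorm(7, 1, 0.3)
    target <- rnorm(1, -1)
    shift <- runif(1, -2, 2)
    s0 <- cytotox_summary(ctx); s1 <- cytotox_summary(ctx + shift)
    expect_equal(s1$mad, s0$mad, tolerance = 1e-12)
    z0 <- z_score(target, s0$m, 0.25)
    z1 <- z_score(target + shift, s1$m, 0.25)
    expect_equal(z1, z0, tolerance = 1e-9)
  }
})

make_hits <- function(...) {
  df <- tibble::tribble(...)
  df$is_hit <- !is.na(df$log10_ac50)
  df$model <- ifelse(df$is_hit, "hill", "constant")
  df$max_modeled_response <- ifelse(df$is_hit, 80, 0)
  df
}

amap <- tibble::tibble(
  assay_id = c("a1", "a2", "a3", "a4", "a5", "ctx1", "ctx2"),
  gene_symbol = c("ESR1", "ESR1", "AR", "AR", "AR", NA, NA),
  is_cytotox = c(rep(FALSE, 5), TRUE, TRUE))

test_that("gene scores aggregate hit-assay Z values per gene", {
  hits <- make_hits(
    ~chemical_id, ~assay_id, ~log10_ac50,
    "c1", "a1", 1.0,
    "c1", "a2", NA_real_,
    "c1", "a3", 0.0,
    "c1", "a4", 1.5,
    "c1", "a5", NA_real_,
    "c1", "ctx1", 2.0,
    "c1", "ctx2", 3.0)
  summ <- cytotox_summaries(hits, amap)
  expect_equal(summ$m, 2.5)
  gs <- gene_scores(hits, summ, m_global = 0.5, amap)
  # singleton hit: G equals its Z
  expect_equal(gene_score(gs$scores, "c1", "ESR1", amap), (2.5 - 1.0) / 0.5)
  # max rule over the two AR hits (Z = 5 and 2)
  expect_equal(gene_score(gs$scores, "c1", "AR", amap), (2.5 - 0.0) / 0.5)
  gs_mean <- gene_scores(hits, summ, m_global = 0.5, amap, aggregation = "mean")
  expect_equal(gene_score(gs_mean$scores, "c1", "AR", amap), mean(c(5, 2)))
  # provenance carries each contributing assay's Z
  prov <- gs$provenance
  expect_setequal(prov$assay_id[prov$gene_symbol == "AR"], c("a3", "a4"))
  expect_equal(sort(prov$Z[prov$gene_symbol == "AR"]), c(2, 5))
})

test_that("a gene with no hit among its assays has no score; unmapped genes error", {
  hits <- make_hits(
    ~chemical_id, ~assay_id, ~log10_ac50,
    "c1", "a1", NA_real_,
    "c1", "a2", NA_real_,
    "c1", "a3", 0.5,
    "c1", "ctx1", 2.0,
    "c1", "ctx2", 2.4)
  summ <- cytotox_summaries(hits, amap)
  gs <- gene_scores(hits, summ, 0.5, amap)
  expect_true(is.na(gene_score(gs$scores, "c1", "ESR1", amap)))
  expect_false(is.na(gene_score(gs$scores, "c1", "AR", amap)))
  expect_error(gene_score(gs$scores, "c1", "TP53", amap), "no mapped assay")
})

test_that("gene scores ignore assay order and duplicated non-maximal assays", {
  hits <- make_hits(
    ~chemical_id, ~assay_id, ~log10_ac50,
    "c1", "a3", 0.0,
    "c1", "a4", 1.5,
    "c1", "ctx1", 2.0,
    "c1", "ctx2", 3.0)
  summ <- cytotox_summaries(hits, amap)
  g1 <- gene_scores(hits, summ, 0.5, amap)$scores
  g2 <- gene_scores(hits[rev(seq_len(nrow(hits))), ], summ, 0.5, amap)$scores
  expect_equal(g1$G, g2$G)
  # duplicating the weaker AR assay through a5 leaves the max unchanged
  dup <- dplyr::bind_rows(hits, make_hits(~chemical_id, ~assay_id, ~log10_ac50,
                                          "c1", "a5", 1.5))
  g3 <- gene_scores(dup, summ, 0.5, amap)$scores
  expect_equal(gene_score(g3, "c1", "AR", amap),
               gene_score(g1, "c1", "AR", amap))
})

test_that("the modified gene score converts to micromolar equivalents", {
  expect_equal(modified_gene_score(0), 1)
  expect_equal(modified_gene_score(2), 0.01)
  expect_equal(modified_gene_score(-1), 10)
  expect_true(is.na(modified_gene_score(NA_real_)))
  # monotone decreasing in G
  g <- sort(rnorm(20))
  expect_true(all(diff(modified_gene_score(g)) < 0))
})

test_that("the wide gene-score matrix mirrors the long table", {
  scores <- tibble::tibble(chemical_id = c("c1", "c1", "c2"),
                           gene_symbol = c("AR", "ESR1", "ESR1"),
                           G = c(1.5, 2.5, 0.5))
  m <- gene_score_matrix(scores)
  expect_equal(m["c1", "AR"], 1.5)
  expect_equal(m["c2", "ESR1"], 0.5)
  expect_true(is.na(m["c2", "AR"]))
})
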