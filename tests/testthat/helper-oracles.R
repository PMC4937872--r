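# Independent oracles and terse fixture builders used across the suite.

# One endpoint record row.
rec <- function(chem, term, lel = NA_real_, study = "multigeneration",
                species = "rat", gen = "F1", study_id = NULL) {
  tibble::tibble(
    chemical_id = chem,
    study_id = if (is.null(study_id)) paste(chem, study, sep = "-") else study_id,
    study_type = study, species = species, generation = gen,
    endpoint_term = term, lel_mg_kg_day = lel)
}

recs <- function(...) dplyr::bind_rows(...)

# Build a clel_matrix directly from a numeric matrix (NA = missing).
clel_from_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("chem", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- mrdt_categories()[seq_len(ncol(m))]
  repromine:::new_clel_matrix(m, array(FALSE, dim(m), dimnames(m)))
}

# Dense-grid least-squares oracle for the Hill model: exhaustive search over
# an explicit (top, log10_ac50, slope) grid inside the fitter's bounds.
grid_oracle_hill <- function(conc, response, n_la = 50L, n_top = 50L,
                             n_slope = 20L) {
  b <- fit_bounds(conc, response)
  la <- seq(b$log10_ac50[1], b$log10_ac50[2], length.out = n_la)
  sl <- seq(b$slope[1], b$slope[2], length.out = n_slope)
  tp <- seq(b$top[1], b$top[2], length.out = n_top)
  grid <- expand.grid(la = la, sl = sl, KEEP.OUT.ATTRS = FALSE)
  lc <- log10(conc)
  expo <- (grid$sl * grid$la) %o% rep(1, length(lc)) - grid$sl %o% lc
  shapes <- 1 / (1 + 10^expo)
  num <- as.vector(shapes %*% response)
  den <- rowSums(shapes^2)
  ss_y <- sum(response^2)
  best <- Inf
  for (t in tp) {
    rss <- ss_y - 2 * t * num + t^2 * den
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# Dense-grid oracle for the gain-loss model (explicit 5-parameter grid).
grid_oracle_gain_loss <- function(conc, response, n_la = 15L, n_slope = 8L,
                                  n_gap = 10L, n_top = 25L) {
  b <- fit_bounds(conc, response)
  span <- b$log10_ac50[2] - b$log10_ac50[1]
  la <- seq(b$log10_ac50[1], b$log10_ac50[2], length.out = n_la)
  sl <- seq(b$slope[1], b$slope[2], length.out = n_slope)
  gap <- seq(0.01, span, length.out = n_gap)
  tp <- seq(b$top[1], b$top[2], length.out = n_top)
  grid <- expand.grid(la = la, sg = sl, gap = gap, sl = sl,
                      KEEP.OUT.ATTRS = FALSE)
  lc <- log10(conc)
  e_gain <- (grid$sg * grid$la) %o% rep(1, length(lc)) - grid$sg %o% lc
  lal <- grid$la + grid$gap
  e_loss <- (grid$sl * lal) %o% rep(1, length(lc)) - grid$sl %o% lc
  shapes <- (1 / (1 + 10^e_gain)) * (1 - 1 / (1 + 10^e_loss))
  num <- as.vector(shapes %*% response)
  den <- rowSums(shapes^2)
  ss_y <- sum(response^2)
  best <- Inf
  for (t in tp) {
    rss <- ss_y - 2 * t * num + t^2 * den
    m <- min(rss)
    if (m < best) best <- m
  }
  best
}

# Exhaustive Ward merge oracle: at every agglomeration step, evaluate the
# increase in total within-cluster sum of squares for every cluster pair
# and merge the cheapest (ties by lowest indices). Returns the sequence of
# merged index sets.
ward_merge_oracle <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  merges <- list()
  wss <- function(idx) {
    if (length(idx) == 1L) return(0)
    ctr <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, ctr)^2)
  }
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      cost <- wss(c(clusters[[i]], clusters[[j]])) -
        wss(clusters[[i]]) - wss(clusters[[j]])
      if (is.null(best) || cost < best$cost - 1e-12) {
        best <- list(i = i, j = j, cost = cost)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- merged
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# The tested half-log concentration grid (0.01 to ~31.6 uM).
halflog_grid <- function() 10^seq(-2, 1.5, by = 0.5)
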