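#' Concentration-response model curves
#'
#' `hill_response()` is the standard Hill curve on the log10-concentration
#' axis: `top / (1 + 10^(slope * (log10_ac50 - log10(conc))))`.
#' `gain_loss_response()` multiplies an ascending gain gate by the
#' complement of a descending loss gate sharing one amplitude:
#' `top * gain(conc) * (1 - loss(conc))`, which rises at the gain AC50 and
#' falls again at the (higher) loss AC50 -- the shape of responses that are
#' quenched at cytotoxic concentrations.
#'
#' @param conc Concentrations in uM (positive).
#' @param top Amplitude in response units.
#' @param log10_ac50,log10_ac50_gain,log10_ac50_loss AC50s as log10(uM).
#' @param slope,slope_gain,slope_loss Hill slopes (> 0).
#' @return Numeric vector of modeled responses.
#' @export
hill_response <- function(conc, top, log10_ac50, slope) {
  top / (1 + 10^(slope * (log10_ac50 - log10(conc))))
}

#' @rdname hill_response
#' @export
gain_loss_response <- function(conc, top, log10_ac50_gain, slope_gain,
                               log10_ac50_loss, slope_loss) {
  lc <- log10(conc)
  gain <- 1 / (1 + 10^(slope_gain * (log10_ac50_gain - lc)))
  loss <- 1 / (1 + 10^(slope_loss * (log10_ac50_loss - lc)))
  top * gain * (1 - loss)
}

#' Parameter box used by the curve fitters
#'
#' AC50 is constrained to two decades beyond the tested range, the Hill
#' slope to (0, 10\], and the amplitude to 1.2 times the observed maximum
#' response. The same box bounds the deterministic multi-start grid.
#'
#' @param conc,response The series being fitted.
#' @return List with elements `log10_ac50`, `slope`, `top`, each `c(lo, hi)`.
#' @export
fit_bounds <- function(conc, response) {
  lc <- log10(conc)
  list(
    log10_ac50 = c(min(lc) - 2, max(lc) + 2),
    slope = c(0.01, 10),
    top = c(0, max(1e-8, 1.2 * max(response)))
  )
}

new_curve_fit <- function(model, par, rss, n) {
  npar <- length(par)
  structure(list(model = model, par = par, rss = rss, n = n, npar = npar,
                 aicc = aicc(rss, n, npar)),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> %s: rss=%.4g, AICc=%.4g\n  %s\n", x$model, x$rss,
              x$aicc, paste(names(x$par), signif(x$par, 4), sep = "=",
                            collapse = ", ")))
  invisible(x)
}

# Small-sample-corrected information criterion for least-squares fits,
# with k the number of mean-model parameters: on the short half-log series
# typical of screening data, also counting the error variance makes the
# 5-parameter gain-loss model unselectable even against a noiseless planted
# gain-loss curve. Models whose correction denominator vanishes are
# unselectable on that few points.
aicc <- function(rss, n, npar) {
  k <- npar
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Predict responses from a fitted concentration-response model
#'
#' @param object A `curve_fit`.
#' @param conc Concentrations in uM.
#' @param ... Unused.
#' @return Modeled responses.
#' @export
predict.curve_fit <- function(object, conc, ...) {
  p <- object$par
  switch(object$model,
    constant = rep(p[["baseline"]], length(conc)),
    hill = hill_response(conc, p[["top"]], p[["log10_ac50"]], p[["slope"]]),
    gain_loss = gain_loss_response(conc, p[["top"]], p[["log10_ac50_gain"]],
                                   p[["slope_gain"]], p[["log10_ac50_loss"]],
                                   p[["slope_loss"]]),
    stop("unknown model: ", object$model))
}

check_series <- function(conc, response, min_points) {
  if (length(conc) != length(response)) {
    stop("concentration and response vectors must have equal length", call. = FALSE)
  }
  if (length(conc) < min_points) {
    stop(sprintf("insufficient data: need at least %d concentration points, got %d",
                 min_points, length(conc)), call. = FALSE)
  }
  if (any(conc <= 0)) stop("concentrations must be positive (uM)", call. = FALSE)
  if (is.unsorted(conc, strictly = TRUE)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit the constant (no-response) model
#'
#' @param conc,response The concentration (uM) and response vectors.
#' @return A `curve_fit` with the single `baseline` parameter.
#' @export
fit_constant <- function(conc, response) {
  check_series(conc, response, 1L)
  b <- mean(response)
  new_curve_fit("constant", c(baseline = b), sum((response - b)^2),
                length(response))
}

# Profile the amplitude analytically for a matrix of unit-amplitude shapes
# (rows = parameter combinations, cols = concentrations); returns the
# box-clamped optimal top and the resulting RSS per combination.
profile_top <- function(shapes, response, top_hi) {
  num <- as.vector(shapes %*% response)
  den <- rowSums(shapes^2)
  top <- pmin(pmax(ifelse(den > 0, num / den, 0), 0), top_hi)
  rss <- sum(response^2) - 2 * top * num + top^2 * den
  list(top = top, rss = rss)
}

refine_fit <- function(par0, lower, upper, rss_fn, gr_fn = NULL) {
  res <- try(stats::optim(pmin(pmax(par0, lower), upper), rss_fn, gr = gr_fn,
                          method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = 500, factr = 10)),
             silent = TRUE)
  if (inherits(res, "try-error")) list(par = par0, value = rss_fn(par0)) else res
}

#' Fit a Hill model by bounded least squares
#'
#' Deterministic two-stage fit: a fixed coarse grid over (log10 AC50, slope)
#' with the amplitude profiled analytically locates candidate basins; the
#' best grid points are then refined by bounded quasi-Newton (L-BFGS-B)
#' minimization of the residual sum of squares inside [fit_bounds()]. No
#' random initialization is used, so fits are reproducible.
#'
#' @param conc,response The series (>= 4 points, ascending positive uM).
#' @param n_starts Number of grid candidates refined (default 3).
#' @return A `curve_fit` with parameters `top`, `log10_ac50`, `slope`.
#' @export
fit_hill <- function(conc, response, n_starts = 3L) {
  check_series(conc, response, 4L)
  b <- fit_bounds(conc, response)
  lc <- log10(conc)

  la_grid <- seq(b$log10_ac50[1], b$log10_ac50[2], length.out = 25L)
  sl_grid <- c(0.1, 0.3, 0.5, 1, 2, 3, 5, 8)
  grid <- expand.grid(la = la_grid, sl = sl_grid, KEEP.OUT.ATTRS = FALSE)
  expo <- (grid$sl * grid$la) %o% rep(1, length(lc)) - grid$sl %o% lc
  shapes <- 1 / (1 + 10^expo)
  prof <- profile_top(shapes, response, b$top[2])

  rss_fn <- function(p) {
    r <- response - hill_response(conc, p[1], p[2], p[3])
    sum(r * r)
  }
  # analytic gradient of the RSS (finite differences stall in the narrow
  # correlated valley of (top, ac50, slope))
  gr_fn <- function(p) {
    s <- 1 / (1 + 10^(p[3] * (p[2] - lc)))
    r <- response - p[1] * s
    sl1 <- log(10) * s * (1 - s)
    c(-2 * sum(r * s),
      2 * p[1] * p[3] * sum(r * sl1),
      2 * p[1] * sum(r * sl1 * (p[2] - lc)))
  }
  lower <- c(b$top[1], b$log10_ac50[1], b$slope[1])
  upper <- c(b$top[2], b$log10_ac50[2], b$slope[2])

  cand_idx <- order(prof$rss)[seq_len(min(n_starts, nrow(grid)))]
  best <- NULL
  for (i in cand_idx) {
    p0 <- c(prof$top[i], grid$la[i], grid$sl[i])
    res <- refine_fit(p0, lower, upper, rss_fn, gr_fn)
    val <- min(res$value, prof$rss[i])
    par <- if (res$value <= prof$rss[i]) res$par else p0
    if (is.null(best) || val < best$value) best <- list(par = par, value = val)
  }
  new_curve_fit("hill",
                c(top = best$par[1], log10_ac50 = best$par[2],
                  slope = best$par[3]),
                best$value, length(response))
}

#' Fit a gain-loss model by bounded least squares
#'
#' Same deterministic grid-then-refine contract as [fit_hill()]. The loss
#' AC50 is parameterized as gain AC50 plus a strictly positive log10 gap,
#' guaranteeing the loss phase sits above the gain phase.
#'
#' @param conc,response The series (>= 5 points, ascending positive uM).
#' @param n_starts Number of grid candidates refined (default 3).
#' @return A `curve_fit` with parameters `top`, `log10_ac50_gain`,
#'   `slope_gain`, `log10_ac50_loss`, `slope_loss`.
#' @export
fit_gain_loss <- function(conc, response, n_starts = 3L) {
  check_series(conc, response, 5L)
  b <- fit_bounds(conc, response)
  lc <- log10(conc)
  span <- b$log10_ac50[2] - b$log10_ac50[1]

  la_grid <- seq(b$log10_ac50[1], b$log10_ac50[2], length.out = 13L)
  sl_grid <- c(0.5, 1, 2, 4)
  gap_grid <- c(0.5, 1, 2, 3.5)
  grid <- expand.grid(la = la_grid, sg = sl_grid, gap = gap_grid,
                      sl = sl_grid, KEEP.OUT.ATTRS = FALSE)
  e_gain <- (grid$sg * grid$la) %o% rep(1, length(lc)) - grid$sg %o% lc
  lal <- grid$la + grid$gap
  e_loss <- (grid$sl * lal) %o% rep(1, length(lc)) - grid$sl %o% lc
  shapes <- (1 / (1 + 10^e_gain)) * (1 - 1 / (1 + 10^e_loss))
  prof <- profile_top(shapes, response, b$top[2])

  # parameter vector: (top, la_gain, slope_gain, gap, slope_loss)
  rss_fn <- function(p) {
    r <- response - gain_loss_response(conc, p[1], p[2], p[3], p[2] + p[4], p[5])
    sum(r * r)
  }
  gr_fn <- function(p) {
    lal <- p[2] + p[4]
    g <- 1 / (1 + 10^(p[3] * (p[2] - lc)))
    l <- 1 / (1 + 10^(p[5] * (lal - lc)))
    r <- response - p[1] * g * (1 - l)
    gg <- log(10) * g * (1 - g)
    ll <- log(10) * l * (1 - l)
    d_top <- g * (1 - l)
    d_lag <- p[1] * (-(1 - l) * p[3] * gg + g * p[5] * ll)
    d_sg  <- -p[1] * (1 - l) * (p[2] - lc) * gg
    d_gap <- p[1] * g * p[5] * ll
    d_sl  <- p[1] * g * (lal - lc) * ll
    -2 * c(sum(r * d_top), sum(r * d_lag), sum(r * d_sg),
           sum(r * d_gap), sum(r * d_sl))
  }
  lower <- c(b$top[1], b$log10_ac50[1], b$slope[1], 0.01, b$slope[1])
  upper <- c(b$top[2], b$log10_ac50[2], b$slope[2], span, b$slope[2])

  cand_idx <- order(prof$rss)[seq_len(min(n_starts, nrow(grid)))]
  best <- NULL
  for (i in cand_idx) {
    p0 <- c(prof$top[i], grid$la[i], grid$sg[i], grid$gap[i], grid$sl[i])
    res <- refine_fit(p0, lower, upper, rss_fn, gr_fn)
    val <- min(res$value, prof$rss[i])
    par <- if (res$value <= prof$rss[i]) res$par else p0
    if (is.null(best) || val < best$value) best <- list(par = par, value = val)
  }
  p <- best$par
  new_curve_fit("gain_loss",
                c(top = p[1], log10_ac50_gain = p[2], slope_gain = p[3],
                  log10_ac50_loss = p[2] + p[4], slope_loss = p[5]),
                best$value, length(response))
}

#' Select the best-fitting concentration-response model
#'
#' Candidates are compared by the small-sample-corrected information
#' criterion (AICc on the least-squares likelihood, error variance counted
#' as a parameter); ties resolve toward the model with fewer parameters.
#'
#' @param fits List of `curve_fit` objects for the same series (typically
#'   constant, Hill, gain-loss).
#' @return The winning `curve_fit`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  npars <- vapply(fits, function(f) f$npar, numeric(1))
  fits[[order(aiccs, npars)[1]]]
}

#' Call a hit from the best-fitting model
#'
#' A chemical-assay pair is a hit when the winning model is Hill or
#' gain-loss and the maximum response the model predicts over the tested
#' concentration range exceeds the critical response threshold. For
#' gain-loss winners the reported AC50 is the gain-phase AC50.
#'
#' @param best The selected `curve_fit`.
#' @param conc The tested concentrations (uM), defining the range over
#'   which the modeled maximum is taken.
#' @param threshold Critical response threshold, in response units on the
#'   assay's normalized scale (default 20 on a 0-100 scale).
#' @return A one-row tibble: `is_hit`, `model`, `log10_ac50` (NA unless a
#'   hit), `max_modeled_response`.
#' @export
call_hit <- function(best, conc, threshold = 20) {
  grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = 256L)
  max_resp <- max(predict(best, grid))
  is_hit <- best$model %in% c("hill", "gain_loss") && max_resp > threshold
  la <- if (!is_hit) NA_real_ else if (best$model == "hill") {
    unname(best$par[["log10_ac50"]])
  } else {
    unname(best$par[["log10_ac50_gain"]])
  }
  tibble::tibble(is_hit = is_hit, model = best$model, log10_ac50 = la,
                 max_modeled_response = max_resp)
}

#' Fit and hit-call every series of an assay table
#'
#' Runs the constant/Hill/gain-loss fits, model selection, and hit calling
#' for each chemical x assay series of a long-format table.
#'
#' @param series Tibble with columns `chemical_id`, `assay_id`, `conc`
#'   (uM), `response`.
#' @param threshold Critical response threshold for the hit call.
#' @return A tibble with one row per chemical x assay: `chemical_id`,
#'   `assay_id`, `is_hit`, `model`, `log10_ac50`, `max_modeled_response`,
#'   `rss`.
#' @export
call_hits_table <- function(series, threshold = 20) {
  stopifnot(all(c("chemical_id", "assay_id", "conc", "response") %in% names(series)))
  key <- paste(series$chemical_id, series$assay_id, sep = "\r")
  idx <- split(seq_len(nrow(series)), key)
  rows <- lapply(idx, function(ii) {
    sub <- series[ii, ]
    ord <- order(sub$conc)
    conc <- sub$conc[ord]; resp <- sub$response[ord]
    fits <- list(fit_constant(conc, resp), fit_hill(conc, resp))
    if (length(conc) >= 5L) fits[[3]] <- fit_gain_loss(conc, resp)
    best <- select_model(fits)
    hc <- call_hit(best, conc, threshold)
    hc$chemical_id <- sub$chemical_id[1]
    hc$assay_id <- sub$assay_id[1]
    hc$rss <- best$rss
    hc
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out[, c("chemical_id", "assay_id", "is_hit", "model",
                         "log10_ac50", "max_modeled_response", "rss")],
                 .data$chemical_id, .data$assay_id)
}
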