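#' Area under the ROC curve by the rank statistic
#'
#' Computed from the Mann-Whitney U statistic with midranks for ties:
#' the probability that a randomly chosen positive outranks a randomly
#' chosen negative.
#'
#' @param scores Numeric scores (larger = more positive); `-Inf` is a valid
#'   "never ranked above" score for unscored items.
#' @param labels Logical vector, TRUE for positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative labels", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare pipeline outputs against the simulator's planted truth
#'
#' Computes whichever recovery metrics the supplied outputs permit:
#' selectivity AUROC (gene scores vs planted selective pairs, with unscored
#' pairs ranked last), the MRDT confusion matrix, AC50 bias and RMSE over
#' hit-called series with a planted curve, and the observed-vs-configured
#' category frequency ladder.
#'
#' @param truth Planted truth: the `truth` element of [simulate_invivo()]
#'   and/or [simulate_assays()] output (pass the full list of either).
#' @param scores Optional long gene-score tibble ([gene_scores()]`$scores`).
#' @param mrdt_flags Optional flag tibble ([flag_mrdt()]).
#' @param hits Optional hit-call tibble ([call_hits_table()]).
#' @param cooccurrence Optional [cooccurrence_summary()].
#' @return A list of class `recovery_report` with any of
#'   `auroc_selectivity`, `mrdt_confusion`, `ac50_bias`, `ac50_rmse`,
#'   `frequency_ladder`.
#' @export
evaluate_recovery <- function(truth, scores = NULL, mrdt_flags = NULL,
                              hits = NULL, cooccurrence = NULL) {
  out <- list()

  if (!is.null(scores) && !is.null(truth$pairs)) {
    pairs <- truth$pairs
    key <- paste(pairs$chemical_id, pairs$gene_symbol)
    skey <- paste(scores$chemical_id, scores$gene_symbol)
    if (!all(skey %in% key)) {
      stop("gene-score identifiers do not match the planted truth", call. = FALSE)
    }
    g <- scores$G[match(key, skey)]
    g[is.na(g)] <- -Inf
    out$auroc_selectivity <- auroc(g, pairs$is_selective)
  }

  if (!is.null(mrdt_flags) && !is.null(truth$is_mrdt)) {
    idx <- match(truth$chemical_id, mrdt_flags$chemical_id)
    called <- !is.na(idx) & mrdt_flags$is_mrdt[idx]
    called[is.na(called)] <- FALSE
    out$mrdt_confusion <- table(truth = truth$is_mrdt, called = called)
  }

  if (!is.null(hits) && !is.null(truth$assays)) {
    at <- truth$assays[truth$assays$kind != "flat", ]
    j <- dplyr::inner_join(hits[hits$is_hit, ],
                           at[, c("chemical_id", "assay_id", "true_log10_ac50")],
                           by = c("chemical_id", "assay_id"))
    if (nrow(j)) {
      err <- j$log10_ac50 - j$true_log10_ac50
      out$ac50_bias <- mean(err)
      out$ac50_rmse <- sqrt(mean(err^2))
      out$ac50_n <- nrow(j)
    }
  }

  if (!is.null(cooccurrence) && !is.null(truth$chemical_id) &&
      "weight" %in% names(truth)) {
    obs <- setNames(cooccurrence$counts$n_positive / nrow(truth),
                    cooccurrence$counts$category)
    cfg <- colMeans(truth[, c("malformation", "tumor", "sperm", "histology",
                              "weight")])
    out$frequency_ladder <- tibble::tibble(
      category = names(cfg), planted = as.numeric(cfg),
      observed = as.numeric(obs[names(cfg)]))
  }

  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  if (!is.null(x$auroc_selectivity)) {
    cat(sprintf("  selectivity AUROC: %.3f\n", x$auroc_selectivity))
  }
  if (!is.null(x$mrdt_confusion)) {
    cat("  MRDT confusion:\n"); print(x$mrdt_confusion)
  }
  if (!is.null(x$ac50_rmse)) {
    cat(sprintf("  AC50 bias %.3f, RMSE %.3f (n=%d)\n",
                x$ac50_bias, x$ac50_rmse, x$ac50_n))
  }
  invisible(x)
}
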