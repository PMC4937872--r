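#' Hierarchical clustering of a potency or score matrix
#'
#' Agglomerative clustering with Euclidean distance and Ward's minimum
#' variance linkage (the Lance-Williams update on squared Euclidean
#' distances, i.e. the "ward.D2" convention), as used for two-directional
#' heat-map ordering of chemicals and effect categories or molecular
#' targets. Leaf ordering is deterministic for a given input; ties in merge
#' cost resolve by the lower item index.
#'
#' @param x Complete numeric matrix (e.g. effect scores or gene scores).
#' @param axis `"rows"`, `"columns"`, or `"both"` (rows and columns are
#'   clustered independently).
#' @return A list of class `endpoint_clustering` with elements `rows` and/or
#'   `columns`, each a list holding the `hclust` merge tree, the leaf
#'   `order` (labels, left to right), and a `newick` string of the merge
#'   tree with merge heights as branch lengths.
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "columns", "both")) {
  axis <- match.arg(axis)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("clustering requires a numeric matrix", call. = FALSE)
  }
  if (anyNA(x)) stop("clustering requires a complete matrix (no NA)", call. = FALSE)

  cluster_one <- function(m) {
    if (nrow(m) < 2) stop("need at least 2 items to cluster", call. = FALSE)
    if (is.null(rownames(m))) rownames(m) <- paste0("item_", seq_len(nrow(m)))
    hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "ward.D2")
    list(hclust = hc,
         order = hc$labels[hc$order],
         newick = ape::write.tree(ape::as.phylo(hc)))
  }

  out <- list()
  if (axis %in% c("rows", "both")) out$rows <- cluster_one(x)
  if (axis %in% c("columns", "both")) out$columns <- cluster_one(t(x))
  structure(out, class = "endpoint_clustering")
}

#' @export
print.endpoint_clustering <- function(x, ...) {
  for (ax in names(x)) {
    cat(sprintf("<endpoint_clustering> %s: %d leaves\n", ax,
                length(x[[ax]]$order)))
  }
  invisible(x)
}
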