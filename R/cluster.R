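#' Average-linkage (UPGMA) hierarchical clustering on Euclidean distance
#'
#' The clustering convention used throughout: Euclidean distance between
#' item rows, agglomerative UPGMA merges. Applied to cells (scaled
#' measurements or disease profiles) and to classifiers (probability,
#' severity or contribution vectors across items).
#'
#' @param x Numeric items x features matrix (>= 2 rows, finite), or a data
#'   frame with an id column followed by feature columns.
#' @param id_column When `x` is a data frame, the column holding item ids.
#' @return An object of class `dendrogram_result` wrapping the
#'   [stats::hclust()] tree: `merge`, `height`, `order`, `labels`, plus
#'   `metric` and `linkage`.
#' @export
hclust_average <- function(x, id_column = 1L) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[id_column]])
    x <- as.matrix(x[, -id_column, drop = FALSE])
    rownames(x) <- ids
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2L) abort("Clustering needs at least 2 items.")
  if (any(!is.finite(x))) abort("Non-finite values in input.")
  hc <- hclust(dist(x, method = "euclidean"), method = "average")
  structure(
    list(
      merge = hc$merge, height = hc$height, order = hc$order,
      labels = hc$labels %||% as.character(seq_len(nrow(x))),
      n = nrow(x), metric = "euclidean", linkage = "average", hclust = hc
    ),
    class = "dendrogram_result"
  )
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("<dendrogram_result> UPGMA over %d items (Euclidean), %d merges\n",
              x$n, length(x$height)))
  invisible(x)
}

#' @describeIn hclust_average Merge table as a tibble (step, the two
#'   merged nodes, height).
#' @param x A `dendrogram_result`.
#' @param ... Unused.
#' @export
tidy.dendrogram_result <- function(x, ...) {
  tibble(
    step = seq_along(x$height),
    node_a = x$merge[, 1L], node_b = x$merge[, 2L],
    height = x$height
  )
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges; labels are renumbered by first
#' occurrence along the item order, so label 1 is always the cluster of
#' the first item.
#'
#' @param d A `dendrogram_result`.
#' @param k Number of clusters, between 1 and the number of items.
#' @return Integer cluster labels named by item.
#' @export
cut_k <- function(d, k) {
  stopifnot(inherits(d, "dendrogram_result"))
  if (!is.numeric(k) || k < 1L || k > d$n) abort("`k` must be between 1 and the number of items.")
  raw <- cutree(d$hclust, k = as.integer(k))
  relabel <- match(raw, unique(raw))
  setNames(relabel, d$labels)
}

#' Cluster composition by condition
#'
#' Cross-tabulates cluster labels against cell conditions and reports
#' per-cluster condition fractions — e.g. "one cluster almost exclusively
#' composed of control cells".
#'
#' @param labels Cluster labels (from [cut_k()]), aligned with `cells`.
#' @param cells A `feature_table` or annotation tibble.
#' @return A tibble: `cluster`, `condition`, `n`, `fraction` (fractions
#'   sum to 1 within each cluster).
#' @export
cluster_composition <- function(labels, cells) {
  ann <- if (inherits(cells, "feature_table")) cells$cells else as_tibble(cells)
  if (length(labels) != nrow(ann)) abort("`labels` and annotations lengths differ.")
  tibble(cluster = as.integer(labels), condition = ann$condition) %>%
    count(.data$cluster, .data$condition) %>%
    group_by(.data$cluster) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
}

#' Export a dendrogram as a Newick string
#'
#' @param d A `dendrogram_result`.
#' @return A Newick-format string (requires the `ape` package).
#' @export
as_newick <- function(d) {
  stopifnot(inherits(d, "dendrogram_result"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the 'ape' package.")
  }
  ape::write.tree(ape::as.phylo(d$hclust))
}
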