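#' Hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering via the Lance-Williams recurrences on a
#' precomputed distance matrix. `"ward"` is interpreted in the `ward.D2`
#' sense (the textbook Ward criterion on distances, squared internally),
#' which is the standard reading for distance-matrix input.
#'
#' @param d A [distance_matrix()], `dist` object, or square symmetric matrix.
#' @param linkage One of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @return An [stats::hclust] tree with leaf labels from `d`.
#' @export
cluster_tree <- function(d, linkage = c("ward", "complete", "average", "single")) {
  linkage <- match.arg(linkage)
  dd <- if (inherits(d, "dist")) d else stats::as.dist(as.matrix(d))
  if (!all(is.finite(dd))) stop("distance matrix has non-finite entries", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(dd, method = method)
}

#' Cut a tree into k clusters
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A tibble with columns `label` and `cluster`.
#' @export
cut_clusters <- function(tree, k) {
  nl <- length(tree$labels %||% tree$order)
  if (k < 1 || k > nl) stop("k must be between 1 and the number of leaves", call. = FALSE)
  cl <- stats::cutree(tree, k = k)
  tibble::tibble(
    label = names(cl) %||% as.character(seq_along(cl)),
    cluster = as.integer(cl)
  )
}

#' Cluster-versus-truth confusion table
#'
#' @param truth,cluster Two-level assignments of the same items.
#' @return A 2x2 counts matrix (rows = truth, columns = cluster).
#' @export
confusion_table <- function(truth, cluster) {
  tab <- table(truth, cluster)
  if (!all(dim(tab) == c(2, 2))) {
    # pad missing cluster or truth levels with zero columns/rows
    m <- matrix(0L, 2, 2)
    m[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    tab <- m
  }
  unclass(tab)
}

#' Misclassification rate of a two-group clustering
#'
#' `MCR = (a12 + a21) / (a11 + a12 + a21 + a22)` for a 2x2 confusion table,
#' minimized over the two possible cluster-to-class matchings (cluster labels
#' are arbitrary).
#'
#' @param tab A 2x2 confusion table ([confusion_table()]), or the truth vector
#'   when `cluster` is given.
#' @param cluster Optional cluster assignment vector.
#' @return MCR in `[0, 0.5]` after label matching.
#' @export
misclassification_rate <- function(tab, cluster = NULL) {
  tab <- confusion_input(tab, cluster)
  total <- sum(tab)
  if (total == 0) stop("empty confusion table", call. = FALSE)
  min(
    (tab[1, 2] + tab[2, 1]) / total,
    (tab[1, 1] + tab[2, 2]) / total
  )
}

#' Balanced error rate of a two-group clustering
#'
#' `BER = 0.5 * (a12 / (a11 + a12) + a21 / (a21 + a22))`, the mean of the two
#' per-class error rates, minimized over the two cluster-to-class matchings.
#' More suitable than [misclassification_rate()] for unequal class sizes.
#'
#' @inheritParams misclassification_rate
#' @return BER in `[0, 1]` (0.5 at chance level).
#' @export
balanced_error_rate <- function(tab, cluster = NULL) {
  tab <- confusion_input(tab, cluster)
  if (any(rowSums(tab) == 0)) stop("empty truth class margin", call. = FALSE)
  ber <- function(m) 0.5 * (m[1, 2] / (m[1, 1] + m[1, 2]) + m[2, 1] / (m[2, 1] + m[2, 2]))
  min(ber(tab), ber(tab[, 2:1]))
}

confusion_input <- function(tab, cluster) {
  if (!is.null(cluster)) {
    return(confusion_table(tab, cluster))
  }
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  tab
}

#' Export a tree in Newick format
#'
#' Branch lengths are derived from the merge heights (each child branch spans
#' the height difference to its parent; leaves sit at height 0). The output is
#' parseable by standard Newick readers.
#'
#' @param tree An [stats::hclust] tree, or a single leaf label for the
#'   degenerate one-leaf case.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
export_newick <- function(tree, file = NULL) {
  if (is.character(tree) && length(tree) == 1) {
    txt <- paste0(tree, ";")
  } else {
    phy <- ape::as.phylo(tree)
    txt <- ape::write.tree(phy)
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
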