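#' Labeled similarity and distance matrices
#'
#' Pairwise results are stored as plain numeric matrices with dimnames plus a
#' small set of attributes: `what` (`"similarity"` or `"distance"`), `axis`
#' (`"samples"` or `"variables"`) and `method` (provenance of the producing
#' computation). Similarity matrices are symmetric with unit diagonal;
#' distance matrices are symmetric, nonnegative, with zero diagonal.
#'
#' @param m Square numeric matrix with matching row/column labels.
#' @param axis What the rows index, `"samples"` or `"variables"`.
#' @param method Provenance tag, e.g. `"gower"`, `"ama"`, `"dcor"`.
#' @return A matrix of class `mixed_sim` or `mixed_dist` (both `mixed_mat`).
#' @name mixed-matrices
NULL

new_mixed_matrix <- function(m, what, axis, method) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) {
    labs <- colnames(m) %||% paste0("V", seq_len(nrow(m)))
    dimnames(m) <- list(labs, labs)
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels must match", call. = FALSE)
  }
  if (!all(is.finite(m))) stop("matrix entries must be finite", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (what == "similarity") {
    if (max(abs(diag(m) - 1)) > 1e-8) stop("similarity matrix needs unit diagonal", call. = FALSE)
    diag(m) <- 1
  } else {
    if (max(abs(diag(m))) > 1e-8) stop("distance matrix needs zero diagonal", call. = FALSE)
    if (min(m) < -1e-12) stop("distance entries must be nonnegative", call. = FALSE)
    m[m < 0] <- 0
    diag(m) <- 0
  }
  structure(m,
    class = c(if (what == "similarity") "mixed_sim" else "mixed_dist", "mixed_mat", "matrix"),
    what = what, axis = axis, method = method
  )
}

#' @rdname mixed-matrices
#' @export
similarity_matrix <- function(m, axis = "variables", method = "custom") {
  new_mixed_matrix(m, "similarity", axis, method)
}

#' @rdname mixed-matrices
#' @export
distance_matrix <- function(m, axis = "samples", method = "custom") {
  new_mixed_matrix(m, "distance", axis, method)
}

#' @export
print.mixed_mat <- function(x, ...) {
  cat(sprintf(
    "%s matrix (%s x %s %s, method = %s)\n",
    attr(x, "what"), nrow(x), ncol(x), attr(x, "axis"), attr(x, "method")
  ))
  print(unclass_mixed(x), ...)
  invisible(x)
}

unclass_mixed <- function(x) {
  attributes(x)[c("what", "axis", "method")] <- NULL
  class(x) <- "matrix"
  x
}

#' @export
as.matrix.mixed_mat <- function(x, ...) unclass_mixed(x)

#' @export
as.dist.mixed_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(unclass_mixed(m), diag = diag, upper = upper)
}

#' Tidy a pairwise matrix into a long tibble
#'
#' Returns one row per unordered pair (`item1`, `item2`, `value`), the
#' broom-style view of a [similarity_matrix()] or [distance_matrix()].
#'
#' @param x A `mixed_mat`.
#' @param ... Unused.
#' @return A tibble with columns `item1`, `item2`, `value`.
#' @exportS3Method generics::tidy
tidy.mixed_mat <- function(x, ...) {
  labs <- rownames(x)
  idx <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    item1 = labs[idx[, 1]],
    item2 = labs[idx[, 2]],
    value = x[idx]
  )
}

#' One-line summary of a pairwise matrix
#'
#' @param x A `mixed_mat`.
#' @param ... Unused.
#' @return A one-row tibble: size, axis, method and off-diagonal value range.
#' @exportS3Method generics::glance
glance.mixed_mat <- function(x, ...) {
  off <- x[upper.tri(x)]
  tibble::tibble(
    n = nrow(x),
    axis = attr(x, "axis"),
    method = attr(x, "method"),
    what = attr(x, "what"),
    min = if (length(off)) min(off) else NA_real_,
    max = if (length(off)) max(off) else NA_real_
  )
}

#' Write a labeled square matrix as TSV
#'
#' The dialect is a header row of labels, a label first column, and entries
#' printed with enough digits that a read/write round trip reproduces values
#' to at least 12 significant digits.
#'
#' @param m A [similarity_matrix()], [distance_matrix()] or plain labeled
#'   symmetric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_square_matrix <- function(m, path) {
  mm <- as.matrix(m)
  if (nrow(mm) != ncol(mm)) stop("matrix must be square", call. = FALSE)
  if (max(abs(mm - t(mm))) > 1e-8 * max(1, max(abs(mm)))) {
    stop("matrix must be symmetric", call. = FALSE)
  }
  labs <- rownames(mm) %||% paste0("V", seq_len(nrow(mm)))
  lines <- c(
    paste(c("", labs), collapse = "\t"),
    vapply(seq_len(nrow(mm)), function(i) {
      paste(c(labs[i], formatC(mm[i, ], format = "g", digits = 15)), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled square matrix written by [write_square_matrix()]
#'
#' @param path Input TSV path.
#' @param what `"distance"`, `"similarity"` or `"auto"` (decided by the
#'   diagonal).
#' @param axis,method Provenance attributes for the returned object.
#' @return A `mixed_sim` or `mixed_dist` matrix.
#' @export
read_square_matrix <- function(path, what = c("auto", "distance", "similarity"),
                               axis = "samples", method = "file") {
  what <- match.arg(what)
  x <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  colnames(m) <- colnames(x)
  if (what == "auto") {
    what <- if (max(abs(diag(m))) < 1e-8) "distance" else "similarity"
  }
  new_mixed_matrix(m, what, axis, method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
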