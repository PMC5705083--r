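#' Type-specific pairwise distances for one variable
#'
#' Builds the n-by-n distance matrix between samples for a single variable,
#' using the metric matching its scale: the discrete metric (0/1) for nominal
#' or binary variables, the absolute difference for quantitative variables,
#' and the absolute midrank difference for ordinal variables. These are the
#' ingredients of the generalized distance correlation, and (up to range
#' normalization, which leaves the correlation unchanged) the same summands
#' that enter Gower's distance between samples.
#'
#' @param x Values of one variable, without missing entries (pairwise-complete
#'   subsetting happens in the caller).
#' @param scale One of `"quantitative"`, `"ordinal"`, `"nominal"`, `"binary"`.
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
type_distances <- function(x, scale = c("quantitative", "ordinal", "nominal", "binary")) {
  scale <- match.arg(scale)
  if (anyNA(x)) stop("missing values must be removed before computing distances", call. = FALSE)
  if (scale == "quantitative") {
    return(abs(outer(as.numeric(x), as.numeric(x), "-")))
  }
  if (scale == "ordinal") {
    r <- rank(ranked_values(x)) # midranks
    return(abs(outer(r, r, "-")))
  }
  xi <- if (is.factor(x)) as.integer(x) else as.integer(factor(x))
  1 - (outer(xi, xi, "==") * 1)
}

#' Double-center a distance matrix
#'
#' `A_ij = d_ij - rowmean_i - colmean_j + grandmean`. Row and column sums of
#' the result are zero.
#'
#' @param dmat Square numeric matrix.
#' @return Centered matrix of the same size.
#' @export
double_center <- function(dmat) {
  dmat <- as.matrix(dmat)
  rm <- rowMeans(dmat)
  cm <- colMeans(dmat)
  gm <- mean(dmat)
  dmat - outer(rm, rep(1, ncol(dmat))) - outer(rep(1, nrow(dmat)), cm) + gm
}

# Modified (U-centered) matrix A* used by the bias-corrected estimator:
# off-diagonal n/(n-1) * (A_ij - d_ij/n); diagonal n/(n-1) * (rowmean_i - grandmean).
u_center <- function(dmat) {
  n <- nrow(dmat)
  a <- double_center(dmat)
  astar <- (n / (n - 1)) * (a - dmat / n)
  diag(astar) <- (n / (n - 1)) * (rowMeans(dmat) - mean(dmat))
  astar
}

#' Bias-corrected squared generalized distance covariance
#'
#' Computes the bias-corrected statistic from two per-variable distance
#' matrices:
#' \deqn{\tilde U = \frac{n-3}{n}\Big(\sum_{i,j} A^*_{ij} B^*_{ij} -
#'   \frac{n}{n-2}\sum_i A^*_{ii} B^*_{ii}\Big)}
#' where A*, B* are the modified centered distance matrices. Unlike the plain
#' (biased) squared distance covariance, the corrected statistic may be
#' negative.
#'
#' @param dk,dl Symmetric distance matrices of the two variables (same n >= 4).
#' @return The (possibly negative) bias-corrected statistic.
#' @export
bias_corrected_dcov <- function(dk, dl) {
  dk <- as.matrix(dk)
  dl <- as.matrix(dl)
  n <- nrow(dk)
  if (n < 4) stop("bias-corrected distance covariance needs n >= 4", call. = FALSE)
  if (!all(dim(dl) == dim(dk))) stop("distance matrices must have equal size", call. = FALSE)
  astar <- u_center(dk)
  bstar <- u_center(dl)
  ((n - 3) / n) * (sum(astar * bstar) - (n / (n - 2)) * sum(diag(astar) * diag(bstar)))
}

#' Bias-corrected generalized distance correlation
#'
#' Normalizes the bias-corrected distance covariance by the corresponding
#' distance variances:
#' \deqn{\tilde R_{kl} = \tilde U_{kl} / \sqrt{\tilde U_{kk}\tilde U_{ll}}}
#' the standard bias-corrected distance correlation statistic. For exclusively
#' quantitative variables this is Székely and Rizzo's bias-corrected estimator
#' of the squared distance correlation; here the per-type metrics generalize
#' it to ordinal and nominal variables. A nonconstant variable has correlation
#' 1 with itself; under independence the statistic is centered near 0 and may
#' be (slightly) negative. A degenerate (constant) variable, for which the
#' distance variance vanishes, yields 0 with a warning.
#'
#' @inheritParams bias_corrected_dcov
#' @return The bias-corrected correlation (can be slightly negative).
#' @export
dcor_coefficient <- function(dk, dl) {
  ukl <- bias_corrected_dcov(dk, dl)
  ukk <- bias_corrected_dcov(dk, dk)
  ull <- bias_corrected_dcov(dl, dl)
  if (ukk <= 1e-12 || ull <= 1e-12) {
    warning("degenerate variable (zero distance variance); correlation set to 0",
      call. = FALSE
    )
    return(0)
  }
  ukl / sqrt(ukk * ull)
}

#' Generalized distance correlation of two mixed-type variables
#'
#' Convenience wrapper: builds the type-specific distance matrices
#' ([type_distances()]) on pairwise-complete observations and returns
#' [dcor_coefficient()].
#'
#' @param x,y Variable values (numeric, factor or ordered factor).
#' @param scale_x,scale_y Scales; inferred from the classes when `NULL`.
#' @return The bias-corrected generalized distance correlation.
#' @export
dcor_similarity <- function(x, y, scale_x = NULL, scale_y = NULL) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4) stop("need >= 4 pairwise-complete observations", call. = FALSE)
  scale_x <- scale_x %||% infer_scale(x)
  scale_y <- scale_y %||% infer_scale(y)
  dcor_coefficient(
    type_distances(subset_any(x, ok), scale_x),
    type_distances(subset_any(y, ok), scale_y)
  )
}

infer_scale <- function(x) {
  if (is.numeric(x)) "quantitative" else if (is.ordered(x)) "ordinal" else "nominal"
}

subset_any <- function(x, ok) {
  x <- x[ok]
  if (is.factor(x)) droplevels(x) else x
}

#' Variable distances from generalized distance correlation
#'
#' For every pair of variables, computes the bias-corrected generalized
#' distance correlation on the type-specific metrics and returns the
#' dissimilarity `d_kl = 1 - R~_kl`. Because the bias-corrected statistic can
#' be slightly negative under independence, entries may marginally exceed 1;
#' they are kept as computed (a message flags this).
#'
#' Missing data are handled per pair (pairwise-complete observations), with
#' ordinal ranks recomputed on the complete subset. With complete data a fast
#' path precomputes the modified centered matrix of each variable once.
#'
#' @inheritParams gower_dist
#' @return A [distance_matrix()] over variables (`method = "dcor"`).
#' @export
dcor_dist <- function(data, spec = NULL) {
  cm <- compile_mixed(data, spec)
  if (cm$p < 2) stop("need at least 2 variables", call. = FALSE)
  p <- cm$p
  n <- cm$n
  r <- diag(1, p)
  complete <- !any(vapply(cm$vars, function(v) anyNA(v$x), logical(1)))
  if (complete) {
    if (n < 4) stop("need >= 4 samples", call. = FALSE)
    stars <- lapply(cm$vars, function(v) u_center(type_distances(v$x, v$scale)))
    m <- vapply(stars, as.vector, numeric(n * n)) # n^2 x p
    dg <- vapply(stars, diag, numeric(n)) # n x p
    u <- ((n - 3) / n) * (crossprod(m) - (n / (n - 2)) * crossprod(dg))
    uv <- diag(u)
    degen <- uv <= 1e-12
    if (any(degen)) {
      warning("degenerate variable(s): ", paste(names(cm$vars)[degen], collapse = ", "),
        "; correlations set to 0",
        call. = FALSE
      )
    }
    r <- u / sqrt(outer(uv, uv))
    r[degen, ] <- 0
    r[, degen] <- 0
    diag(r) <- 1
  } else {
    for (k in seq_len(p - 1)) {
      for (l in (k + 1):p) {
        vk <- cm$vars[[k]]
        vl <- cm$vars[[l]]
        ok <- !is.na(vk$x) & !is.na(vl$x)
        if (sum(ok) < 4) {
          stop("pair (", vk$name, ", ", vl$name, ") has < 4 complete observations",
            call. = FALSE
          )
        }
        r[k, l] <- r[l, k] <- dcor_coefficient(
          type_distances(subset_any(vk$x, ok), vk$scale),
          type_distances(subset_any(vl$x, ok), vl$scale)
        )
      }
    }
  }
  d <- 1 - r
  diag(d) <- 0
  if (any(d > 1)) {
    message(
      sum(d[upper.tri(d)] > 1),
      " variable pair(s) have distance > 1 (negative bias-corrected correlation)"
    )
  }
  dimnames(d) <- list(names(cm$vars), names(cm$vars))
  new_mixed_matrix(d, "distance", "variables", "dcor")
}
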