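#' Absolute Spearman correlation similarity
#'
#' Similarity between two rank-order variables: the absolute Pearson
#' correlation of midranks, computed on pairwise-complete observations.
#' Ordinal factors enter through their level codes (their midranks equal the
#' midranks of the ordered values).
#'
#' @param x,y Numeric vectors or ordered factors.
#' @return A similarity in `[0, 1]`. Fewer than 3 complete pairs or a constant
#'   variable yields 0 with a warning.
#' @export
spearman_similarity <- function(x, y) {
  x <- ranked_values(x)
  y <- ranked_values(y)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    warning("fewer than 3 complete pairs; similarity set to 0", call. = FALSE)
    return(0)
  }
  x <- x[ok]
  y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant variable; similarity set to 0", call. = FALSE)
    return(0)
  }
  abs(stats::cor(x, y, method = "spearman"))
}

ranked_values <- function(x) {
  if (is.factor(x)) as.numeric(as.integer(x)) else as.numeric(x)
}

#' Goodman-Kruskal gamma
#'
#' `gamma = (n_c - n_d) / (n_c + n_d)` over concordant and discordant pairs of
#' observations of two ordered variables, computed from their cross-table
#' under its current category orders.
#'
#' @param x A contingency table/matrix, or the first variable (ordered factor
#'   or numeric) when `y` is given.
#' @param y Optional second variable, cross-tabulated against `x`.
#' @return Gamma in `[-1, 1]`; 0 with a warning when there are no concordant
#'   or discordant pairs.
#' @export
#' @examples
#' gk_gamma(matrix(c(10, 0, 0, 10), 2))
gk_gamma <- function(x, y = NULL) {
  tab <- if (is.null(y)) as.matrix(x) else crosstab(x, y)
  cc <- concordance_counts(tab)
  if (cc$n_c + cc$n_d == 0) {
    warning("no concordant or discordant pairs; gamma set to 0", call. = FALSE)
    return(0)
  }
  (cc$n_c - cc$n_d) / (cc$n_c + cc$n_d)
}

crosstab <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  unclass(table(x[ok], y[ok]))
}

# Concordant/discordant pair counts of a cross-table, each pair counted once,
# via tail-sum matrices (O(RC)).
concordance_counts <- function(tab) {
  tab <- as.matrix(tab)
  R <- nrow(tab)
  C <- ncol(tab)
  if (R < 1 || C < 1) {
    return(list(n_c = 0, n_d = 0))
  }
  # padded 2-D cumulative sums give O(1) block sums
  total <- matrix(0, R + 1, C + 1)
  total[2:(R + 1), 2:(C + 1)] <- t(apply(apply(tab, 2, cumsum), 1, cumsum))
  cell_sum <- function(i1, i2, j1, j2) {
    # inclusive block sum over rows i1..i2, cols j1..j2 using the padded cumsum
    total[i2 + 1, j2 + 1] - total[i1, j2 + 1] - total[i2 + 1, j1] + total[i1, j1]
  }
  n_c <- 0
  n_d <- 0
  for (i in seq_len(R - 1)) {
    for (j in seq_len(C)) {
      if (tab[i, j] == 0) next
      if (j < C) n_c <- n_c + tab[i, j] * cell_sum(i + 1, R, j + 1, C)
      if (j > 1) n_d <- n_d + tab[i, j] * cell_sum(i + 1, R, 1, j - 1)
    }
  }
  list(n_c = n_c, n_d = n_d)
}

#' Order the categories of a nominal variable by a ranked response
#'
#' Sorts the categories of `x` ascending by the mean midrank of `y` within
#' each category, turning a nominal factor into an ordinal one whose order is
#' "correct" with respect to `y`. Ties keep the original relative order;
#' categories left empty after removing missing values are dropped with a
#' warning.
#'
#' @param x Factor or character vector (nominal).
#' @param y Numeric vector or ordered factor providing the ranks.
#' @return Character vector of categories, low to high.
#' @export
order_categories_by_response <- function(x, y) {
  x <- if (is.factor(x)) x else factor(x)
  yv <- ranked_values(y)
  ok <- !is.na(x) & !is.na(yv)
  ry <- rank(yv[ok])
  means <- tapply(ry, droplevels(x[ok]), mean)
  dropped <- setdiff(levels(x), names(means))
  if (length(dropped) > 0) {
    warning("empty categor", if (length(dropped) > 1) "ies" else "y", " dropped: ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  names(means)[order(means)] # order() is stable: ties keep original order
}

#' Similarity between a nominal variable and a ranked variable
#'
#' Implements the category-reordering strategy for a nominal factor `x`
#' against a quantitative or ordinal `y`: a Kruskal-Wallis pre-test screens
#' for any shift of `y` across the categories of `x`; only if it is
#' significant (`p < alpha`) are the categories reordered by mean rank of `y`
#' (see [order_categories_by_response()]) before computing the absolute
#' Spearman correlation (`y` quantitative) or absolute Goodman-Kruskal gamma
#' (`y` ordinal). Otherwise the same coefficient is computed on `x` in its
#' original category order, which for unrelated variables represents a random
#' ordering and yields a coefficient near 0.
#'
#' @param x Nominal factor or character vector.
#' @param y Numeric vector (quantitative) or ordered factor (ordinal).
#' @param alpha Pre-test significance level (default 0.05).
#' @return A similarity in `[0, 1]`, with attribute `gate` recording whether
#'   the pre-test passed.
#' @export
nominal_vs_ranked_similarity <- function(x, y, alpha = 0.05) {
  x <- if (is.factor(x)) x else factor(x)
  y_ordinal <- is.factor(y)
  yv <- ranked_values(y)
  ok <- !is.na(x) & !is.na(yv)
  x <- droplevels(factor(x[ok], levels = levels(x)))
  yv <- yv[ok]
  if (nlevels(x) < 2 || length(yv) < 3) {
    warning("fewer than 2 categories on complete cases; similarity set to 0", call. = FALSE)
    return(0)
  }
  p <- suppressWarnings(stats::kruskal.test(yv, x)$p.value)
  gate <- is.finite(p) && p < alpha
  if (gate) {
    ord <- order_categories_by_response(x, yv)
    x <- factor(x, levels = ord, ordered = TRUE)
  }
  s <- if (y_ordinal) {
    abs(gk_gamma(crosstab(x, yv)))
  } else {
    spearman_similarity(as.integer(x), yv)
  }
  structure(s, gate = gate)
}

#' Diagonalize a cross-table
#'
#' Reorders the categories of both factors of a contingency table so that
#' large frequencies concentrate on the diagonal, maximizing the absolute
#' Goodman-Kruskal gamma of the reordered table. The side with fewer
#' categories is permuted exhaustively (up to `max_exhaustive` categories;
#' permutations visited in lexicographic order and the first maximizer kept);
#' for each permutation the other side is ordered ascending by the mean
#' position of its observations on the permuted side. Above the cap a
#' frequency-sorted start followed by two rounds of reciprocal mean-score
#' reordering is used instead.
#'
#' @param tab Contingency table or counts matrix (>= 2 rows and columns).
#' @param max_exhaustive Largest category count searched exhaustively.
#' @return The reordered counts matrix, with attributes `gamma`, `row_order`
#'   and `col_order`.
#' @export
diagonalize_crosstab <- function(tab, max_exhaustive = 6) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("need >= 2 rows and >= 2 columns", call. = FALSE)
  swap <- ncol(tab) < nrow(tab)
  m <- if (swap) t(tab) else tab # rows = smaller side
  R <- nrow(m)
  if (R <= max_exhaustive) {
    best <- NULL
    best_g <- -Inf
    perms <- lex_permutations(R)
    for (pi in seq_len(nrow(perms))) {
      perm <- perms[pi, ]
      cand <- reorder_other_side(m, perm)
      g <- abs(gk_gamma(cand$tab))
      if (g > best_g + 1e-12) {
        best_g <- g
        best <- cand
      }
    }
  } else {
    perm <- order(-rowSums(m)) # frequency-sorted start
    cord <- order(-colSums(m))
    cur <- list(tab = m[perm, cord, drop = FALSE], row_order = perm, col_order = cord)
    for (r in 1:2) {
      cand <- reorder_other_side(m, cur$row_order)
      # reciprocal step: re-order rows by mean column position
      rowscore <- as.vector(m[, cand$col_order, drop = FALSE] %*% seq_len(ncol(m))) /
        pmax(rowSums(m), 1)
      cur <- list(
        row_order = order(rowscore), col_order = cand$col_order
      )
    }
    best <- list(
      tab = m[cur$row_order, cur$col_order, drop = FALSE],
      row_order = cur$row_order, col_order = cur$col_order
    )
  }
  out <- if (swap) t(best$tab) else best$tab
  structure(out,
    gamma = gk_gamma(out),
    row_order = if (swap) best$col_order else best$row_order,
    col_order = if (swap) best$row_order else best$col_order
  )
}

# Apply a permutation to the rows and order columns ascending by the mean
# (count-weighted) permuted row position of their observations.
reorder_other_side <- function(m, perm) {
  mp <- m[perm, , drop = FALSE]
  colscore <- as.vector(seq_along(perm) %*% mp) / pmax(colSums(mp), 1)
  cord <- order(colscore)
  list(tab = mp[, cord, drop = FALSE], row_order = perm, col_order = cord)
}

lex_permutations <- function(k) {
  if (k == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- lex_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Similarity between two nominal/binary variables
#'
#' A chi-square pre-test of association (no continuity correction) gates the
#' cross-table diagonalization: if `p < alpha` the absolute Goodman-Kruskal
#' gamma of the diagonalized table is returned, otherwise the absolute gamma
#' of the table in its original category orders.
#'
#' @param x,y Factors or character vectors.
#' @param alpha Pre-test significance level (default 0.05).
#' @param max_exhaustive Passed to [diagonalize_crosstab()].
#' @return A similarity in `[0, 1]`.
#' @export
nominal_nominal_similarity <- function(x, y, alpha = 0.05, max_exhaustive = 6) {
  tab <- crosstab(x, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warning("degenerate cross-table; similarity set to 0", call. = FALSE)
    return(0)
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  if (is.finite(p) && p < alpha) {
    abs(attr(diagonalize_crosstab(tab, max_exhaustive), "gamma"))
  } else {
    abs(gk_gamma(tab))
  }
}

#' Variable similarity matrix by combination of association measures
#'
#' Builds the p-by-p similarity matrix between variables by dispatching, per
#' pair of scales, to the coefficient suited for that data-type combination:
#'
#' * quantitative-quantitative, quantitative-ordinal: absolute Spearman
#'   correlation ([spearman_similarity()]);
#' * ordinal-ordinal, quantitative-binary, ordinal-binary: absolute
#'   Goodman-Kruskal gamma ([gk_gamma()]), the binary variable entering as a
#'   two-level ordinal;
#' * quantitative/ordinal-nominal: category reordering with Kruskal-Wallis
#'   gate ([nominal_vs_ranked_similarity()]);
#' * nominal/binary-nominal/binary: cross-table diagonalization with
#'   chi-square gate ([nominal_nominal_similarity()]).
#'
#' Every coefficient and pre-test uses pairwise-complete observations; a pair
#' with fewer than 3 complete observations gets similarity 0 with a warning.
#'
#' @inheritParams gower_dist
#' @param alpha Pre-test significance level for the gated coefficients.
#' @param max_exhaustive Cap for the exhaustive diagonalization search.
#' @return A [similarity_matrix()] over variables (`method = "ama"`), entries
#'   in `[0, 1]`, unit diagonal. Not necessarily positive semi-definite; see
#'   [nearest_psd()] and [ama_dist()].
#' @export
ama_similarity <- function(data, spec = NULL, alpha = 0.05, max_exhaustive = 6) {
  cm <- compile_mixed(data, spec)
  if (cm$p < 2) stop("need at least 2 variables", call. = FALSE)
  s <- diag(1, cm$p)
  for (k in seq_len(cm$p - 1)) {
    for (l in (k + 1):cm$p) {
      s[k, l] <- s[l, k] <- ama_pair(cm$vars[[k]], cm$vars[[l]], alpha, max_exhaustive)
    }
  }
  dimnames(s) <- list(names(cm$vars), names(cm$vars))
  new_mixed_matrix(s, "similarity", "variables", "ama")
}

ama_pair <- function(vk, vl, alpha, max_exhaustive) {
  ok <- !is.na(vk$x) & !is.na(vl$x)
  if (sum(ok) < 3) {
    warning("pair (", vk$name, ", ", vl$name, ") has < 3 complete observations; similarity 0",
      call. = FALSE
    )
    return(0)
  }
  x <- subset_var(vk, ok)
  y <- subset_var(vl, ok)
  key <- paste(sort(c(vk$scale, vl$scale)), collapse = "-")
  a <- if (vk$scale <= vl$scale) x else y # alphabetical orientation
  b <- if (vk$scale <= vl$scale) y else x
  switch(key,
    "quantitative-quantitative" = ,
    "ordinal-quantitative" = spearman_similarity(x, y),
    "ordinal-ordinal" = ,
    "binary-quantitative" = ,
    "binary-ordinal" = abs(gk_gamma(crosstab(x, y))),
    "nominal-quantitative" = ,
    "nominal-ordinal" = nominal_vs_ranked_similarity(a, b, alpha = alpha),
    "binary-binary" = ,
    "binary-nominal" = ,
    "nominal-nominal" = nominal_nominal_similarity(x, y,
      alpha = alpha, max_exhaustive = max_exhaustive
    ),
    stop("unhandled scale combination: ", key)
  )
}

subset_var <- function(v, ok) {
  x <- v$x[ok]
  if (is.factor(x)) droplevels(x) else x
}

#' Nearest positive semi-definite correlation-like matrix
#'
#' Projects a symmetric unit-diagonal similarity matrix onto the closest (in
#' weighted Frobenius norm) positive semi-definite matrix, via Higham's
#' alternating-projection algorithm with unit weights ([Matrix::nearPD()],
#' `corr = TRUE`, tolerance 1e-7, at most 100 iterations, diagonal re-pinned
#' to 1 each iteration). A matrix that is already PSD (smallest eigenvalue
#' >= -1e-8) is returned unchanged. Entries of the projection are clamped to
#' `[-1, 1]` and the diagonal restored. With a PSD similarity matrix S, the
#' distances `sqrt(1 - S)` are Euclidean (Gower's theorem), hence metric.
#'
#' @param s A [similarity_matrix()] (symmetric, unit diagonal).
#' @return A PSD [similarity_matrix()] with the same labels.
#' @export
nearest_psd <- function(s) {
  m <- as.matrix(s)
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8) {
    return(similarity_matrix(m, axis = attr(s, "axis") %||% "variables",
      method = attr(s, "method") %||% "custom"))
  }
  res <- Matrix::nearPD(m,
    corr = TRUE, keepDiag = TRUE, do2eigen = TRUE,
    conv.tol = 1e-7, maxit = 100
  )
  if (!res$converged) {
    warning("PSD projection did not converge within 100 iterations; using best iterate",
      call. = FALSE
    )
  }
  out <- as.matrix(res$mat)
  out <- pmin(pmax(out, -1), 1)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  similarity_matrix(out, axis = attr(s, "axis") %||% "variables",
    method = paste0(attr(s, "method") %||% "custom", "+psd"))
}

#' Variable distances from the association-measure similarity matrix
#'
#' Computes the [ama_similarity()] matrix, repairs it to the nearest positive
#' semi-definite matrix ([nearest_psd()]) so that the induced distances are
#' Euclidean, and returns `D = sqrt(1 - S')` entrywise.
#'
#' @inheritParams ama_similarity
#' @param psd Apply the PSD repair (default `TRUE`). Without it `sqrt(1 - S)`
#'   may violate triangle inequalities.
#' @return A [distance_matrix()] over variables (`method = "ama"`).
#' @export
ama_dist <- function(data, spec = NULL, alpha = 0.05, max_exhaustive = 6, psd = TRUE) {
  s <- ama_similarity(data, spec, alpha = alpha, max_exhaustive = max_exhaustive)
  if (psd) s <- nearest_psd(s)
  d <- sqrt(pmax(1 - as.matrix(s), 0))
  diag(d) <- 0
  new_mixed_matrix(d, "distance", "variables", "ama")
}
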