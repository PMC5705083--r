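# Independent naive oracles, written directly from the printed formulas with
# explicit loops. They share no code with the package internals.

# Double-centered matrix, elementwise.
naive_center <- function(d) {
  n <- nrow(d)
  a <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      a[i, j] <- d[i, j] - sum(d[i, ]) / n - sum(d[, j]) / n + sum(d) / n^2
    }
  }
  a
}

# Modified matrix A*: off-diagonal n/(n-1) (A_ij - d_ij/n);
# diagonal n/(n-1) (rowmean_i - grandmean).
naive_star <- function(d) {
  n <- nrow(d)
  a <- naive_center(d)
  s <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      s[i, j] <- if (i != j) {
        n / (n - 1) * (a[i, j] - d[i, j] / n)
      } else {
        n / (n - 1) * (sum(d[i, ]) / n - sum(d) / n^2)
      }
    }
  }
  s
}

# Bias-corrected squared generalized distance covariance.
naive_ucov <- function(dk, dl) {
  n <- nrow(dk)
  astar <- naive_star(dk)
  bstar <- naive_star(dl)
  tot <- 0
  dtot <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      tot <- tot + astar[i, j] * bstar[i, j]
    }
    dtot <- dtot + astar[i, i] * bstar[i, i]
  }
  (n - 3) / n * (tot - n / (n - 2) * dtot)
}

# Generalized distance correlation: R~ = U~kl / sqrt(U~kk U~ll).
naive_dcor <- function(dk, dl) {
  ukl <- naive_ucov(dk, dl)
  ukk <- naive_ucov(dk, dk)
  ull <- naive_ucov(dl, dl)
  if (ukk <= 1e-12 || ull <= 1e-12) {
    return(0)
  }
  ukl / sqrt(ukk * ull)
}

# Per-variable distance matrix by explicit loops.
naive_type_distances <- function(x, scale) {
  n <- length(x)
  d <- matrix(0, n, n)
  v <- if (scale == "quantitative") {
    as.numeric(x)
  } else if (scale == "ordinal") {
    rank(as.integer(x))
  } else {
    as.integer(factor(x))
  }
  for (i in 1:n) {
    for (j in 1:n) {
      d[i, j] <- if (scale %in% c("nominal", "binary")) {
        as.numeric(v[i] != v[j])
      } else {
        abs(v[i] - v[j])
      }
    }
  }
  d
}

# Concordant/discordant counts by brute-force enumeration of observation pairs.
brute_gamma <- function(x, y) {
  xs <- if (is.factor(x)) as.integer(x) else as.numeric(x)
  ys <- if (is.factor(y)) as.integer(y) else as.numeric(y)
  nc <- 0
  nd <- 0
  n <- length(xs)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(xs[i] - xs[j]) * sign(ys[i] - ys[j])
      if (s > 0) nc <- nc + 1
      if (s < 0) nd <- nd + 1
    }
  }
  list(n_c = nc, n_d = nd, gamma = if (nc + nd > 0) (nc - nd) / (nc + nd) else 0)
}

# Greedy Ward oracle on 1-D points: at each step merge the pair of clusters
# whose union minimally increases total within-cluster sum of squares.
ward_partitions_1d <- function(x) {
  clusters <- as.list(seq_along(x))
  sse <- function(idx) sum((x[idx] - mean(x[idx]))^2)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_inc <- Inf
    for (a in 1:(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        inc <- sse(c(clusters[[a]], clusters[[b]])) -
          sse(clusters[[a]]) - sse(clusters[[b]])
        if (inc < best_inc - 1e-12) {
          best_inc <- inc
          best <- c(a, b)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    membership <- integer(length(x))
    for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1]] <- membership
  }
  partitions # element k holds the (n - k)-cluster membership
}

# Random mixed dataset with all four scales; complete by default.
random_mixed_data <- function(n, p, seed, missing_rate = 0) {
  set.seed(seed)
  scales <- sample(c("quantitative", "ordinal", "nominal", "binary"), p, replace = TRUE)
  cols <- list()
  for (j in seq_len(p)) {
    x <- rnorm(n)
    cols[[j]] <- switch(scales[j],
      quantitative = x,
      ordinal = categorize_quantile(x, sample(3:5, 1), "ordinal"),
      nominal = categorize_quantile(x, sample(3:5, 1), "nominal"),
      binary = categorize_quantile(x, 2, "binary")
    )
  }
  names(cols) <- sprintf("v%02d", seq_len(p))
  data <- tibble::as_tibble(cols)
  if (missing_rate > 0) {
    for (j in seq_len(p)) {
      miss <- runif(n) < missing_rate
      data[[j]][miss] <- NA
    }
  }
  spec <- mixed_spec(
    names(cols), scales,
    lapply(data, function(c) if (is.factor(c)) levels(c) else NULL)
  )
  list(data = data, spec = spec)
}

# All triangle inequalities of a distance matrix hold up to `slack`.
max_triangle_violation <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  worst <- -Inf
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      worst <- max(worst, max(d[i, j] - (d[i, ] + d[, j])))
    }
  }
  worst
}
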