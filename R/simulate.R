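#' Quantile-based categorization in "perfect agreement"
#'
#' Replaces a quantitative variable by a K-category version cut at its
#' empirical j/K quantiles, so the categorized variable carries the same
#' association ordering as its quantitative parent: a binary variable is a
#' median cut, four categories are quartile cuts, and so on. Cuts are
#' rank-based, so when n is divisible by K the categories are perfectly
#' balanced.
#'
#' @param x Numeric vector.
#' @param k Number of categories (>= 2).
#' @param scale `"ordinal"` keeps the cut order as the level order,
#'   `"nominal"` randomly permutes the level order (so that the original
#'   ordering carries no information), `"binary"` is a two-level median cut.
#' @return A factor (ordered for `"ordinal"`).
#' @export
categorize_quantile <- function(x, k, scale = c("ordinal", "nominal", "binary")) {
  scale <- match.arg(scale)
  if (scale == "binary") k <- 2L
  if (k < 2 || k > length(x)) stop("invalid number of categories", call. = FALSE)
  labs <- if (k == 2) c("low", "high") else sprintf("C%d", seq_len(k))
  idx <- ceiling(k * rank(x, ties.method = "first") / length(x))
  if (scale == "ordinal") {
    factor(labs[idx], levels = labs, ordered = TRUE)
  } else if (scale == "nominal") {
    factor(labs[idx], levels = sample(labs))
  } else {
    factor(labs[idx], levels = labs)
  }
}

#' Simulate a correlated pair of mixed-type variables
#'
#' Draws a bivariate standard normal pair with Pearson correlation `rho`, then
#' replaces each requested side by a quantile-categorized version in perfect
#' agreement ([categorize_quantile()]). This is the design used to validate
#' the variable similarity measures: the categorized variables should carry
#' the same amount of association as their quantitative parents.
#'
#' @param n Sample size.
#' @param rho Imposed Pearson correlation, in `[0, 1)`.
#' @param type_x,type_y Scale of each output variable: `"quantitative"`,
#'   `"ordinal"`, `"nominal"` or `"binary"`.
#' @param k_x,k_y Number of categories for categorized sides (default 4;
#'   binary always uses 2).
#' @param seed Optional integer seed.
#' @return A list with `data` (tibble with columns `x`, `y`), `spec`
#'   ([mixed_spec()]) and `quantitative` (the underlying normal pair).
#' @export
sim_correlated_pair <- function(n, rho, type_x = "quantitative", type_y = "quantitative",
                                k_x = 4, k_y = 4, seed = NULL) {
  stopifnot(rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x0 <- z1
  y0 <- rho * z1 + sqrt(1 - rho^2) * z2
  mk <- function(x, type, k) {
    if (type == "quantitative") x else categorize_quantile(x, k, type)
  }
  data <- tibble::tibble(x = mk(x0, type_x, k_x), y = mk(y0, type_y, k_y))
  spec <- mixed_spec(
    c("x", "y"), c(type_x, type_y),
    list(
      if (type_x == "quantitative") NULL else levels(data$x),
      if (type_y == "quantitative") NULL else levels(data$y)
    )
  )
  list(data = data, spec = spec, quantitative = tibble::tibble(x = x0, y = y0))
}

#' Simulate two groups of correlated variables
#'
#' Builds a p-variable multivariate normal dataset whose variables form two
#' equally sized groups. Within each group of size g, the target correlation
#' between variables a and b decays linearly with index distance from `rho`
#' down to 0: `corr(a, b) = rho * (1 - |a - b| / (g - 1))`. Between-group
#' correlations are 0, except that a random `noise_fraction` of the
#' inter-group entries is set to 0.5 (sampled without replacement,
#' symmetrically). If the assembled matrix is indefinite it is repaired to the
#' nearest positive semi-definite correlation matrix before sampling.
#'
#' A random `categorical_fraction` of the variables is then categorized in
#' perfect agreement ([categorize_quantile()]) with K drawn uniformly from
#' `k_range` and ordinal/nominal decided by a fair coin, so the true variable
#' grouping is preserved under categorization.
#'
#' @param n Number of samples.
#' @param p Number of variables (even).
#' @param rho Maximal within-group correlation, in `[0, 1)`.
#' @param noise_fraction Share of inter-group correlations set to 0.5.
#' @param categorical_fraction Share of variables categorized.
#' @param k_range Candidate category counts (default 2:8).
#' @param seed Optional integer seed.
#' @return A list with `data` (tibble), `spec`, `groups` (1/2 per variable),
#'   `quantitative` (pre-categorization numeric tibble), `sigma` (the
#'   sampled-from, possibly PSD-repaired correlation matrix) and
#'   `sigma_target` (the assembled target before repair).
#' @export
sim_two_groups <- function(n, p, rho, noise_fraction = 0, categorical_fraction = 0,
                           k_range = 2:8, seed = NULL) {
  stopifnot(p %% 2 == 0, rho >= 0, rho < 1)
  stopifnot(noise_fraction >= 0, noise_fraction <= 1)
  stopifnot(categorical_fraction >= 0, categorical_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- p / 2
  block <- diag(1, g)
  if (g > 1) {
    idx <- abs(outer(seq_len(g), seq_len(g), "-"))
    block <- rho * (1 - idx / (g - 1))
    diag(block) <- 1
  }
  sigma <- matrix(0, p, p)
  sigma[1:g, 1:g] <- block
  sigma[(g + 1):p, (g + 1):p] <- block
  m <- round(noise_fraction * g * g)
  if (m > 0) {
    pick <- sample(g * g, m)
    i <- (pick - 1) %% g + 1
    j <- (pick - 1) %/% g + 1 + g
    sigma[cbind(i, j)] <- 0.5
    sigma[cbind(j, i)] <- 0.5
  }
  target <- sigma
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-6) {
      stop("correlation structure infeasible after PSD repair", call. = FALSE)
    }
  }
  x <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
  colnames(x) <- sprintf("V%03d", seq_len(p))
  quant <- tibble::as_tibble(x)
  data <- quant
  scales <- rep("quantitative", p)
  n_cat <- round(categorical_fraction * p)
  if (n_cat > 0) {
    which_cat <- sort(sample(p, n_cat))
    for (j in which_cat) {
      k <- if (length(k_range) == 1) k_range else sample(k_range, 1)
      sc <- sample(c("ordinal", "nominal"), 1)
      data[[j]] <- categorize_quantile(data[[j]], k, sc)
      scales[j] <- sc
    }
  }
  spec <- mixed_spec(
    colnames(x), scales,
    lapply(data, function(col) if (is.factor(col)) levels(col) else NULL)
  )
  list(
    data = data, spec = spec,
    groups = rep(1:2, each = g),
    quantitative = quant, sigma = sigma, sigma_target = target
  )
}

#' Binarize a mixed table at the median
#'
#' Quantitative variables and ordinal variables (through their midranks) are
#' cut at the median (`<= median` becomes `"low"`); nominal variables are
#' collapsed to most-frequent category versus the rest (ties broken by level
#' order); binary variables pass through. A constant variable is dropped with
#' a warning.
#'
#' @inheritParams gower_dist
#' @return A list with the binarized `data` tibble and its all-binary `spec`.
#' @export
binarize_median <- function(data, spec = NULL) {
  cm <- compile_mixed(data, spec)
  out <- list()
  keep <- character()
  for (v in cm$vars) {
    x <- v$x
    obs <- x[!is.na(x)]
    if (length(unique(obs)) < 2) {
      warning("constant variable '", v$name, "' dropped", call. = FALSE)
      next
    }
    if (v$scale %in% c("quantitative", "ordinal")) {
      num <- ranked_values(x)
      med <- stats::median(num, na.rm = TRUE)
      b <- factor(ifelse(num <= med, "low", "high"), levels = c("low", "high"))
    } else if (v$scale == "binary" || length(unique(obs)) == 2) {
      b <- droplevels(factor(x))
    } else {
      counts <- table(x)
      top <- names(counts)[which.max(counts)] # which.max: first max = level order
      b <- factor(ifelse(as.character(x) == top, top, "other"),
        levels = c(top, "other")
      )
    }
    out[[v$name]] <- b
    keep <- c(keep, v$name)
  }
  if (length(keep) == 0) stop("no non-constant variables left", call. = FALSE)
  data_out <- tibble::as_tibble(out)
  list(
    data = data_out,
    spec = mixed_spec(keep, "binary", lapply(data_out, levels))
  )
}

#' Simple matching coefficient distance
#'
#' Distance between two binary vectors as the proportion of mismatching
#' positions (positions with a missing value on either side are skipped).
#'
#' @inheritParams gower_dist
#' @param axis Compare `"samples"` (rows) or `"variables"` (columns).
#' @return A [distance_matrix()] (`method = "matching"`).
#' @export
simple_matching_dist <- function(data, spec = NULL, axis = c("samples", "variables")) {
  axis <- match.arg(axis)
  cm <- compile_mixed(data, spec)
  n_lev <- vapply(cm$vars, function(v) length(unique(v$x[!is.na(v$x)])), integer(1))
  if (any(n_lev > 2)) {
    stop(
      "non-binary variable(s): ",
      paste(names(cm$vars)[n_lev > 2], collapse = ", "),
      call. = FALSE
    )
  }
  m <- vapply(cm$vars, function(v) as.character(v$x), character(cm$n))
  if (axis == "samples") {
    labs <- cm$ids
  } else {
    m <- t(m)
    labs <- names(cm$vars)
  }
  nr <- nrow(m)
  d <- matrix(0, nr, nr, dimnames = list(labs, labs))
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      cmp <- m[i, ] != m[j, ]
      d[i, j] <- d[j, i] <- mean(cmp, na.rm = TRUE)
    }
  }
  new_mixed_matrix(d, "distance", axis, "matching")
}

#' Run the variable-clustering simulation study
#'
#' For each replicate, simulates a two-group dataset ([sim_two_groups()]),
#' computes variable distance matrices with the requested methods, clusters
#' them with Ward linkage, cuts the trees at k = 2 and scores the recovered
#' grouping against the truth with the misclassification rate. The baselines
#' are the Euclidean distance on the pre-categorization quantitative data and
#' the simple matching distance on median-binarized data.
#'
#' Replicate r uses the child seed `seed + r`, so studies are reproducible and
#' can be partitioned across runs.
#'
#' @inheritParams sim_two_groups
#' @param replicates Number of simulated datasets.
#' @param methods Subset of `"ama"`, `"dcor"`, `"euclidean"`, `"binarized"`.
#' @param alpha Pre-test level passed to [ama_dist()].
#' @param seed Root seed (integer).
#' @return A tidy tibble with columns `replicate`, `method`, `mcr`, plus the
#'   root seed as attribute `seed`.
#' @export
run_variable_clustering_study <- function(replicates, n, p, rho,
                                          noise_fraction = 0,
                                          categorical_fraction = 0,
                                          methods = c("ama", "dcor", "euclidean", "binarized"),
                                          alpha = 0.05, k_range = 2:8, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  res <- purrr::map_dfr(seq_len(replicates), function(r) {
    sim <- sim_two_groups(n, p, rho,
      noise_fraction = noise_fraction,
      categorical_fraction = categorical_fraction,
      k_range = k_range, seed = seed + r
    )
    purrr::map_dfr(methods, function(mth) {
      d <- switch(mth,
        ama = suppressWarnings(ama_dist(sim$data, sim$spec, alpha = alpha)),
        dcor = suppressMessages(suppressWarnings(dcor_dist(sim$data, sim$spec))),
        euclidean = stats::dist(t(as.matrix(sim$quantitative))),
        binarized = {
          b <- suppressWarnings(binarize_median(sim$data, sim$spec))
          simple_matching_dist(b$data, b$spec, axis = "variables")
        }
      )
      tree <- cluster_tree(d, "ward")
      cl <- cut_clusters(tree, 2)
      keep <- match(cl$label, colnames(sim$quantitative))
      tibble::tibble(
        replicate = r, method = mth,
        mcr = misclassification_rate(sim$groups[keep], cl$cluster)
      )
    })
  })
  attr(res, "seed") <- seed
  res
}

#' Run the pairwise similarity validation study
#'
#' For each replicate, simulates a correlated pair ([sim_correlated_pair()])
#' and records, per requested method, the similarity between the two
#' variables: the association-measure coefficient (`"ama"`), the
#' bias-corrected generalized distance correlation (`"dcor"`, signed), or the
#' absolute Pearson correlation of the underlying quantitative pair
#' (`"pearson"`).
#'
#' @inheritParams sim_correlated_pair
#' @param replicates Number of simulated pairs.
#' @param methods Subset of `"ama"`, `"dcor"`, `"pearson"`.
#' @param alpha Pre-test level for the ama coefficients.
#' @param seed Root seed; replicate r uses `seed + r`.
#' @return A tidy tibble with columns `replicate`, `method`, `value`.
#' @export
run_pair_similarity_study <- function(replicates, n, rho,
                                      type_x = "quantitative", type_y = "quantitative",
                                      k_x = 4, k_y = 4,
                                      methods = c("ama", "dcor", "pearson"),
                                      alpha = 0.05, seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  purrr::map_dfr(seq_len(replicates), function(r) {
    sim <- sim_correlated_pair(n, rho, type_x, type_y, k_x, k_y, seed = seed + r)
    vals <- vapply(methods, function(mth) {
      switch(mth,
        ama = suppressWarnings(
          as.matrix(ama_similarity(sim$data, sim$spec, alpha = alpha))[1, 2]
        ),
        dcor = suppressWarnings(dcor_similarity(
          sim$data$x, sim$data$y,
          scale_x = sim$spec$scale[1], scale_y = sim$spec$scale[2]
        )),
        pearson = abs(stats::cor(sim$quantitative$x, sim$quantitative$y))
      )
    }, numeric(1))
    tibble::tibble(replicate = r, method = methods, value = vals)
  })
}
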