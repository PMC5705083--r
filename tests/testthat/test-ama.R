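test_that("spearman similarity handles monotone, antitone and tied cases", {
  expect_equal(spearman_similarity(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_similarity(1:3, c(30, 20, 10)), 1) # absolute value
  expect_equal(spearman_similarity(1:4, c(2, 1, 4, 3)), 0.6)
  expect_warning(s <- spearman_similarity(c(1, 1, 1), 1:3), "constant")
  expect_equal(s, 0)
  expect_warning(s2 <- spearman_similarity(c(1, NA, 3, NA), c(1, 2, NA, NA)), "fewer than 3")
  expect_equal(s2, 0)
})

test_that("Goodman-Kruskal gamma matches brute-force pair enumeration", {
  expect_equal(gk_gamma(matrix(c(10, 0, 0, 10), 2)), 1)
  expect_equal(gk_gamma(matrix(c(0, 10, 10, 0), 2)), -1)
  # [[4,2],[1,3]]: n_c = 12, n_d = 2
  expect_equal(gk_gamma(matrix(c(4, 1, 2, 3), 2)), 10 / 14)
  expect_warning(g0 <- gk_gamma(matrix(c(5, 0, 5, 0), 2)), "no concordant")
  expect_equal(g0, 0)

  set.seed(31)
  for (rep in 1:10) {
    x <- sample(1:4, 40, replace = TRUE)
    y <- sample(1:3, 40, replace = TRUE)
    oracle <- brute_gamma(x, y)
    tab <- table(x, y)
    cc <- mixedclust:::concordance_counts(tab)
    expect_equal(cc$n_c, oracle$n_c)
    expect_equal(cc$n_d, oracle$n_d)
    expect_equal(gk_gamma(tab), oracle$gamma)
  }
})

test_that("categories are ordered by mean response rank, ties stable", {
  # mean ranks: A = 1.5, B = 5.5, C = 3.5 -> A < C < B
  x <- factor(c("A", "A", "C", "C", "B", "B"))
  y <- c(1, 2, 3, 4, 5, 6)
  expect_equal(order_categories_by_response(x, y), c("A", "C", "B"))

  # already ordered means stay put
  expect_equal(order_categories_by_response(factor(c("A", "B")), c(1, 2)), c("A", "B"))

  # exact tie keeps original relative order
  xt <- factor(c("B", "B", "A", "A"), levels = c("B", "A"))
  expect_equal(order_categories_by_response(xt, c(1, 4, 2, 3)), c("B", "A"))

  expect_warning(
    ord <- order_categories_by_response(factor("A", levels = c("A", "Z")), 1),
    "dropped"
  )
  expect_equal(ord, "A")
})

test_that("nominal-vs-ranked gate reorders only on a significant pre-test", {
  y <- 1:30
  x <- factor(rep(c("A", "C", "B"), each = 10)) # A low, C middle, B high
  s <- nominal_vs_ranked_similarity(x, y)
  expect_true(attr(s, "gate"))
  # frozen from the oracle: |Pearson(midranks of y, tied scores of A<C<B)|
  expect_equal(as.numeric(s), 0.9433332613, tolerance = 1e-9)

  # independence: gate mostly closed, similarity near zero in median
  set.seed(77)
  vals <- replicate(100, {
    as.numeric(nominal_vs_ranked_similarity(
      factor(sample(LETTERS[1:4], 200, TRUE)), rnorm(200)
    ))
  })
  expect_lt(median(vals), 0.1)

  expect_warning(
    s1 <- nominal_vs_ranked_similarity(factor(rep("A", 10)), 1:10),
    "fewer than 2 categories"
  )
  expect_equal(as.numeric(s1), 0)
})

test_that("gate pass rate under independence is near alpha", {
  set.seed(99)
  gates <- replicate(500, {
    attr(nominal_vs_ranked_similarity(
      factor(sample(letters[1:3], 60, TRUE)), rnorm(60)
    ), "gate")
  })
  alpha <- 0.05
  se <- sqrt(alpha * (1 - alpha) / 500)
  expect_lt(abs(mean(gates) - alpha), 3 * se)
})

test_that("cross-table diagonalization maximizes |gamma|", {
  anti <- matrix(c(0, 5, 5, 0), 2)
  dg <- diagonalize_crosstab(anti)
  expect_equal(abs(attr(dg, "gamma")), 1)

  already <- matrix(c(5, 0, 0, 5), 2)
  dg2 <- diagonalize_crosstab(already)
  expect_equal(unclass(dg2)[1:2, 1:2], already, ignore_attr = TRUE)
  expect_equal(attr(dg2, "gamma"), 1)

  # shuffled 3x3 identity recovers a perfect ordering
  perm3 <- diag(c(7, 7, 7))[c(2, 3, 1), ]
  expect_equal(abs(attr(diagonalize_crosstab(perm3), "gamma")), 1)

  # exhaustive oracle on random 3x4 tables: no ordering beats the returned one
  set.seed(17)
  for (rep in 1:5) {
    tab <- matrix(rpois(12, 4), 3, 4)
    got <- abs(attr(diagonalize_crosstab(tab), "gamma"))
    best <- 0
    rp <- mixedclust:::lex_permutations(3)
    cp <- mixedclust:::lex_permutations(4)
    for (i in seq_len(nrow(rp))) {
      for (j in seq_len(nrow(cp))) {
        g <- abs(gk_gamma(tab[rp[i, ], cp[j, ]]))
        if (is.finite(g)) best <- max(best, g)
      }
    }
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("nominal-nominal similarity gates on the chi-square pre-test", {
  x <- factor(rep(c("a", "b"), each = 5))
  y_assoc <- factor(rep(c("v", "u"), each = 5)) # anti-diagonal table
  expect_equal(nominal_nominal_similarity(x, y_assoc), 1)

  x2 <- factor(rep(c("a", "b"), 10))
  y2 <- factor(rep(c("u", "u", "v", "v"), 5))
  tab <- table(x2, y2) # balanced, chi-square p = 1
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  expect_gte(p, 0.05)
  expect_equal(nominal_nominal_similarity(x2, y2), abs(gk_gamma(tab)))

  big <- factor(rep(c("a", "b", "c"), each = 50))
  expect_equal(nominal_nominal_similarity(big, big), 1)

  expect_warning(
    s <- nominal_nominal_similarity(factor(rep("a", 10)), factor(rep(c("u", "v"), 5))),
    "degenerate"
  )
  expect_equal(s, 0)
})

test_that("ama similarity matrix dispatches per scale pair", {
  set.seed(41)
  x <- rnorm(200)
  d <- tibble::tibble(
    q = x,
    o = categorize_quantile(x, 4, "ordinal")
  )
  spec <- mixed_spec(c("q", "o"), c("quantitative", "ordinal"), list(NULL, levels(d$o)))
  s <- ama_similarity(d, spec)
  expect_gte(s["q", "o"], 0.9) # quartile copy of itself
  expect_equal(diag(as.matrix(s)), c(q = 1, o = 1))

  # identical nominal variables are perfectly similar
  f <- factor(sample(letters[1:3], 50, TRUE))
  d2 <- tibble::tibble(f1 = f, f2 = f)
  s2 <- ama_similarity(d2, mixed_spec(c("f1", "f2"), "nominal"))
  expect_equal(s2["f1", "f2"], 1)

  # < 3 complete observations per pair -> 0 with warning
  d3 <- tibble::tibble(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2))
  expect_warning(
    s3 <- ama_similarity(d3, mixed_spec(c("a", "b"), "quantitative")),
    "complete observations"
  )
  expect_equal(s3["a", "b"], 0)
})

test_that("PSD projection repairs indefinite similarity matrices minimally", {
  s2 <- similarity_matrix(matrix(c(1, 0.4, 0.4, 1), 2))
  expect_equal(as.matrix(nearest_psd(s2)), as.matrix(s2)) # 2x2 always PSD

  expect_equal(as.matrix(nearest_psd(similarity_matrix(diag(3)))), diag(3), ignore_attr = TRUE)

  chain <- matrix(c(1, 0.9, 0, 0.9, 1, 0.9, 0, 0.9, 1), 3)
  expect_lt(min(eigen(chain, symmetric = TRUE)$values), 0)
  proj <- nearest_psd(similarity_matrix(chain))
  ev <- eigen(as.matrix(proj), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(diag(as.matrix(proj)), rep(1, 3), ignore_attr = TRUE)
  # the projection moves entries by less than the PSD violation magnitude
  viol <- sqrt(sum(pmin(eigen(chain, symmetric = TRUE)$values, 0)^2))
  expect_lt(norm(as.matrix(proj) - chain, "F"), 2 * viol + 1e-6)
})

test_that("ama distances are sqrt(1 - s') and metric", {
  toy <- random_mixed_data(40, 6, seed = 13)
  s <- suppressWarnings(ama_similarity(toy$data, toy$spec))
  sp <- nearest_psd(s)
  d <- suppressWarnings(ama_dist(toy$data, toy$spec))
  expect_equal(as.matrix(d), sqrt(pmax(1 - as.matrix(sp), 0)), tolerance = 1e-12)
  expect_lte(max_triangle_violation(d), 1e-9)
  expect_true(all(as.matrix(s) >= 0 & as.matrix(s) <= 1))
})
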