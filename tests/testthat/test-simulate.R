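test_that("quantile categorization is balanced and order-preserving", {
  set.seed(2)
  x <- rnorm(400)
  b <- categorize_quantile(x, 2, "binary")
  expect_equal(as.vector(table(b)), c(200, 200))
  expect_true(all(x[b == "low"] < min(x[b == "high"]) + 1e-12))
  o <- categorize_quantile(x, 8, "ordinal")
  expect_equal(as.vector(table(o)), rep(50, 8))
  expect_s3_class(o, "ordered")
  n <- categorize_quantile(x, 4, "nominal")
  expect_false(is.ordered(n))
  expect_setequal(levels(n), paste0("C", 1:4))
})

test_that("correlated pairs hit the imposed correlation", {
  cors <- vapply(1:50, function(r) {
    sim <- sim_correlated_pair(400, 0.95, seed = 1000 + r)
    cor(sim$quantitative$x, sim$quantitative$y)
  }, numeric(1))
  expect_lt(abs(median(cors) - 0.95), 0.03)

  null_cors <- vapply(1:50, function(r) {
    sim <- sim_correlated_pair(400, 0, seed = 2000 + r)
    abs(cor(sim$quantitative$x, sim$quantitative$y))
  }, numeric(1))
  expect_lt(median(null_cors), 0.06)

  sim <- sim_correlated_pair(40, 0.5, type_x = "binary", type_y = "nominal", seed = 5)
  expect_equal(as.vector(table(sim$data$x)), c(20, 20))
  expect_equal(sim$spec$scale, c("binary", "nominal"))
})

test_that("two-group datasets carry the declared correlation structure", {
  sim <- sim_two_groups(100, 50, 0.75, noise_fraction = 0, seed = 3)
  g <- 25
  # noise_fraction = 0: all inter-group target correlations are exactly 0
  expect_true(all(sim$sigma[1:g, (g + 1):50] == 0))
  # adjacent within-group pairs: target rho * (1 - 1/(g-1))
  adj <- mean(vapply(1:(g - 1), function(a) {
    cor(sim$quantitative[[a]], sim$quantitative[[a + 1]])
  }, numeric(1)))
  expect_lt(abs(adj - 0.75 * (1 - 1 / (g - 1))), 0.1)

  simc <- sim_two_groups(30, 100, 0.5, categorical_fraction = 0.5, seed = 4)
  expect_equal(sum(simc$spec$scale != "quantitative"), 50)
  expect_equal(simc$groups, rep(1:2, each = 50))

  simn <- sim_two_groups(20, 20, 0.5, noise_fraction = 0.2, seed = 6)
  inter <- simn$sigma_target[1:10, 11:20]
  expect_equal(sum(inter == 0.5), round(0.2 * 100))
})

test_that("median binarization follows the stated rules", {
  b <- binarize_median(tibble::tibble(q = c(1, 2, 3, 4)), mixed_spec("q", "quantitative"))
  expect_equal(as.character(b$data$q), c("low", "low", "high", "high"))

  f <- factor(c("u", "v", "u", "v"))
  b2 <- binarize_median(tibble::tibble(f = f), mixed_spec("f", "binary"))
  expect_equal(as.character(b2$data$f), as.character(f))

  expect_warning(
    b3 <- binarize_median(
      tibble::tibble(k = c(1, 1, 1), q = c(1, 2, 3)),
      mixed_spec(c("k", "q"), "quantitative")
    ),
    "constant"
  )
  expect_equal(names(b3$data), "q")

  # nominal: most frequent category (ties by level order) vs rest
  nom <- factor(c("a", "b", "b", "c"))
  b4 <- binarize_median(tibble::tibble(f = nom), mixed_spec("f", "nominal"))
  expect_equal(levels(b4$data$f), c("b", "other"))
  expect_equal(as.character(b4$data$f), c("other", "b", "b", "other"))
})

test_that("simple matching distance is the mismatch proportion", {
  d <- tibble::tibble(
    b1 = factor(c("x", "x", "y")),
    b2 = factor(c("u", "u", "v")),
    b3 = factor(c("p", "q", "q"))
  )
  m <- simple_matching_dist(d, axis = "samples")
  expect_equal(m[1, 2], 1 / 3) # b3 differs
  expect_equal(m[1, 1], 0)

  comp <- tibble::tibble(a = factor(c("x", "y")), b = factor(c("y", "x")))
  mv <- simple_matching_dist(comp, axis = "variables")
  expect_equal(mv["a", "b"], 1)

  eight <- tibble::tibble(
    r1 = factor(c(rep("a", 6), "b", "b")),
    r2 = factor(c(rep("a", 8)))
  )
  # 2 mismatches out of 8 positions
  expect_equal(simple_matching_dist(eight, axis = "variables")[1, 2], 0.25)

  expect_error(
    simple_matching_dist(tibble::tibble(f = factor(c("a", "b", "c"))), axis = "samples"),
    "non-binary"
  )
})

test_that("study runners are deterministic and tidy", {
  res1 <- run_variable_clustering_study(
    replicates = 2, n = 30, p = 10, rho = 0.75,
    categorical_fraction = 0.5, methods = c("dcor", "binarized"), seed = 42
  )
  res2 <- run_variable_clustering_study(
    replicates = 2, n = 30, p = 10, rho = 0.75,
    categorical_fraction = 0.5, methods = c("dcor", "binarized"), seed = 42
  )
  expect_identical(res1, res2)
  expect_named(res1, c("replicate", "method", "mcr"))
  expect_true(all(res1$mcr >= 0 & res1$mcr <= 0.5))

  pair <- run_pair_similarity_study(3, 50, 0.5,
    type_x = "ordinal", type_y = "binary",
    methods = c("ama", "pearson"), seed = 7
  )
  expect_equal(nrow(pair), 6)
  expect_true(all(pair$value >= 0 & pair$value <= 1))
})
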