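test_that("type-specific distances follow the per-scale metrics", {
  expect_equal(
    type_distances(factor(c("A", "B", "A")), "nominal"),
    matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  )
  expect_equal(type_distances(c(1, 4), "quantitative"), matrix(c(0, 3, 3, 0), 2))
  # ordinal L < M < H observed as (L, H, M): ranks 1, 3, 2
  o <- factor(c("L", "H", "M"), levels = c("L", "M", "H"), ordered = TRUE)
  d <- type_distances(o, "ordinal")
  expect_equal(d[1, 2], 2)
  expect_equal(d[1, 3], 1)
  expect_equal(d[2, 3], 1)
  expect_error(type_distances(c(1, NA), "quantitative"), "missing")
})

test_that("double centering matches hand evaluation and kills margins", {
  expect_equal(
    double_center(matrix(c(0, 2, 2, 0), 2)),
    matrix(c(-1, 1, 1, -1), 2)
  )
  expect_equal(double_center(matrix(0, 3, 3)), matrix(0, 3, 3))
  set.seed(3)
  m <- as.matrix(dist(rnorm(8)))
  a <- double_center(m)
  expect_lt(max(abs(rowSums(a))), 1e-10 * 8 * max(m))
  expect_lt(max(abs(colSums(a))), 1e-10 * 8 * max(m))
})

test_that("bias-corrected distance covariance matches the naive oracle", {
  z <- matrix(0, 5, 5)
  expect_equal(bias_corrected_dcov(z, z), 0)
  expect_error(bias_corrected_dcov(matrix(0, 3, 3), matrix(0, 3, 3)), "n >= 4")

  dk <- type_distances(c(1, 2, 3, 4), "quantitative")
  expect_gt(bias_corrected_dcov(dk, dk), 0)
  expect_equal(bias_corrected_dcov(dk, dk), naive_ucov(dk, dk), tolerance = 1e-12)

  dl <- type_distances(factor(c("A", "A", "B", "B")), "nominal")
  expect_equal(bias_corrected_dcov(dk, dl), naive_ucov(dk, dl), tolerance = 1e-12)
})

test_that("distance correlation normalization identities hold", {
  set.seed(8)
  x <- rnorm(30)
  dk <- type_distances(x, "quantitative")
  expect_equal(dcor_coefficient(dk, dk), 1)
  # |.| metric is sign-blind: y = -x has the identical distance matrix
  expect_equal(type_distances(-x, "quantitative"), dk)
  expect_equal(dcor_similarity(x, -x), 1)
  # normalization keeps the coefficient on the correlation scale
  y <- rnorm(30)
  dl <- type_distances(y, "quantitative")
  r <- dcor_coefficient(dk, dl)
  expect_true(r >= -1 && r <= 1)
  expect_equal(r, naive_dcor(dk, dl), tolerance = 1e-12)
  expect_warning(
    r0 <- dcor_coefficient(matrix(0, 6, 6), dl[1:6, 1:6]),
    "degenerate"
  )
  expect_equal(r0, 0)
})

test_that("production dcor equals the naive equation-level oracle", {
  for (seed in 1:10) {
    toy <- random_mixed_data(15, 4, seed = 100 + seed)
    d <- suppressMessages(suppressWarnings(dcor_dist(toy$data, toy$spec)))
    for (k in 1:3) {
      for (l in (k + 1):4) {
        dk <- naive_type_distances(toy$data[[k]], toy$spec$scale[k])
        dl <- naive_type_distances(toy$data[[l]], toy$spec$scale[l])
        expect_equal(1 - d[k, l], naive_dcor(dk, dl), tolerance = 1e-10)
      }
    }
  }
})

test_that("distance correlation is scale-invariant", {
  for (seed in 1:5) {
    toy <- random_mixed_data(20, 3, seed = 300 + seed)
    for (k in 1:2) {
      for (l in (k + 1):3) {
        dk <- type_distances(toy$data[[k]], toy$spec$scale[k])
        dl <- type_distances(toy$data[[l]], toy$spec$scale[l])
        norm_k <- if (max(dk) > 0) dk / max(dk) else dk
        norm_l <- if (max(dl) > 0) dl / max(dl) else dl
        expect_equal(
          dcor_coefficient(dk, dl),
          dcor_coefficient(norm_k, norm_l),
          tolerance = 1e-12
        )
      }
    }
  }
})

test_that("relabeling samples leaves dcor unchanged", {
  toy <- random_mixed_data(25, 4, seed = 55)
  d1 <- suppressMessages(suppressWarnings(dcor_dist(toy$data, toy$spec)))
  perm <- sample(25)
  d2 <- suppressMessages(suppressWarnings(dcor_dist(toy$data[perm, ], toy$spec)))
  expect_equal(as.matrix(d1), as.matrix(d2), tolerance = 1e-12)
})

test_that("dcor distance matrix handles duplicates, missingness and d > 1", {
  set.seed(12)
  x <- rnorm(40)
  d <- tibble::tibble(a = x, b = x, c = rnorm(40))
  dm <- suppressMessages(dcor_dist(d, mixed_spec(c("a", "b", "c"), "quantitative")))
  expect_equal(dm["a", "b"], 0, tolerance = 1e-12)
  # independent pair can have slightly negative correlation, so d may exceed 1
  expect_true(all(as.matrix(dm) >= 0))

  # pairwise-complete path agrees with direct computation on the subset
  dmiss <- d
  dmiss$c[1:3] <- NA
  dm2 <- suppressMessages(dcor_dist(dmiss, mixed_spec(c("a", "b", "c"), "quantitative")))
  expect_equal(dm2["a", "c"], 1 - dcor_similarity(x[-(1:3)], dmiss$c[-(1:3)]),
    tolerance = 1e-12
  )

  few <- tibble::tibble(a = c(1, 2, 3, NA, NA), b = c(NA, NA, 3, 4, 5))
  expect_error(
    dcor_dist(few, mixed_spec(c("a", "b"), "quantitative")),
    "< 4 complete"
  )
})
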