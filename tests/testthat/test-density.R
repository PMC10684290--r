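test_that("an empty point set yields an all-zero density map", {
  d <- make_density_map(point_set("e", 64, 64), sigma = 15)
  expect_equal(dim(d$values), c(64, 64))
  expect_true(all(d$values == 0))
  expect_equal(sum(d$values), 0)
})

test_that("one interior Gaussian bump integrates to one object", {
  # oracle: numeric integration of the discretized isotropic Gaussian over
  # the full plane is the separable product of two 1-D sums, each ~1
  sigma <- 15
  g1 <- sum(dnorm(-300:300, mean = 0.3, sd = sigma))
  expect_lt(abs(g1^2 - 1), 1e-6)
  d <- make_density_map(point_set("c", 256, 256, cbind(128, 128)), sigma)
  expect_lt(abs(sum(d$values) - 1), 1e-3)
})

test_that("density sum matches point count for interior points", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:15, 1)
    sigma <- 4
    ps <- random_point_set("r", 96, 96, n, margin = 4 * sigma)
    d <- make_density_map(ps, sigma)
    expect_lt(abs(sum(d$values) - n) / n, 0.01)
    expect_true(all(d$values >= 0))
  }
})

test_that("invalid density-map inputs are rejected", {
  expect_error(point_set("b", 32, 32, cbind(40, 10)), "outside")
  ps <- point_set("b", 32, 32, cbind(10, 10))
  expect_error(make_density_map(ps, sigma = 0), "positive")
  expect_error(make_density_map(ps, sigma = -2), "positive")
})

test_that("block downsampling sums blocks and preserves totals exactly", {
  expect_identical(downsample_sum(density_map(matrix(1:16, 4, 4)), 1)$values,
                   density_map(matrix(1:16, 4, 4))$values)
  d <- downsample_sum(density_map(matrix(1, 4, 4)), 2)
  expect_equal(d$values, matrix(4, 2, 2))
  expect_equal(d$resolution_divisor, 2L)
  set.seed(5)
  v <- matrix(runif(64 * 48), 64, 48)
  d8 <- downsample_sum(density_map(v), 8)
  expect_equal(dim(d8$values), c(8, 6))
  expect_equal(sum(d8$values), sum(v))
  # oracle on one random block
  expect_equal(d8$values[2, 3], sum(v[9:16, 17:24]))
  expect_error(downsample_sum(density_map(matrix(0, 5, 8)), 2), "divisible")
})

test_that("threshold quantile rule follows the ascending-sequence index", {
  # {d_p} = (0.1, 0.2, 0.3, 0.4): S = 0.5 -> index ceil(2) -> 0.2
  d <- density_map(matrix(c(0.1, 0.2, 0.3, 0.4, 0, 0), 2, 3))
  th <- compute_thresholds(list(d), c(0, 0.5, 1))
  expect_equal(th$thresholds, c(0.1, 0.2, 0.4))
  expect_equal(th$n_levels, 2L)
  # S = 0 maps to the smallest nonzero value
  th4 <- compute_thresholds(list(d), c(0, 0.33, 0.66, 1))
  expect_equal(th4$thresholds[1], 0.1)
  expect_equal(th4$thresholds[4], 0.4)
  expect_equal(th4$n_levels, 3L)
})

test_that("constant nonzero values give constant thresholds", {
  d <- density_map(matrix(c(0, 0.7, 0.7, 0.7), 2, 2))
  th <- compute_thresholds(list(d), c(0, 0.33, 0.66, 1))
  expect_true(all(th$thresholds == 0.7))
})

test_that("thresholds are permutation-invariant and need nonzero data", {
  set.seed(7)
  maps <- lapply(1:4, function(i) density_map(matrix(runif(36) * (runif(36) > 0.4), 6, 6)))
  th1 <- compute_thresholds(maps)
  th2 <- compute_thresholds(rev(maps))
  # shuffling values inside a map must not matter either
  shuf <- lapply(maps, function(d) {
    v <- d$values
    density_map(matrix(sample(as.vector(v)), nrow(v), ncol(v)))
  })
  th3 <- compute_thresholds(shuf)
  expect_equal(th1$thresholds, th2$thresholds)
  expect_equal(th1$thresholds, th3$thresholds)
  expect_error(compute_thresholds(list(density_map(matrix(0, 4, 4)))),
               "degenerate")
})

test_that("level targets realize the interval rule", {
  # effective upper bounds 0.2 / 0.3 / 0.4 (the S=0 threshold only anchors
  # the sequence; the lowest interval opens at 0): density 0.25 -> level 2
  th <- structure(list(quantile_positions = c(0, 0.33, 0.66, 1),
                       thresholds = c(0.05, 0.2, 0.3, 0.4), n_levels = 3L),
                  class = "threshold_set")
  d <- density_map(matrix(c(0.25, 0, 0.05, 0.31), 2, 2), 8L)
  lt <- make_level_targets(d, th)
  expect_equal(lt$maps[1, 1, ], c(0, 1, 0))  # 0.25 in (0.2, 0.3]
  expect_equal(lt$maps[2, 1, ], c(0, 0, 0))  # exact zero is background
  expect_equal(lt$maps[1, 2, ], c(1, 0, 0))  # 0.05 in (0, 0.2]
  expect_equal(lt$maps[2, 2, ], c(0, 0, 1))  # 0.31 in (0.3, 0.4]
  expect_true(all(lt$validity == 1))
  expect_identical(lt$source, "ground_truth")
})

test_that("an all-zero density map has all-background level targets", {
  th <- compute_thresholds(list(density_map(matrix(c(0, 1, 2, 3), 2, 2))))
  lt <- make_level_targets(density_map(matrix(0, 4, 4), 8L), th)
  expect_true(all(lt$maps == 0))
})

test_that("vectorized level targets match the per-pixel loop oracle", {
  set.seed(23)
  for (rep in 1:8) {
    v <- matrix(runif(256, 0, 0.5) * (runif(256) > 0.3), 16, 16)
    if (all(v == 0)) v[1, 1] <- 0.2
    th <- compute_thresholds(list(density_map(v)))
    lt <- make_level_targets(density_map(v, 8L), th)
    expect_equal(lt$maps, level_targets_oracle(v, th$thresholds))
    # mutual exclusion: at most one level per pixel
    expect_true(all(apply(lt$maps, c(1, 2), sum) <= 1))
  }
})

test_that("raising a pixel's density never lowers its level index", {
  th <- structure(list(quantile_positions = c(0, 0.33, 0.66, 1),
                       thresholds = c(0.1, 0.2, 0.3, 0.4), n_levels = 3L),
                  class = "threshold_set")
  level_of <- function(x) {
    lt <- make_level_targets(density_map(matrix(x, 1, 1), 8L), th)
    idx <- which(lt$maps[1, 1, ] == 1)
    if (length(idx) == 0) {
      if (x > 0.4) 4L else 0L  # above-top treated as beyond the last level
    } else {
      idx
    }
  }
  xs <- sort(runif(60, 0, 0.5))
  levels <- vapply(xs, level_of, 0L)
  expect_true(all(diff(levels) >= 0))
})

test_that("threshold count inconsistent with n_levels is rejected", {
  th <- structure(list(quantile_positions = c(0, 1),
                       thresholds = c(0.1, 0.2), n_levels = 3L),
                  class = "threshold_set")
  expect_error(make_level_targets(density_map(matrix(0, 2, 2), 8L), th),
               "inconsistent")
})
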