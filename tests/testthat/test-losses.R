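test_that("masked binary cross-entropy matches hand-evaluated cases", {
  # one pixel, k = 2, target (1, 0), predictions (0.5, 0.5):
  # -(log 0.5 + log 0.5) / 2 = log 2
  probs <- array(0.5, dim = c(1, 1, 2))
  maps <- array(c(1, 0), dim = c(1, 1, 2))
  t <- targets_from_maps(maps)
  expect_equal(cross_entropy_loss(outputs_from_probs(probs), t), log(2),
               tolerance = 1e-6)
  # confident correct predictions at the clip bound are near-zero loss
  eps <- 1e-8
  conf <- array(c(1 - eps, eps), dim = c(1, 1, 2))
  expect_lt(cross_entropy_loss(outputs_from_probs(conf), t, eps), 1e-6)
})

test_that("invalid pixels contribute nothing to the cross-entropy", {
  set.seed(9)
  probs <- array(runif(2 * 3 * 2), dim = c(2, 3, 2))
  maps <- array(0, dim = c(2, 3, 2))
  maps[, , 1] <- matrix(c(1, 0, 1, 0, 0, 0), 2, 3)
  validity <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3)
  t <- level_targets(maps, validity, "pseudo_label")
  l1 <- cross_entropy_loss(outputs_from_probs(probs), t)
  flipped <- probs
  flipped[2, 1, ] <- 1 - flipped[2, 1, ]  # an invalid pixel
  flipped[1, 3, ] <- 1 - flipped[1, 3, ]  # the other invalid pixel
  expect_equal(cross_entropy_loss(outputs_from_probs(flipped), t), l1)
  # all-invalid: defined 0 with a warning
  t0 <- level_targets(maps * 0, validity * 0, "pseudo_label")
  expect_warning(l0 <- cross_entropy_loss(outputs_from_probs(probs), t0),
                 "valid")
  expect_equal(l0, 0)
})

test_that("cross-entropy decreases along interpolation toward the target", {
  set.seed(13)
  maps <- array(rbinom(32, 1, 0.3), dim = c(4, 4, 2))
  maps[, , 2] <- maps[, , 2] * (1 - maps[, , 1])
  t <- targets_from_maps(maps)
  start <- array(runif(32, 0.2, 0.8), dim = c(4, 4, 2))
  losses <- vapply(seq(0, 0.95, by = 0.05), function(a) {
    cross_entropy_loss(outputs_from_probs(start + a * (maps - start)), t)
  }, 0)
  expect_true(all(diff(losses) < 0))
})

test_that("cosine similarity closed forms hold", {
  expect_equal(cosine_similarity(c(2, 3), c(2, 3)), 1, tolerance = 1e-7)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-7)
  expect_equal(cosine_similarity(c(0, 0), c(1, 1)), 0)
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("density difference loss matches its worked example", {
  # k = 2, 2x2 disjoint one-hot targets, predictions equal to targets:
  # per level one matching unit column (S = 1) and one all-zero column
  # (S = 0), so L_max = -(1/2) * 2 = -1 and L_min = 0
  m1 <- matrix(c(1, 1, 0, 0), 2, 2)  # column 1 foreground
  m2 <- matrix(c(0, 0, 1, 1), 2, 2)  # column 2 foreground
  maps <- array(c(m1, m2), dim = c(2, 2, 2))
  t <- targets_from_maps(maps)
  out <- outputs_from_probs(maps)
  l <- density_difference_loss(out, t)
  expect_equal(attr(l, "l_max"), -1.0, tolerance = 1e-6)
  expect_equal(attr(l, "l_min"), 0.0, tolerance = 1e-6)
  expect_equal(as.numeric(l), -1.0, tolerance = 1e-6)
  # swapping the predicted maps mismatches every level and raises the loss
  swapped <- outputs_from_probs(maps[, , c(2, 1)])
  expect_gt(as.numeric(density_difference_loss(swapped, t)), as.numeric(l))
  # all-zero predictions and targets: epsilon-dominated, exactly 0
  zero <- array(0, dim = c(2, 2, 2))
  expect_equal(as.numeric(density_difference_loss(outputs_from_probs(zero),
                                                  targets_from_maps(zero))), 0)
})

test_that("vectorized density difference loss equals the brute-force loop", {
  set.seed(17)
  for (rep in 1:150) {
    k <- sample(2:3, 1)
    probs <- array(runif(16 * k), dim = c(4, 4, k))
    maps <- array(0, dim = c(4, 4, k))
    lev <- matrix(sample(0:k, 16, replace = TRUE), 4, 4)
    for (j in seq_len(k)) maps[, , j] <- as.numeric(lev == j)
    if (rep %% 2 == 0) {
      validity <- matrix(rbinom(16, 1, 0.8), 4, 4)
      t <- level_targets(maps * array(rep(validity, k), dim = dim(maps)),
                         validity, "pseudo_label")
      ora <- dd_oracle(probs, t$maps, validity)
    } else {
      t <- targets_from_maps(maps)
      ora <- dd_oracle(probs, maps)
    }
    l <- density_difference_loss(outputs_from_probs(probs), t)
    expect_equal(as.numeric(l), ora$l_dd, tolerance = 1e-10)
    expect_equal(attr(l, "l_max"), ora$l_max, tolerance = 1e-10)
  }
})

test_that("identity assignment minimizes the loss over map permutations", {
  set.seed(19)
  k <- 3
  maps <- array(0, dim = c(4, 4, k))
  lev <- matrix(sample(1:k, 16, replace = TRUE), 4, 4)
  for (j in seq_len(k)) maps[, , j] <- as.numeric(lev == j)
  t <- targets_from_maps(maps)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  losses <- vapply(perms, function(p) {
    as.numeric(density_difference_loss(outputs_from_probs(maps[, , p]), t))
  }, 0)
  expect_equal(which.min(losses), 1L)
})

test_that("density MSE follows the summed squared difference", {
  a <- density_map(matrix(c(1, 2), 1, 2), 8L)
  b <- density_map(matrix(c(0, 0), 1, 2), 8L)
  expect_equal(mse_density_loss(a, b), 5.0)
  expect_equal(mse_density_loss(b, a), 5.0)  # symmetric
  expect_equal(mse_density_loss(a, a), 0)
  expect_error(mse_density_loss(a, density_map(matrix(0, 2, 2), 8L)), "shape")
})

test_that("loss composition routes labeled and unlabeled terms correctly", {
  w <- loss_weights()
  expect_equal(w$lambda1, 0.01)
  expect_equal(w$lambda2, 1)
  expect_equal(w$lambda3, 0.01)
  expect_equal(w$lambda4, 1)
  lab <- compose_losses(list(mse = 2, ce = 1, dd = -1), w, TRUE)
  expect_equal(lab$labeled_total, 2 + 0.01 * 1 + 1 * (-1))
  expect_equal(lab$labeled_total, 1.01)
  expect_equal(lab$total, lab$labeled_total)
  unl <- compose_losses(list(ce = 1, dd = -1), w, FALSE)
  expect_equal(unl$mse, 0)
  expect_equal(unl$unlabeled_total, 0.01 * 1 - 1)
  expect_equal(unl$total, unl$unlabeled_total)
  expect_error(compose_losses(list(mse = 1, ce = 0, dd = 0), w, FALSE),
               "contract")
})

test_that("loss composition is linear in each component", {
  w <- loss_weights(lambda1 = 0.5, lambda2 = 2, lambda3 = 0.1, lambda4 = 3)
  base <- compose_losses(list(mse = 1, ce = 1, dd = 1), w, TRUE)
  for (part in c("mse", "ce", "dd")) {
    p <- list(mse = 1, ce = 1, dd = 1)
    p[[part]] <- 3
    delta <- compose_losses(p, w, TRUE)$labeled_total - base$labeled_total
    coef <- switch(part, mse = 1, ce = w$lambda1, dd = w$lambda2)
    expect_equal(delta, 2 * coef)
  }
})
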