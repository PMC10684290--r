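test_that("the learning-rate schedule halves every period", {
  expect_equal(learning_rate_schedule(0, 1e-6, 30), 1e-6)
  expect_equal(learning_rate_schedule(29, 1e-6, 30), 1e-6)
  expect_equal(learning_rate_schedule(30, 1e-6, 30), 5e-7)
  expect_equal(learning_rate_schedule(65, 1e-6, 30), 2.5e-7)
  expect_equal(learning_rate_schedule(119, 1e-6, 30), 1.25e-7)
})

test_that("dataset splitting is proportional, disjoint, exhaustive and seeded", {
  ids <- sprintf("im%03d", 1:300)
  sp <- split_dataset(ids, c(3, 1, 1), seed = 4)
  expect_equal(lengths(sp), c(train = 180L, val = 60L, test = 60L))
  expect_equal(sort(unname(unlist(sp))), sort(ids))
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  expect_identical(split_dataset(ids, c(3, 1, 1), seed = 4), sp)
  expect_false(identical(split_dataset(ids, c(3, 1, 1), seed = 5), sp))
  # largest-remainder rounding on 5 ids
  expect_equal(lengths(split_dataset(letters[1:5], c(3, 1, 1), seed = 1)),
               c(train = 3L, val = 1L, test = 1L))
  expect_error(split_dataset(letters[1:2], c(3, 1, 1)), "fewer ids")
  expect_error(split_dataset(c("a", "a", "b")), "unique")
})

test_that("augmentation crops, re-references and flips points correctly", {
  img <- array(runif(100 * 100 * 3), c(100, 100, 3))
  ps <- point_set("a", 100, 100, cbind(x = c(10, 50, 99), y = c(5, 50, 99)))
  # identity crop (augment itself accepts any crop size; the divisible-by-8
  # constraint belongs to train_config used with the network)
  cfg_id <- structure(list(crop_size = c(100L, 100L), flip_probability = 0),
                      class = "train_config")
  a <- augment(img, ps, cfg_id)
  expect_equal(n_points(a$points), 3)           # full-frame crop drops nothing
  expect_equal(a$points$points, ps$points)
  # deterministic flip: x -> w - 1 - x
  cfg_flip <- structure(list(crop_size = c(100L, 100L), flip_probability = 1),
                        class = "train_config")
  f <- augment(img, ps, cfg_flip)
  expect_equal(f$points$points[1, "x"], c(x = 89))
  expect_equal(f$image[1, , 1], rev(img[1, , 1]))
  # involution: flipping twice with the same full crop restores everything
  ff <- augment(f$image, f$points, cfg_flip)
  expect_equal(ff$points$points, ps$points)
  expect_equal(ff$image, img)
})

test_that("cropped augmentation keeps only in-crop points, re-referenced", {
  set.seed(77)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ps <- point_set("a", 64, 64, cbind(x = runif(30, 0, 63.9), y = runif(30, 0, 63.9)))
  cfg <- train_config(crop_size = c(32, 32), flip_probability = 0)
  for (rep in 1:10) {
    a <- augment(img, ps, cfg)
    expect_equal(dim(a$image), c(32, 32, 3))
    if (n_points(a$points) > 0) {
      expect_true(all(a$points$points >= 0 & a$points$points < 32))
    }
  }
  # crop larger than image: centered pad fallback
  cfg_big <- train_config(crop_size = c(128, 128), flip_probability = 0)
  expect_message(big <- augment(img, ps, cfg_big), "pad")
  expect_equal(dim(big$image), c(128, 128, 3))
  expect_equal(n_points(big$points), 30)
})

make_toy_records <- function(n, seed, size = 64L) {
  spec <- scene_spec(image_size = c(size, size), n_clusters = c(1L, 3L),
                     berries_per_cluster = 8, cluster_sigma = c(3, 8),
                     berry_radius = c(2, 4), count_range = c(3L, 30L))
  seeds <- berrycount:::with_seed(seed, sample.int(1e6, n))
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(spec, seed = seeds[i], image_id = paste0("t", i))
    list(id = paste0("t", i), image = sc$image, points = sc$points)
  })
}

test_that("unlabeled steps route no gradient to the density head", {
  recs <- make_toy_records(1, seed = 3)
  net <- build_network(network_config(width_scale = 1 / 16), seed = 1)
  w <- loss_weights()
  st <- berrycount:::unlabeled_step(net, recs[[1]]$image, w,
                                    pseudo_label_config())
  expect_true(all(st$grads$head_density$W == 0))
  expect_true(all(st$grads$head_density$b == 0))
  expect_equal(st$breakdown$mse, 0)
  expect_equal(st$breakdown$labeled_total, 0)
  # a labeled step does reach the density head
  stl <- berrycount:::labeled_step(
    net, recs[[1]]$image, recs[[1]]$points,
    compute_thresholds(list(downsample_sum(
      make_density_map(recs[[1]]$points, 2), 8))), w, 2)
  expect_true(any(stl$grads$head_density$W != 0))
})

test_that("training is reproducible under a fixed seed and guards its contract", {
  recs <- make_toy_records(4, seed = 5)
  th <- compute_thresholds(lapply(recs[1:2], function(r) {
    downsample_sum(make_density_map(r$points, 2), 8)
  }))
  cfg <- train_config(epochs = 2L, initial_lr = 1e-3, crop_size = c(64, 64),
                      seed = 11)
  run <- function() {
    net <- build_network(network_config(width_scale = 1 / 16), seed = 11)
    train(net, recs[1:2],
          lapply(recs[3:4], function(r) r[c("id", "image")]),
          th, cfg = cfg, sigma = 2)
  }
  s1 <- run()
  s2 <- run()
  expect_identical(s1$history$total, s2$history$total)
  expect_identical(s1$network$params, s2$network$params)
  expect_error(train(build_network(network_config(width_scale = 1 / 16)),
                     list(), list(), th, cfg = cfg), "unsupervisable")
  expect_error(train(build_network(network_config(width_scale = 1 / 16)),
                     recs[1:2], lapply(recs[2:3], function(r) r[c("id", "image")]),
                     th, cfg = cfg), "disjoint")
})

test_that("labeled training MSE decreases over a short synthetic run", {
  recs <- make_toy_records(20, seed = 21)
  labeled <- recs[1:2]   # 10% labeled
  unlabeled <- lapply(recs[3:20], function(r) r[c("id", "image")])
  th <- compute_thresholds(lapply(labeled, function(r) {
    downsample_sum(make_density_map(r$points, 2), 8)
  }))
  cfg <- train_config(epochs = 20L, initial_lr = 1e-3, crop_size = c(64, 64),
                      seed = 2)
  net <- build_network(network_config(width_scale = 1 / 16), seed = 2)
  st <- train(net, labeled, unlabeled, th, cfg = cfg, sigma = 2)
  mse_per_epoch <- st$history$mse
  expect_lt(tail(mse_per_epoch, 1), mse_per_epoch[1])
})

test_that("the benefit harness trains both arms from one initialization", {
  r <- semi_supervised_benefit(seed = 99, n_images = 6, labeled_fraction = 0.2,
                               n_val = 2, epochs = 1)
  expect_equal(r$n_labeled, 1L)
  expect_true(is.finite(r$full_mae) && is.finite(r$label_only_mae))
  expect_equal(nrow(r$full$history), 1)
})
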