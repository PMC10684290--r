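#' Training configuration
#'
#' Defaults mirror the method's published protocol: batch size 1, Adam with
#' initial learning rate 1e-6 halved every 30 epochs, 120 epochs, random
#' 1296 x 864 crops and random horizontal flips. For desk-scale synthetic
#' runs, shrink `crop_size` and `epochs` and raise `initial_lr` to match the
#' tiny network (see the package vignette).
#'
#' @param epochs number of passes over the shuffled labeled+unlabeled union.
#' @param batch_size images per optimization step (the protocol uses 1).
#' @param initial_lr Adam learning rate at epoch 0.
#' @param lr_halving_period epochs between halvings of the learning rate.
#' @param crop_size `c(width, height)` of the random crop; both divisible
#'   by 8.
#' @param flip_probability probability of a horizontal flip per draw.
#' @param labeled_ratio fraction of training images carrying annotations
#'   (bookkeeping; the split itself is supplied by the caller).
#' @param seed integer seed controlling shuffling, cropping and flips.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, batch_size = 1L, initial_lr = 1e-6,
                         lr_halving_period = 30L, crop_size = c(1296L, 864L),
                         flip_probability = 0.5, labeled_ratio = NULL,
                         seed = 0L) {
  if (any(crop_size %% 8 != 0)) stop("crop dimensions must be divisible by 8")
  if (!is.null(labeled_ratio) &&
      !(labeled_ratio > 0 && labeled_ratio <= 1)) {
    stop("labeled_ratio must lie in (0, 1]")
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 crop_size = as.integer(crop_size),
                 flip_probability = flip_probability,
                 labeled_ratio = labeled_ratio, seed = as.integer(seed)),
            class = "train_config")
}

#' Stepwise-halved learning-rate schedule
#'
#' `lr(epoch) = initial_lr * 0.5 ^ floor(epoch / halving_period)` with
#' 0-based epochs, i.e. the rate is halved every `halving_period` epochs.
#'
#' @param epoch 0-based epoch index.
#' @param initial_lr learning rate at epoch 0.
#' @param halving_period epochs between halvings.
#' @return Numeric learning rate.
#' @examples
#' learning_rate_schedule(65, 1e-6, 30) # 2.5e-7
#' @export
learning_rate_schedule <- function(epoch, initial_lr = 1e-6,
                                   halving_period = 30L) {
  initial_lr * 0.5^floor(epoch / halving_period)
}

#' Seed-deterministic train/validation/test split
#'
#' Random, disjoint, exhaustive partition of the image ids with sizes
#' proportional to `ratios` using largest-remainder rounding (300 ids at
#' 3:1:1 give 180/60/60).
#'
#' @param image_ids character or integer vector of unique ids.
#' @param ratios positive weights, one per part (default 3:1:1).
#' @param seed integer seed.
#' @return List of id vectors named `train`, `val`, `test` (or `part1..n`
#'   when more than three ratios are given).
#' @export
split_dataset <- function(image_ids, ratios = c(3, 1, 1), seed = 0L) {
  if (anyDuplicated(image_ids)) stop("image ids must be unique")
  if (any(ratios <= 0)) stop("ratios must be positive")
  n <- length(image_ids)
  if (n < length(ratios)) stop("fewer ids than parts")
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- exact - sizes
    ord <- order(-frac, seq_along(frac)) # ties favor earlier parts
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1
  }
  shuffled <- with_seed(seed, sample(image_ids))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  parts <- lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0) image_ids[0] else shuffled[starts[i]:ends[i]]
  })
  names(parts) <- if (length(sizes) == 3) c("train", "val", "test")
  else paste0("part", seq_along(sizes))
  parts
}

#' Random crop and horizontal flip augmentation
#'
#' Takes a uniform crop of `cfg$crop_size` (width, height) from the image,
#' drops annotation points that fall outside it, re-references the survivors
#' to the crop origin, and applies a horizontal flip with probability
#' `cfg$flip_probability` (`x -> width - 1 - x`, 0-based pixel centers).
#' A crop equal to the image size is the identity crop; a crop larger than
#' the image falls back to a centered zero-pad (with a message). Randomness
#' comes from the current R RNG stream.
#'
#' @param image `H x W x 3` array.
#' @param points a [point_set()] or `NULL` (unlabeled image).
#' @param cfg a [train_config()].
#' @return List with `image` and `points` (possibly `NULL`).
#' @export
augment <- function(image, points, cfg = train_config()) {
  cw <- cfg$crop_size[1]; ch <- cfg$crop_size[2]
  H <- dim(image)[1]; W <- dim(image)[2]
  if (cw > W || ch > H) {
    message("crop exceeds image; using centered zero-pad")
    padded <- array(0, dim = c(max(ch, H), max(cw, W), dim(image)[3]))
    oy <- (dim(padded)[1] - H) %/% 2; ox <- (dim(padded)[2] - W) %/% 2
    padded[oy + seq_len(H), ox + seq_len(W), ] <- image
    if (!is.null(points) && n_points(points) > 0) {
      pts <- points$points
      points <- point_set(points$image_id, dim(padded)[2], dim(padded)[1],
                          cbind(x = pts[, "x"] + ox, y = pts[, "y"] + oy))
    } else if (!is.null(points)) {
      points <- point_set(points$image_id, dim(padded)[2], dim(padded)[1])
    }
    image <- padded
    H <- dim(image)[1]; W <- dim(image)[2]
  }
  ox <- if (W > cw) sample.int(W - cw + 1, 1) - 1L else 0L
  oy <- if (H > ch) sample.int(H - ch + 1, 1) - 1L else 0L
  img <- image[oy + seq_len(ch), ox + seq_len(cw), , drop = FALSE]
  if (!is.null(points)) {
    pts <- points$points
    keep <- pts[, "x"] >= ox & pts[, "x"] < ox + cw &
      pts[, "y"] >= oy & pts[, "y"] < oy + ch
    pts <- pts[keep, , drop = FALSE]
    pts[, "x"] <- pts[, "x"] - ox
    pts[, "y"] <- pts[, "y"] - oy
    points <- point_set(points$image_id, cw, ch, pts)
  }
  if (stats::runif(1) < cfg$flip_probability) {
    img <- img[, rev(seq_len(cw)), , drop = FALSE]
    if (!is.null(points) && n_points(points) > 0) {
      pts <- points$points
      # fractional coordinates in (cw-1, cw) would map just below 0; clamp
      pts[, "x"] <- pmax(cw - 1 - pts[, "x"], 0)
      points <- point_set(points$image_id, cw, ch, pts)
    }
  }
  list(image = img, points = points)
}

# ---- Adam optimizer over the nested parameter list ----

adam_init <- function(params) {
  zero_like <- function(p) list(W = p$W * 0, b = p$b * 0)
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (fld in c("W", "b")) {
      g <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[fld]] <- params[[nm]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# one labeled optimization step; returns loss breakdown and gradients
labeled_step <- function(net, image, points, thresholds, weights, sigma,
                         use_dd = TRUE) {
  gt_full <- make_density_map(points, sigma)
  gt8 <- downsample_sum(gt_full, net$config$downsample_factor)
  out <- forward(net, image, cache = TRUE)
  lt <- make_level_targets(gt8, thresholds)
  diff <- out$density$values - gt8$values
  mse <- sum(diff^2)
  ce <- ce_loss_grad(out$level_probs, lt, weights$epsilon)
  d_probs <- weights$lambda1 * ce$dprobs
  dd_loss <- 0
  if (use_dd) {
    dd <- dd_loss_grad(out$level_probs, lt, weights$epsilon)
    dd_loss <- dd$loss
    d_probs <- d_probs + weights$lambda2 * dd$dprobs
  }
  grads <- net_backward(net, out, 2 * diff, d_probs)
  bd <- compose_losses(list(mse = mse, ce = ce$loss, dd = dd_loss), weights,
                       image_is_labeled = TRUE)
  list(breakdown = bd, grads = grads)
}

# one unlabeled step: pseudo-labels from the model's own predictions;
# the density head receives no gradient
unlabeled_step <- function(net, image, weights, pl_cfg, use_dd = TRUE) {
  out <- forward(net, image, cache = TRUE)
  pl <- generate_pseudo_labels(out, pl_cfg)
  # early on no pixel may be confident; the zero-valid warning is routine here
  ce <- suppressWarnings(ce_loss_grad(out$level_probs, pl, weights$epsilon))
  d_probs <- weights$lambda3 * ce$dprobs
  dd_loss <- 0
  if (use_dd) {
    dd <- dd_loss_grad(out$level_probs, pl, weights$epsilon)
    dd_loss <- dd$loss
    d_probs <- d_probs + weights$lambda4 * dd$dprobs
  }
  d_density <- out$density$values * 0
  grads <- net_backward(net, out, d_density, d_probs)
  bd <- compose_losses(list(ce = ce$loss, dd = dd_loss), weights,
                       image_is_labeled = FALSE)
  list(breakdown = bd, grads = grads)
}

validate_mae <- function(net, validation) {
  if (length(validation) == 0) return(NA_real_)
  errs <- vapply(validation, function(rec) {
    pred <- predict_count(net, rec$image)$count
    abs(pred - n_points(rec$points))
  }, 0)
  mean(errs)
}

#' Semi-supervised training loop
#'
#' Trains the network with batch size 1 on the shuffled union of labeled and
#' unlabeled images: labeled steps optimize the density MSE plus the
#' weighted auxiliary cross-entropy and density-difference terms against
#' ground-truth level targets; unlabeled steps optimize only the auxiliary
#' terms against mutual-exclusion-corrected pseudo-labels regenerated at
#' every step, so the density regressor never receives unlabeled gradients.
#' Each image is seen once per epoch; the Adam learning rate follows
#' [learning_rate_schedule()]. When a validation set is given, per-epoch MAE
#' is tracked and the best-MAE parameters are retained.
#'
#' @param net a [build_network()] handle.
#' @param labeled list of records `list(id, image, points)`.
#' @param unlabeled list of records `list(id, image)`; may be empty for a
#'   labels-only ablation run.
#' @param thresholds a `threshold_set` computed from the labeled images
#'   only.
#' @param weights a [loss_weights()].
#' @param cfg a [train_config()].
#' @param validation optional list of annotated records for per-epoch MAE.
#' @param sigma Gaussian width used for ground-truth density maps.
#' @param pl_cfg a [pseudo_label_config()].
#' @param use_dd include the density-difference loss (off reproduces the
#'   "without L_DD" ablation axis).
#' @param verbose print per-epoch summaries.
#' @return A `train_state` list: `network` (final), `best_network`,
#'   `best_val_mae`, `best_epoch`, and `history` (per-epoch data frame with
#'   lr, mean loss components and validation MAE).
#' @export
train <- function(net, labeled, unlabeled = list(), thresholds,
                  weights = loss_weights(), cfg = train_config(),
                  validation = NULL, sigma = 15,
                  pl_cfg = pseudo_label_config(), use_dd = TRUE,
                  verbose = FALSE) {
  if (length(labeled) == 0) stop("empty labeled set: training is unsupervisable")
  lab_ids <- vapply(labeled, `[[`, "", "id")
  unl_ids <- vapply(unlabeled, function(r) as.character(r$id), "")
  if (length(intersect(lab_ids, unl_ids)) > 0) {
    stop("labeled and unlabeled sets must be disjoint")
  }
  set.seed(cfg$seed)
  state <- adam_init(net$params)
  n_lab <- length(labeled); n_unl <- length(unlabeled)
  hist <- vector("list", cfg$epochs)
  best_mae <- Inf; best_epoch <- NA_integer_; best_params <- NULL
  for (epoch in seq_len(cfg$epochs) - 1L) {
    lr <- learning_rate_schedule(epoch, cfg$initial_lr, cfg$lr_halving_period)
    order_idx <- sample(n_lab + n_unl)
    ep <- c(mse = 0, ce = 0, dd = 0, total = 0)
    for (ii in order_idx) {
      if (ii <= n_lab) {
        rec <- labeled[[ii]]
        aug <- augment(rec$image, rec$points, cfg)
        st <- labeled_step(net, aug$image, aug$points, thresholds, weights,
                           sigma, use_dd)
      } else {
        rec <- unlabeled[[ii - n_lab]]
        aug <- augment(rec$image, NULL, cfg)
        st <- unlabeled_step(net, aug$image, weights, pl_cfg, use_dd)
      }
      upd <- adam_step(net$params, st$grads, state, lr)
      net$params <- upd$params
      state <- upd$state
      ep <- ep + c(st$breakdown$mse, st$breakdown$ce, st$breakdown$dd,
                   st$breakdown$total)
    }
    ep <- ep / (n_lab + n_unl)
    vm <- if (is.null(validation)) NA_real_ else validate_mae(net, validation)
    if (!is.na(vm) && vm < best_mae) {
      best_mae <- vm; best_epoch <- epoch; best_params <- net$params
    }
    hist[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                     mse = ep[1], ce = ep[2], dd = ep[3],
                                     total = ep[4], val_mae = vm)
    if (verbose) {
      cat(sprintf("epoch %3d  lr %.2e  loss %.4f  val MAE %s\n", epoch, lr,
                  ep[4], ifelse(is.na(vm), "-", sprintf("%.2f", vm))))
    }
  }
  best_net <- net
  if (!is.null(best_params)) best_net$params <- best_params
  structure(list(network = net, best_network = best_net,
                 best_val_mae = if (is.finite(best_mae)) best_mae else NA_real_,
                 best_epoch = best_epoch,
                 history = do.call(rbind, hist)),
            class = "train_state")
}

#' Toy-scale semi-supervised benefit experiment
#'
#' Directional check of the semi-supervised mechanism: on one seeded
#' synthetic dataset, trains the identical tiny network twice from the same
#' initialization — once with the full objective on labeled plus unlabeled
#' images, once labels-only — and compares best validation MAE. The scene
#' scale (128 x 128, counts 8-50) is a quarter-area analogue of the default
#' test scene so both arms finish in minutes on one CPU; it checks the
#' direction of the effect, not field-scale magnitudes.
#'
#' @param seed integer seed controlling data, initialization and training.
#' @param n_images training images (10 percent of them labeled).
#' @param labeled_fraction labeled share of the training images.
#' @param n_val annotated held-out images for validation MAE.
#' @param epochs training epochs per arm.
#' @param width_scale tiny-network channel multiplier.
#' @param sigma density-map Gaussian width, scaled to the synthetic berry
#'   radius.
#' @param initial_lr Adam learning rate for the tiny runs.
#' @param verbose print per-epoch progress.
#' @return List with `full_mae`, `label_only_mae` (best validation MAE of
#'   each arm), `n_labeled`, and the two `train_state`s.
#' @export
semi_supervised_benefit <- function(seed, n_images = 40L,
                                    labeled_fraction = 0.1, n_val = 8L,
                                    epochs = 30L, width_scale = 1 / 16,
                                    sigma = 4, initial_lr = 1e-3,
                                    verbose = FALSE) {
  spec <- scene_spec(image_size = c(128L, 128L), n_clusters = c(2L, 6L),
                     berries_per_cluster = 12, cluster_sigma = c(4, 10),
                     berry_radius = c(2, 4), count_range = c(8L, 50L))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      n_images + n_val))
  recs <- lapply(seq_len(n_images + n_val), function(i) {
    sc <- generate_scene(spec, seed = seeds[i],
                         image_id = sprintf("img_%03d", i))
    list(id = sprintf("img_%03d", i), image = sc$image, points = sc$points)
  })
  validation <- recs[n_images + seq_len(n_val)]
  train_recs <- recs[seq_len(n_images)]
  n_labeled <- max(1L, floor(n_images * labeled_fraction))
  lab_idx <- with_seed(seed + 1L, sort(sample(n_images, n_labeled)))
  labeled <- train_recs[lab_idx]
  unlabeled <- lapply(train_recs[-lab_idx], function(r) r[c("id", "image")])
  maps8 <- lapply(labeled, function(r) {
    downsample_sum(make_density_map(r$points, sigma), 8L)
  })
  th <- compute_thresholds(maps8)
  cfg <- train_config(epochs = epochs, initial_lr = initial_lr,
                      lr_halving_period = 30L,
                      crop_size = spec$image_size, seed = seed)
  net0 <- build_network(network_config(width_scale = width_scale), seed = seed)
  full <- train(net0, labeled, unlabeled, th, cfg = cfg, sigma = sigma,
                validation = validation, verbose = verbose)
  label_only <- train(net0, labeled, list(), th, cfg = cfg, sigma = sigma,
                      validation = validation, verbose = verbose)
  list(full_mae = full$best_val_mae, label_only_mae = label_only$best_val_mae,
       n_labeled = n_labeled, full = full, label_only = label_only)
}
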