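#' Project configuration
#'
#' Bundles every tunable of the pipeline — density-map sigma, quantile
#' positions, network, training, loss-weight, pseudo-label and scene
#' settings — into one object that round-trips losslessly through YAML.
#'
#' @param sigma Gaussian kernel width for ground-truth density maps.
#' @param quantile_positions quantile positions defining the density levels.
#' @param network a [network_config()].
#' @param train a [train_config()].
#' @param weights a [loss_weights()].
#' @param pseudo a [pseudo_label_config()].
#' @param scene a [scene_spec()].
#' @return An object of class `project_config`.
#' @export
project_config <- function(sigma = 15,
                           quantile_positions = c(0, 0.33, 0.66, 1),
                           network = network_config(),
                           train = train_config(),
                           weights = loss_weights(),
                           pseudo = pseudo_label_config(),
                           scene = scene_spec()) {
  structure(list(sigma = sigma, quantile_positions = quantile_positions,
                 network = network, train = train, weights = weights,
                 pseudo = pseudo, scene = scene),
            class = "project_config")
}

#' Write / read a project configuration as YAML
#'
#' @param cfg a [project_config()].
#' @param file YAML path.
#' @return `write_config()` the path invisibly; `read_config()` a
#'   [project_config()].
#' @export
write_config <- function(cfg, file) {
  stopifnot(inherits(cfg, "project_config"))
  plain <- lapply(unclass(cfg), function(x) {
    if (is.object(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  y <- yaml::read_yaml(file)
  project_config(
    sigma = y$sigma,
    quantile_positions = as.numeric(y$quantile_positions),
    network = do.call(network_config, y$network),
    train = do.call(train_config, y$train[!vapply(y$train, is.null, TRUE)]),
    weights = do.call(loss_weights, y$weights),
    pseudo = do.call(pseudo_label_config, y$pseudo),
    scene = do.call(scene_spec, y$scene)
  )
}

#' Prepare cached training targets for a dataset
#'
#' Computes ground-truth density maps for the labeled images, downsamples
#' them to the network grid, derives the density-level thresholds from the
#' labeled images only (so training can never leak unlabeled statistics),
#' builds the ground-truth level targets, and caches everything under
#' `<dir>/cache` as serialized arrays. A re-run with unchanged parameters
#' is a cache hit and leaves the outputs untouched.
#'
#' @param dir dataset directory from [generate_dataset()].
#' @param sigma density-map Gaussian width.
#' @param quantile_positions density-level quantile positions.
#' @param factor network downsampling factor (8).
#' @return List with `thresholds` and the cache directory, invisibly.
#' @export
prepare_dataset <- function(dir, sigma = 15,
                            quantile_positions = c(0, 0.33, 0.66, 1),
                            factor = 8L) {
  cache <- file.path(dir, "cache")
  stamp_file <- file.path(cache, "prepare.json")
  stamp <- list(sigma = sigma, quantile_positions = quantile_positions,
                factor = factor)
  if (file.exists(stamp_file)) {
    old <- jsonlite::read_json(stamp_file, simplifyVector = TRUE)
    if (isTRUE(all.equal(old$sigma, sigma)) &&
        isTRUE(all.equal(as.numeric(old$quantile_positions),
                         as.numeric(quantile_positions))) &&
        old$factor == factor) {
      th <- readRDS(file.path(cache, "thresholds.rds"))
      return(invisible(list(thresholds = th, cache = cache, cache_hit = TRUE)))
    }
  }
  dir.create(cache, recursive = TRUE, showWarnings = FALSE)
  ds <- read_dataset(dir)
  maps8 <- lapply(ds$labeled, function(rec) {
    d <- downsample_sum(make_density_map(rec$points, sigma), factor)
    saveRDS(d, file.path(cache, paste0(rec$id, "_density.rds")))
    d
  })
  th <- compute_thresholds(maps8, quantile_positions)
  saveRDS(th, file.path(cache, "thresholds.rds"))
  for (i in seq_along(ds$labeled)) {
    lt <- make_level_targets(maps8[[i]], th)
    saveRDS(lt, file.path(cache, paste0(ds$labeled[[i]]$id, "_levels.rds")))
  }
  jsonlite::write_json(stamp, stamp_file, auto_unbox = TRUE, digits = NA)
  invisible(list(thresholds = th, cache = cache, cache_hit = FALSE))
}

# ---- command-line interface ----

parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      flags[[key]] <- TRUE
      i <- i + 1
    }
  }
  flags
}

flag_num <- function(flags, key, default) {
  if (is.null(flags[[key]])) default else as.numeric(flags[[key]])
}

cli_log <- function(...) cat(sprintf(...), "\n", sep = "")

cli_usage <- function() {
  cat("usage: berrycount <generate|prepare|train|evaluate|predict> [--flags]\n",
      "  generate --out DIR --n N [--labeled-fraction F] [--seed S] [--force]\n",
      "  prepare  --data DIR [--sigma S] [--quantiles q1,q2,...]\n",
      "  train    --data DIR --out DIR [--epochs N] [--seed S] [--lr LR]\n",
      "           [--width-scale W] [--n-levels K] [--sigma S] [--label-only]\n",
      "  evaluate --checkpoint CK --data DIR [--out metrics.json]\n",
      "  predict  --checkpoint CK --image IMG [--out pred.json]\n", sep = "")
}

#' Command-line entry point
#'
#' Subcommands: `generate` (synthetic dataset), `prepare` (density maps,
#' thresholds and level targets cached), `train`, `evaluate` (counting
#' metrics on the held-out annotations), and `predict` (density map and
#' count for one image). Every run that writes an output directory records
#' its resolved settings and seed there. Returns (rather than calls
#' `quit()` with) the exit code: 0 on success, 2 on usage errors, 1 on
#' runtime errors.
#'
#' @param argv character vector of arguments (defaults to the process
#'   command line).
#' @return Integer exit code, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 ||
      !argv[1] %in% c("generate", "prepare", "train", "evaluate", "predict")) {
    cli_usage()
    return(invisible(2L))
  }
  cmd <- argv[1]
  code <- tryCatch({
    flags <- parse_flags(argv[-1])
    switch(cmd,
           generate = cli_generate(flags),
           prepare = cli_prepare(flags),
           train = cli_train(flags),
           evaluate = cli_evaluate(flags),
           predict = cli_predict(flags))
    0L
  }, error = function(e) {
    cli_log("error: %s", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_generate <- function(flags) {
  if (is.null(flags$out) || is.null(flags$n)) stop("generate needs --out and --n")
  spec <- scene_spec()
  generate_dataset(spec, n_images = as.integer(flags$n),
                   labeled_fraction = flag_num(flags, "labeled-fraction", 0.1),
                   dir = flags$out, seed = as.integer(flag_num(flags, "seed", 0)),
                   force = isTRUE(flags$force))
  cli_log("generated %s images in %s", flags$n, flags$out)
}

cli_quantiles <- function(flags) {
  if (is.null(flags$quantiles)) c(0, 0.33, 0.66, 1)
  else as.numeric(strsplit(flags$quantiles, ",")[[1]])
}

cli_prepare <- function(flags) {
  if (is.null(flags$data)) stop("prepare needs --data")
  r <- prepare_dataset(flags$data, sigma = flag_num(flags, "sigma", 15),
                       quantile_positions = cli_quantiles(flags))
  cli_log("prepare: %s (thresholds: %s)",
          if (r$cache_hit) "cache hit" else "cache written",
          paste(signif(r$thresholds$thresholds, 4), collapse = ", "))
}

cli_train <- function(flags) {
  if (is.null(flags$data) || is.null(flags$out)) stop("train needs --data and --out")
  seed <- as.integer(flag_num(flags, "seed", 0))
  sigma <- flag_num(flags, "sigma", 15)
  prep <- prepare_dataset(flags$data, sigma = sigma,
                          quantile_positions = cli_quantiles(flags))
  ds <- read_dataset(flags$data)
  img_h <- dim(ds$labeled[[1]]$image)[1]
  img_w <- dim(ds$labeled[[1]]$image)[2]
  ncfg <- network_config(n_levels = as.integer(flag_num(flags, "n-levels", 3)),
                         width_scale = flag_num(flags, "width-scale", 1))
  tcfg <- train_config(epochs = as.integer(flag_num(flags, "epochs", 120)),
                       initial_lr = flag_num(flags, "lr", 1e-6),
                       crop_size = c(img_w, img_h),
                       seed = seed)
  net <- build_network(ncfg, seed = seed)
  unlab <- if (isTRUE(flags[["label-only"]])) list() else ds$unlabeled
  st <- train(net, ds$labeled, unlab, prep$thresholds,
              cfg = tcfg, sigma = sigma, verbose = TRUE)
  dir.create(flags$out, recursive = TRUE, showWarnings = FALSE)
  save_checkpoint(st$network, file.path(flags$out, "checkpoint.rds"),
                  thresholds = prep$thresholds,
                  extra = list(sigma = sigma, seed = seed))
  utils::write.csv(st$history, file.path(flags$out, "history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, sigma = sigma, epochs = tcfg$epochs,
         initial_lr = tcfg$initial_lr, width_scale = ncfg$width_scale,
         n_levels = ncfg$n_levels, label_only = isTRUE(flags[["label-only"]])),
    file.path(flags$out, "run_config.json"), auto_unbox = TRUE, digits = NA)
  cli_log("trained %d epochs; checkpoint at %s", tcfg$epochs,
          file.path(flags$out, "checkpoint.rds"))
}

cli_evaluate <- function(flags) {
  if (is.null(flags$checkpoint) || is.null(flags$data)) {
    stop("evaluate needs --checkpoint and --data")
  }
  ck <- load_checkpoint(flags$checkpoint)
  ds <- read_dataset(flags$data, include_sealed = TRUE)
  records <- c(ds$labeled, ds$unlabeled)
  m <- evaluate_records(ck$network, records)
  out <- list(mae = m$mae, rmse = m$rmse, r2 = m$r2, n_images = m$n_images)
  if (!is.null(flags$out)) {
    jsonlite::write_json(out, flags$out, auto_unbox = TRUE, digits = NA)
  }
  cli_log("evaluate: n=%d MAE=%.3f RMSE=%.3f R2=%s", m$n_images, m$mae,
          m$rmse, ifelse(is.na(m$r2), "NA", sprintf("%.4f", m$r2)))
}

cli_predict <- function(flags) {
  if (is.null(flags$checkpoint) || is.null(flags$image)) {
    stop("predict needs --checkpoint and --image")
  }
  ck <- load_checkpoint(flags$checkpoint)
  img <- png::readPNG(flags$image)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  pr <- predict_count(ck$network, img)
  if (!is.null(flags$out)) {
    jsonlite::write_json(list(image = flags$image, count = pr$count),
                         flags$out, auto_unbox = TRUE, digits = NA)
  }
  cli_log("predict: %s -> count %.2f", flags$image, pr$count)
}
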