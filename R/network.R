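#' Network configuration
#'
#' Describes the density-counting architecture: a VGG-style front end whose
#' four stages emit feature maps at 1/2, 1/4, 1/8, 1/8 of the input
#' resolution with the stated channel widths, followed by two dilated
#' 3x3 convolution stages (rate 2, padding 2) that keep 1/8 resolution, then
#' a 1x1 density-regression head and k 1x1 sigmoid level-predictor heads.
#' `width_scale` shrinks every stage width proportionally for desk-scale
#' "tiny" variants without changing the topology.
#'
#' @param n_levels number of density-level predictors k (>= 2; 3 performs
#'   best in the source study's ablation).
#' @param width_scale channel multiplier in (0, 1].
#' @param dilation_rate dilation of the two final trunk stages (default 2).
#' @param channel_plan full-width stage channels.
#' @param downsample_factor output stride; fixed at 8 (three halvings).
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_levels = 3L, width_scale = 1,
                           dilation_rate = 2L,
                           channel_plan = c(64, 128, 256, 512, 512, 256),
                           downsample_factor = 8L) {
  if (downsample_factor != 8L) stop("downsample_factor is fixed at 8")
  if (n_levels < 2) stop("density mutual exclusion needs n_levels >= 2")
  if (!(width_scale > 0 && width_scale <= 1)) stop("width_scale must be in (0, 1]")
  if (length(channel_plan) != 6) stop("channel_plan must list 6 stage widths")
  structure(list(n_levels = as.integer(n_levels), width_scale = width_scale,
                 dilation_rate = as.integer(dilation_rate),
                 channel_plan = as.integer(channel_plan),
                 downsample_factor = 8L),
            class = "network_config")
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

conv_param <- function(c_in, c_out, k) {
  fan_in <- k * k * c_in
  list(W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = c_out),
       b = numeric(c_out))
}

#' Build a counting network
#'
#' Constructs the layer plan of [network_config()] with seeded He-normal
#' initialization, so two builds from the same seed have identical
#' parameters. An optional `pretrained` hook loads a previously saved
#' parameter list (e.g. converted backbone weights); it is off by default so
#' nothing is downloaded.
#'
#' @param cfg a [network_config()].
#' @param seed integer RNG seed for initialization.
#' @param pretrained optional path to an `.rds` parameter list to load over
#'   the matching entries.
#' @return An object of class `berry_network`.
#' @export
build_network <- function(cfg = network_config(), seed = 0L, pretrained = NULL) {
  stopifnot(inherits(cfg, "network_config"))
  ch <- pmax(1L, as.integer(round(cfg$channel_plan * cfg$width_scale)))
  d <- cfg$dilation_rate
  layers <- list(
    list(op = "conv", param = "conv1", k = 3L, pad = 1L, dil = 1L),
    list(op = "relu"),
    list(op = "pool"),
    list(op = "conv", param = "conv2", k = 3L, pad = 1L, dil = 1L),
    list(op = "relu"),
    list(op = "pool"),
    list(op = "conv", param = "conv3", k = 3L, pad = 1L, dil = 1L),
    list(op = "relu"),
    list(op = "pool"),
    list(op = "conv", param = "conv4", k = 3L, pad = 1L, dil = 1L),
    list(op = "relu"),
    list(op = "conv", param = "conv5", k = 3L, pad = d, dil = d),
    list(op = "relu"),
    list(op = "conv", param = "conv6", k = 3L, pad = d, dil = d),
    list(op = "relu")
  )
  c_in <- c(3L, ch[1], ch[2], ch[3], ch[4], ch[5])
  params <- with_seed(seed, {
    p <- list()
    for (i in 1:6) p[[paste0("conv", i)]] <- conv_param(c_in[i], ch[i], 3L)
    p$head_density <- conv_param(ch[6], 1L, 1L)
    for (j in seq_len(cfg$n_levels)) {
      p[[paste0("head_level", j)]] <- conv_param(ch[6], 1L, 1L)
    }
    p
  })
  if (!is.null(pretrained)) {
    pre <- readRDS(pretrained)
    for (nm in intersect(names(pre), names(params))) params[[nm]] <- pre[[nm]]
  }
  structure(list(config = cfg, channels = ch, layers = layers, params = params),
            class = "berry_network")
}

#' @export
print.berry_network <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("<berry_network> k = %d levels, widths %s, %d parameters\n",
              x$config$n_levels, paste(x$channels, collapse = "-"), np))
  invisible(x)
}

#' Network outputs for one image
#'
#' Holds the raw density-regression map (1/8 resolution, unconstrained sign)
#' and the k sigmoid level-probability maps, all of shape `(H/8, W/8)`.
#'
#' @param density a [density_map()] with `resolution_divisor = 8`.
#' @param level_probs `H/8 x W/8 x k` array of values in `[0, 1]`.
#' @return An object of class `predictor_outputs`.
#' @export
predictor_outputs <- function(density, level_probs) {
  stopifnot(inherits(density, "density_map"), length(dim(level_probs)) == 3,
            all(dim(density$values) == dim(level_probs)[1:2]))
  structure(list(density = density, level_probs = level_probs,
                 resolution_divisor = density$resolution_divisor),
            class = "predictor_outputs")
}

#' Normalize an image array for the network
#'
#' Accepts `H x W x 3` arrays either already in `[0, 1]` or in 0-255 and
#' returns the `[0, 1]` per-channel form the network expects.
#'
#' @param image numeric `H x W x 3` array.
#' @return Normalized array.
#' @export
normalize_image <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("input must be an H x W x 3 RGB array")
  }
  if (max(image) > 1.5) image <- image / 255
  image
}

pad_to_multiple <- function(image, m = 8L) {
  H <- dim(image)[1]; W <- dim(image)[2]
  Hp <- as.integer(ceiling(H / m) * m); Wp <- as.integer(ceiling(W / m) * m)
  if (Hp == H && Wp == W) return(image)
  out <- array(0, dim = c(Hp, Wp, dim(image)[3]))
  out[seq_len(H), seq_len(W), ] <- image
  out
}

#' Forward pass
#'
#' Runs an RGB image through the trunk and both head groups. Images whose
#' sides are not divisible by 8 are zero-padded on the right/bottom before
#' the pass (the output grid then covers the padded extent). Deterministic
#' given the parameters.
#'
#' @param net a [build_network()] handle.
#' @param image `H x W x 3` array (see [normalize_image()]).
#' @param cache logical; keep intermediate activations for backpropagation
#'   (attached as attribute `"cache"`).
#' @return A [predictor_outputs()].
#' @export
forward <- function(net, image, cache = FALSE) {
  stopifnot(inherits(net, "berry_network"))
  x <- pad_to_multiple(normalize_image(image), 8L)
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    l <- net$layers[[li]]
    if (l$op == "conv") {
      p <- net$params[[l$param]]
      caches[[li]] <- list(x = x)
      x <- cpp_conv_forward(x, p$W, p$b, l$k, l$pad, l$dil)
    } else if (l$op == "relu") {
      caches[[li]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else { # pool
      caches[[li]] <- list(H = dim(x)[1], W = dim(x)[2])
      r <- cpp_maxpool_forward(x)
      caches[[li]]$idx <- r$idx
      x <- r$y
    }
  }
  trunk_out <- x
  pd <- net$params$head_density
  dens <- cpp_conv_forward(trunk_out, pd$W, pd$b, 1L, 0L, 1L)[, , 1]
  H8 <- dim(trunk_out)[1]; W8 <- dim(trunk_out)[2]
  dens <- matrix(dens, H8, W8)
  k <- net$config$n_levels
  probs <- array(0, dim = c(H8, W8, k))
  for (j in seq_len(k)) {
    pl <- net$params[[paste0("head_level", j)]]
    z <- cpp_conv_forward(trunk_out, pl$W, pl$b, 1L, 0L, 1L)[, , 1]
    probs[, , j] <- 1 / (1 + exp(-z))
  }
  out <- predictor_outputs(density_map(dens, 8L), probs)
  if (cache) {
    attr(out, "cache") <- list(layer_caches = caches, trunk_out = trunk_out)
  }
  out
}

# Backward pass: gradients of a scalar loss wrt all parameters, given the
# loss gradients at the two head outputs. d_level_probs is the gradient wrt
# the sigmoid probabilities (chained through the sigmoid here). Returns a
# list mirroring net$params.
net_backward <- function(net, outputs, d_density, d_level_probs) {
  cache <- attr(outputs, "cache")
  if (is.null(cache)) stop("forward() must be called with cache = TRUE")
  trunk_out <- cache$trunk_out
  grads <- list()
  dx_trunk <- array(0, dim = dim(trunk_out))

  pd <- net$params$head_density
  dd <- array(d_density, dim = c(dim(d_density), 1L))
  r <- cpp_conv_backward(trunk_out, pd$W, dd, 1L, 0L, 1L)
  grads$head_density <- list(W = r$dW, b = as.numeric(r$db))
  dx_trunk <- dx_trunk + r$dx

  k <- net$config$n_levels
  for (j in seq_len(k)) {
    nm <- paste0("head_level", j)
    p <- outputs$level_probs[, , j]
    dz <- d_level_probs[, , j] * p * (1 - p)
    dz <- array(dz, dim = c(dim(dz), 1L))
    r <- cpp_conv_backward(trunk_out, net$params[[nm]]$W, dz, 1L, 0L, 1L)
    grads[[nm]] <- list(W = r$dW, b = as.numeric(r$db))
    dx_trunk <- dx_trunk + r$dx
  }

  dx <- dx_trunk
  for (li in rev(seq_along(net$layers))) {
    l <- net$layers[[li]]
    lc <- cache$layer_caches[[li]]
    if (l$op == "conv") {
      r <- cpp_conv_backward(lc$x, net$params[[l$param]]$W, dx, l$k, l$pad, l$dil)
      grads[[l$param]] <- list(W = r$dW, b = as.numeric(r$db))
      dx <- r$dx
    } else if (l$op == "relu") {
      dx <- dx * lc$mask
    } else {
      dx <- cpp_maxpool_backward(lc$idx, dx, lc$H, lc$W)
    }
  }
  grads
}

#' Predict a density map and count for one image
#'
#' @param net a trained [build_network()] handle.
#' @param image `H x W x 3` array.
#' @param clip_negative zero out negative density pixels before counting
#'   (off by default; raw sums are reported).
#' @return List with `density` ([density_map()]) and `count` (numeric).
#' @export
predict_count <- function(net, image, clip_negative = FALSE) {
  out <- forward(net, image)
  d <- out$density
  if (clip_negative) d$values[d$values < 0] <- 0
  list(density = d, count = count_from_density(d))
}

#' Save / load a checkpoint
#'
#' A checkpoint is a single serialized archive holding the network
#' configuration and parameters, the frozen density thresholds, and a format
#' tag for forward compatibility.
#'
#' @param net a [build_network()] handle.
#' @param path file path (`.rds`).
#' @param thresholds optional `threshold_set` to embed.
#' @param extra optional named list of additional metadata.
#' @return `save_checkpoint()` returns the path invisibly;
#'   `load_checkpoint()` returns a list with `network` and `thresholds`.
#' @export
save_checkpoint <- function(net, path, thresholds = NULL, extra = list()) {
  stopifnot(inherits(net, "berry_network"))
  saveRDS(list(format = "berrycount-checkpoint-v1",
               config = net$config, channels = net$channels,
               params = net$params, thresholds = thresholds, extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "berrycount-checkpoint-v1")) {
    stop("unrecognized checkpoint format tag")
  }
  net <- build_network(ck$config, seed = 0L)
  net$params <- ck$params
  list(network = net, thresholds = ck$thresholds, extra = ck$extra)
}

# flat census of the layer plan, for topology assertions
layer_census <- function(net) {
  ops <- vapply(net$layers, `[[`, "", "op")
  dils <- vapply(net$layers, function(l) if (l$op == "conv") l$dil else NA_integer_,
                 NA_integer_)
  data.frame(op = ops, dilation = dils)
}
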