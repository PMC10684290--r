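#' Density map container
#'
#' A nonnegative grid of object density (objects per pixel) whose sum is the
#' (fractional) object count. Ground truth and network predictions share this
#' type; `resolution_divisor` records how much coarser the grid is than the
#' source image (1 for full-resolution ground truth, 8 for network-resolution
#' maps).
#'
#' @param values numeric matrix of densities.
#' @param resolution_divisor positive integer scale factor relative to the
#'   image.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, resolution_divisor = 1L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(resolution_divisor >= 1)
  structure(list(values = values,
                 resolution_divisor = as.integer(resolution_divisor)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d (1/%d resolution), sum = %.4f\n",
              nrow(x$values), ncol(x$values), x$resolution_divisor,
              sum(x$values)))
  invisible(x)
}

#' Build a ground-truth density map from point annotations
#'
#' Each annotation contributes one isotropic Gaussian bump of standard
#' deviation `sigma` pixels, sampled at pixel centers and scaled so that its
#' full (untruncated) integral is 1; the sum of the map therefore equals the
#' point count up to border truncation. Bumps are evaluated on a window of
#' half-width `4*sigma` (the fixed kernel size; mass beyond it is below
#' 2e-4) and truncated at the image border without renormalization, the
#' standard convention in the density-map counting lineage.
#'
#' @param points a [point_set()].
#' @param sigma Gaussian kernel width in pixels; default 15, matched to
#'   field images where a berry spans tens of pixels. Scale it with the berry
#'   radius for smaller synthetic scenes.
#' @return A full-resolution [density_map()] of size `height x width`.
#' @examples
#' ps <- point_set("a", 64, 64, cbind(32, 32))
#' d <- make_density_map(ps, sigma = 4)
#' sum(d$values) # ~1
#' @export
make_density_map <- function(points, sigma = 15) {
  stopifnot(inherits(points, "point_set"))
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  H <- points$height; W <- points$width
  vals <- matrix(0, H, W)
  hw <- ceiling(4 * sigma)
  for (n in seq_len(n_points(points))) {
    x <- points$points[n, "x"]; y <- points$points[n, "y"]
    # 0-based pixel centers: pixel (i, j) is at (x = j, y = i)
    rows <- max(0, floor(y - hw)):min(H - 1, ceiling(y + hw))
    cols <- max(0, floor(x - hw)):min(W - 1, ceiling(x + hw))
    gy <- stats::dnorm(rows, mean = y, sd = sigma)
    gx <- stats::dnorm(cols, mean = x, sd = sigma)
    vals[rows + 1, cols + 1] <- vals[rows + 1, cols + 1] + outer(gy, gx)
  }
  density_map(vals, 1L)
}

#' Sum-preserving block downsampling of a density map
#'
#' Reduces resolution by summing non-overlapping `factor x factor` blocks, so
#' the total count is preserved exactly. Used to bring full-resolution ground
#' truth to the network's 1/8-resolution output grid.
#'
#' @param d a [density_map()].
#' @param factor positive integer; grid dimensions must be divisible by it.
#' @return A [density_map()] with `resolution_divisor` multiplied by `factor`.
#' @export
downsample_sum <- function(d, factor) {
  stopifnot(inherits(d, "density_map"))
  factor <- as.integer(factor)
  stopifnot(length(factor) == 1, factor >= 1)
  if (factor == 1L) return(d)
  v <- d$values
  H <- nrow(v); W <- ncol(v)
  if (H %% factor != 0 || W %% factor != 0) {
    stop(sprintf("dimensions %d x %d not divisible by factor %d (pad or crop first)",
                 H, W, factor))
  }
  dim(v) <- c(factor, H %/% factor, W)        # column-major: split rows
  v <- colSums(v)                             # (H/f, W)
  v <- t(v)                                   # (W, H/f)
  dim(v) <- c(factor, W %/% factor, H %/% factor)
  v <- t(colSums(v))                          # (H/f, W/f)
  density_map(v, d$resolution_divisor * factor)
}

#' Density-level thresholds from labeled data
#'
#' Pools all strictly positive density values of the labeled ground-truth
#' maps, sorts them ascending into a sequence of length T, and takes as the
#' threshold for quantile position S the value at 1-based index
#' `clamp(ceiling(S * T), 1, T)`. With the default positions
#' `{0, 0.33, 0.66, 1}` this yields 4 thresholds bounding k = 3 density
#' levels.
#'
#' @param labeled_maps list of [density_map()]s from labeled images, at the
#'   resolution at which level targets will be built.
#' @param quantile_positions sorted numeric vector in `[0, 1]` of length >= 3
#'   (k = length - 1 levels; the mutual-exclusion rule needs k >= 2).
#' @return An object of class `threshold_set` with fields
#'   `quantile_positions`, `thresholds`, `n_levels`.
#' @export
compute_thresholds <- function(labeled_maps,
                               quantile_positions = c(0, 0.33, 0.66, 1)) {
  if (inherits(labeled_maps, "density_map")) labeled_maps <- list(labeled_maps)
  stopifnot(length(labeled_maps) >= 1,
            all(vapply(labeled_maps, inherits, TRUE, "density_map")))
  qp <- as.numeric(quantile_positions)
  if (is.unsorted(qp) || any(qp < 0) || any(qp > 1)) {
    stop("quantile_positions must be sorted within [0, 1]")
  }
  if (length(qp) < 3) stop("need at least 3 quantile positions (k >= 2 levels)")
  dp <- sort(unlist(lapply(labeled_maps, function(d) {
    v <- d$values
    v[v > 0]
  })))
  if (length(dp) == 0) {
    stop("degenerate labeled data: no nonzero density values")
  }
  T_len <- length(dp)
  idx <- pmin(pmax(ceiling(qp * T_len), 1L), T_len)
  structure(list(quantile_positions = qp,
                 thresholds = dp[idx],
                 n_levels = length(qp) - 1L),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> k = %d levels, thresholds: %s\n", x$n_levels,
              paste(signif(x$thresholds, 4), collapse = ", ")))
  invisible(x)
}

#' Binary density-level target maps
#'
#' Container for the k mutually exclusive binary maps supervising the
#' auxiliary level predictors, plus a per-pixel validity mask (1 = pixel
#' contributes to supervision). Ground-truth targets are always fully valid;
#' pseudo-label targets mark non-mutually-exclusive pixels invalid.
#'
#' @param maps numeric `H x W x k` array of 0/1 values.
#' @param validity numeric `H x W` matrix of 0/1 values.
#' @param source `"ground_truth"` or `"pseudo_label"`.
#' @param resolution_divisor grid scale relative to the image.
#' @return An object of class `level_targets`.
#' @export
level_targets <- function(maps, validity, source = c("ground_truth", "pseudo_label"),
                          resolution_divisor = 8L) {
  source <- match.arg(source)
  if (length(dim(maps)) != 3) stop("`maps` must be an H x W x k array")
  if (any(apply(maps, c(1, 2), sum) > 1 + 1e-12)) {
    stop("level maps are not mutually exclusive")
  }
  if (source == "ground_truth" && !all(validity == 1)) {
    stop("ground-truth targets must be fully valid")
  }
  structure(list(maps = maps, validity = validity, source = source,
                 resolution_divisor = as.integer(resolution_divisor)),
            class = "level_targets")
}

#' Ground-truth level targets from a density map
#'
#' Assigns every pixel with density in `(lower_j, t_{j+1}]` to level j, where
#' the thresholds come from [compute_thresholds()], `lower_1 = 0`, and
#' `lower_j = t_j` for j >= 2. The lowest interval opens at 0 (not at the
#' smallest nonzero value) so every nonzero pixel belongs to exactly one
#' level; ties on the upper bound resolve to the lower level (closed upper
#' bound). Pixels above the top threshold, and exact zeros, are background on
#' all maps.
#'
#' @param d a [density_map()] at the network's resolution (apply
#'   [downsample_sum()] first).
#' @param th a `threshold_set`.
#' @return [level_targets()] with `source = "ground_truth"` and full validity.
#' @export
make_level_targets <- function(d, th) {
  stopifnot(inherits(d, "density_map"), inherits(th, "threshold_set"))
  c_th <- length(th$thresholds)
  if (c_th != th$n_levels + 1L) {
    stop("threshold count inconsistent with n_levels")
  }
  uppers <- th$thresholds[2:c_th]
  lowers <- c(0, th$thresholds[2:(c_th - 1)])
  v <- d$values
  maps <- array(0, dim = c(nrow(v), ncol(v), th$n_levels))
  for (j in seq_len(th$n_levels)) {
    maps[, , j] <- as.numeric(v > lowers[j] & v <= uppers[j])
  }
  level_targets(maps, matrix(1, nrow(v), ncol(v)), "ground_truth",
                resolution_divisor = d$resolution_divisor)
}
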