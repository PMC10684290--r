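#' Pseudo-labeling configuration
#'
#' @param t_p prediction-confidence threshold in (0, 1); a level predictor
#'   "fires" at a pixel when its probability is strictly greater than `t_p`.
#'   Default 0.8.
#' @param exclude_unconfident how zero-fire pixels (no predictor above
#'   `t_p`) are treated. `TRUE` (default) excludes them from supervision
#'   like the contradictory multi-fire pixels, the usual
#'   confidence-thresholding convention in pseudo-labeling; single-fire
#'   pixels still supervise the other k - 1 maps' background, so negative
#'   signal remains. `FALSE` keeps zero-fire pixels as valid all-background
#'   supervision; in practice this lets the bulk of unconfident unlabeled
#'   pixels suppress the level heads below `t_p` indefinitely, so the
#'   mutual-exclusion correction never engages (see the package vignette).
#' @return An object of class `pseudo_label_config`.
#' @export
pseudo_label_config <- function(t_p = 0.8, exclude_unconfident = TRUE) {
  if (!(t_p > 0 && t_p < 1)) stop("t_p must lie strictly in (0, 1)")
  structure(list(t_p = t_p, exclude_unconfident = isTRUE(exclude_unconfident)),
            class = "pseudo_label_config")
}

#' Mutual-exclusion-corrected pseudo-labels
#'
#' Turns the k level-probability maps predicted for an unlabeled image into
#' binary supervision, using the prior that a pixel's density belongs to
#' exactly one level. Per pixel: predictors with probability strictly above
#' `t_p` fire; if exactly one fires the pixel becomes foreground of that
#' level; if two or more fire the predictions contradict the
#' mutual-exclusion prior, so the pixel is marked invalid and excluded from
#' supervision; if none fire the pixel is excluded as unconfident (or, with
#' `exclude_unconfident = FALSE`, supervises the background class of all
#' levels). The result is mutually exclusive by construction and carries
#' no gradient (targets are constants).
#'
#' @param outputs a [predictor_outputs()].
#' @param cfg a [pseudo_label_config()].
#' @return [level_targets()] with `source = "pseudo_label"`.
#' @export
generate_pseudo_labels <- function(outputs, cfg = pseudo_label_config()) {
  stopifnot(inherits(cfg, "pseudo_label_config"))
  probs <- outputs$level_probs
  if (length(dim(probs)) != 3) stop("level_probs must be an H x W x k array")
  fires <- probs > cfg$t_p
  n_fire <- apply(fires, c(1, 2), sum)
  single <- n_fire == 1
  maps <- array(0, dim = dim(probs))
  for (j in seq_len(dim(probs)[3])) {
    maps[, , j] <- as.numeric(fires[, , j] & single)
  }
  validity <- if (cfg$exclude_unconfident) as.numeric(n_fire == 1)
  else 1 - as.numeric(n_fire >= 2)
  dim(validity) <- dim(n_fire)
  level_targets(maps, validity, "pseudo_label",
                resolution_divisor = outputs$resolution_divisor %||% 8L)
}

#' Summary statistics of a pseudo-label map
#'
#' @param targets [level_targets()] with `source = "pseudo_label"`.
#' @return List with `foreground_per_level` (pixel counts), `invalid_fraction`
#'   (share of pixels excluded by mutual exclusion), `background_fraction`,
#'   and `n_pixels`.
#' @export
exclusion_stats <- function(targets) {
  stopifnot(inherits(targets, "level_targets"))
  if (targets$source != "pseudo_label") {
    stop("exclusion_stats expects pseudo-label targets")
  }
  n_pixels <- length(targets$validity)
  fg <- apply(targets$maps, 3, sum)
  invalid <- sum(targets$validity == 0)
  list(foreground_per_level = fg,
       invalid_fraction = invalid / n_pixels,
       background_fraction = (n_pixels - invalid - sum(fg)) / n_pixels,
       n_pixels = n_pixels)
}
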