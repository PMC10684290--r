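#' Loss weights for the composite semi-supervised objective
#'
#' The labeled objective is `L_MSE + lambda1 * L_CE + lambda2 * L_DD`; the
#' unlabeled objective is `lambda3 * L_CE + lambda4 * L_DD` (unlabeled images
#' never train the density regressor). Defaults follow the method's stated
#' settings: cross-entropy terms weighted 0.01, density-difference terms 1.
#'
#' @param lambda1,lambda2 labeled-image weights for cross-entropy and
#'   density-difference losses.
#' @param lambda3,lambda4 unlabeled-image weights, same roles.
#' @param epsilon small positive constant stabilizing cosine similarity and
#'   clipping probabilities before logs.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.01, lambda2 = 1, lambda3 = 0.01,
                         lambda4 = 1, epsilon = 1e-8) {
  w <- c(lambda1, lambda2, lambda3, lambda4)
  if (any(w < 0) || epsilon <= 0) stop("weights must be >= 0 and epsilon > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, epsilon = epsilon),
            class = "loss_weights")
}

#' Masked binary cross-entropy over the level predictors
#'
#' Standard per-pixel binary cross-entropy between each predicted level
#' probability map and its binary target, restricted to valid pixels and
#' averaged over valid pixel-level pairs (so the average over the k
#' predictors is respected). Probabilities are clipped to
#' `[epsilon, 1 - epsilon]` before taking logs.
#'
#' @param outputs a [predictor_outputs()] (uses `level_probs`).
#' @param targets a [level_targets()].
#' @param epsilon clipping constant.
#' @return Nonnegative scalar loss; 0 (with a warning) when no pixel is
#'   valid.
#' @export
cross_entropy_loss <- function(outputs, targets, epsilon = 1e-8) {
  ce_loss_grad(outputs$level_probs, targets, epsilon, want_grad = FALSE)$loss
}

# internal: loss and gradient wrt the probability array
ce_loss_grad <- function(probs, targets, epsilon, want_grad = TRUE) {
  k <- dim(probs)[3]
  stopifnot(k == dim(targets$maps)[3],
            all(dim(probs)[1:2] == dim(targets$validity)))
  vmask <- targets$validity
  n_valid <- sum(vmask)
  if (n_valid == 0) {
    warning("no valid pixels; cross-entropy loss is 0")
    return(list(loss = 0,
                dprobs = if (want_grad) array(0, dim = dim(probs)) else NULL))
  }
  p <- pmin(pmax(probs, epsilon), 1 - epsilon)
  m <- targets$maps
  vm <- array(rep(vmask, k), dim = dim(probs))
  loss <- -sum(vm * (m * log(p) + (1 - m) * log(1 - p))) / (k * n_valid)
  dprobs <- NULL
  if (want_grad) {
    dprobs <- vm * (p - m) / (p * (1 - p)) / (k * n_valid)
  }
  list(loss = loss, dprobs = dprobs)
}

#' Epsilon-stabilized cosine similarity
#'
#' `dot(f1, f2) / (||f1|| * ||f2|| + epsilon)`. The epsilon sits in the
#' denominator (rather than a zero-vector branch) so the expression stays
#' differentiable; an all-zero vector yields similarity 0.
#'
#' @param f1,f2 numeric vectors of equal length.
#' @param epsilon small positive stabilizer.
#' @return Scalar in `[-1, 1]`.
#' @export
cosine_similarity <- function(f1, f2, epsilon = 1e-8) {
  if (length(f1) != length(f2)) stop("vectors must have equal length")
  sum(f1 * f2) / (sqrt(sum(f1^2)) * sqrt(sum(f2^2)) + epsilon)
}

#' Density difference loss
#'
#' Column-wise cosine-similarity objective over the k predicted and target
#' level maps. Writing `f'_{i,w}` for column w of predicted map i and
#' `f_{j,w}` for column w of target map j:
#' `L_max = -(1/k) * sum_i sum_w S(f'_{i,w}, f_{i,w})` pulls each predicted
#' map toward its own target, and
#' `L_min = (1/(k(k-1))) * sum_i sum_{j != i} sum_w S(f'_{i,w}, f_{j,w})`
#' pushes it away from the other levels' targets; the loss is their sum
#' (plain sums over columns, so the value scales with map width). For
#' pseudo-label targets, invalid pixels are zeroed in the target columns
#' before the similarities.
#'
#' @param outputs a [predictor_outputs()].
#' @param targets a [level_targets()] with k >= 2 maps.
#' @param epsilon cosine stabilizer.
#' @return Scalar loss with attributes `l_max` and `l_min`.
#' @export
density_difference_loss <- function(outputs, targets, epsilon = 1e-8) {
  r <- dd_loss_grad(outputs$level_probs, targets, epsilon, want_grad = FALSE)
  structure(r$loss, l_max = r$l_max, l_min = r$l_min)
}

# internal: L_DD and gradient wrt the predicted probability array.
# d/df1 S(f1, f2) = f2/(q+eps) - S * n2 * f1 / (n1 * (q+eps)),  q = n1*n2
dd_loss_grad <- function(probs, targets, epsilon, want_grad = TRUE) {
  k <- dim(probs)[3]
  if (k < 2) stop("density difference loss needs k >= 2 predictors")
  stopifnot(k == dim(targets$maps)[3])
  tmaps <- targets$maps
  if (targets$source == "pseudo_label") {
    vm <- array(rep(targets$validity, k), dim = dim(tmaps))
    tmaps <- tmaps * vm
  }
  W <- dim(probs)[2]
  np <- sqrt(apply(probs^2, c(2, 3), sum))   # W x k predicted column norms
  nt <- sqrt(apply(tmaps^2, c(2, 3), sum))   # W x k target column norms
  l_max <- 0; l_min <- 0
  dprobs <- if (want_grad) array(0, dim = dim(probs)) else NULL
  for (i in seq_len(k)) {
    Pi <- probs[, , i]
    for (j in seq_len(k)) {
      Tj <- tmaps[, , j]
      dots <- colSums(Pi * Tj)
      q <- np[, i] * nt[, j] + epsilon
      s <- dots / q
      coef <- if (i == j) -1 / k else 1 / (k * (k - 1))
      if (i == j) l_max <- l_max - sum(s) / k
      else l_min <- l_min + sum(s) / (k * (k - 1))
      if (want_grad) {
        # per-column gradient of S wrt the predicted column
        safe_np <- pmax(np[, i], 1e-12)
        g <- sweep(Tj, 2, 1 / q, "*") -
          sweep(Pi, 2, s * nt[, j] / (safe_np * q), "*")
        dprobs[, , i] <- dprobs[, , i] + coef * g
      }
    }
  }
  list(loss = l_max + l_min, l_max = l_max, l_min = l_min, dprobs = dprobs)
}

#' Density regression loss
#'
#' Squared L2 norm of the per-pixel difference between predicted and target
#' density maps, summed over pixels (per-image; with batch size 1 the batch
#' average is the image itself).
#'
#' @param predicted,target [density_map()]s of equal shape and resolution.
#' @return Nonnegative scalar.
#' @export
mse_density_loss <- function(predicted, target) {
  stopifnot(inherits(predicted, "density_map"), inherits(target, "density_map"))
  if (!all(dim(predicted$values) == dim(target$values)) ||
      predicted$resolution_divisor != target$resolution_divisor) {
    stop("density maps differ in shape or resolution")
  }
  sum((predicted$values - target$values)^2)
}

#' Compose per-image loss terms into the semi-supervised objective
#'
#' Labeled images contribute `L_MSE + lambda1 * L_CE + lambda2 * L_DD`;
#' unlabeled images contribute `lambda3 * L_CE + lambda4 * L_DD` only — the
#' density regressor never sees unlabeled supervision, which is the routing
#' that shields it from pseudo-label noise. The total is the sum of both
#' sides.
#'
#' @param parts named list with elements `ce`, `dd`, and (labeled only)
#'   `mse`.
#' @param weights a [loss_weights()].
#' @param image_is_labeled logical flag.
#' @return A `loss_breakdown` list with fields `mse`, `ce`, `dd`,
#'   `labeled_total`, `unlabeled_total`, `total`.
#' @export
compose_losses <- function(parts, weights, image_is_labeled) {
  stopifnot(inherits(weights, "loss_weights"))
  ce <- parts$ce %||% 0
  dd <- as.numeric(parts$dd %||% 0)
  if (image_is_labeled) {
    if (is.null(parts$mse)) stop("labeled image requires an mse part")
    mse <- parts$mse
    labeled_total <- mse + weights$lambda1 * ce + weights$lambda2 * dd
    unlabeled_total <- 0
  } else {
    if (!is.null(parts$mse)) {
      stop("contract violation: unlabeled image supplied a density (mse) term")
    }
    mse <- 0
    labeled_total <- 0
    unlabeled_total <- weights$lambda3 * ce + weights$lambda4 * dd
  }
  structure(list(mse = mse, ce = ce, dd = dd,
                 labeled_total = labeled_total,
                 unlabeled_total = unlabeled_total,
                 total = labeled_total + unlabeled_total),
            class = "loss_breakdown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
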