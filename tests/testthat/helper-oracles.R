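# Independent scalar-loop oracles used to cross-check the vectorized
# implementations, plus small fixture builders.

# per-pixel interval-rule oracle for ground-truth level targets
level_targets_oracle <- function(values, thresholds) {
  c_th <- length(thresholds)
  k <- c_th - 1
  uppers <- thresholds[2:c_th]
  lowers <- c(0, thresholds[2:(c_th - 1)])
  maps <- array(0, dim = c(nrow(values), ncol(values), k))
  for (i in seq_len(nrow(values))) {
    for (j in seq_len(ncol(values))) {
      v <- values[i, j]
      for (lev in seq_len(k)) {
        if (v > lowers[lev] && v <= uppers[lev]) maps[i, j, lev] <- 1
      }
    }
  }
  maps
}

# per-pixel mutual-exclusion oracle: returns maps and validity
pseudo_label_oracle <- function(probs, t_p, exclude_unconfident = TRUE) {
  k <- dim(probs)[3]
  maps <- array(0, dim = dim(probs))
  validity <- matrix(1, dim(probs)[1], dim(probs)[2])
  for (i in seq_len(dim(probs)[1])) {
    for (j in seq_len(dim(probs)[2])) {
      fired <- which(probs[i, j, ] > t_p)
      if (length(fired) == 1) {
        maps[i, j, fired] <- 1
      } else if (length(fired) >= 2) {
        validity[i, j] <- 0
      } else if (exclude_unconfident) {
        validity[i, j] <- 0
      }
    }
  }
  list(maps = maps, validity = validity)
}

# brute-force column-loop oracle for the density difference loss
dd_oracle <- function(probs, tmaps, validity = NULL, eps = 1e-8) {
  k <- dim(probs)[3]
  W <- dim(probs)[2]
  if (!is.null(validity)) {
    for (j in seq_len(k)) tmaps[, , j] <- tmaps[, , j] * validity
  }
  l_max <- 0
  l_min <- 0
  for (i in seq_len(k)) {
    for (w in seq_len(W)) {
      l_max <- l_max - cosine_similarity(probs[, w, i], tmaps[, w, i], eps) / k
      for (j in seq_len(k)) {
        if (j != i) {
          l_min <- l_min +
            cosine_similarity(probs[, w, i], tmaps[, w, j], eps) / (k * (k - 1))
        }
      }
    }
  }
  list(l_max = l_max, l_min = l_min, l_dd = l_max + l_min)
}

# predictor_outputs fixture from a probability array (density all zero)
outputs_from_probs <- function(probs) {
  predictor_outputs(density_map(matrix(0, dim(probs)[1], dim(probs)[2]), 8L),
                    probs)
}

# ground-truth level_targets fixture directly from binary maps
targets_from_maps <- function(maps, source = "ground_truth",
                              validity = NULL) {
  if (is.null(validity)) validity <- matrix(1, dim(maps)[1], dim(maps)[2])
  level_targets(maps, validity, source)
}

random_point_set <- function(id, width, height, n, margin = 0) {
  point_set(id, width, height,
            cbind(x = runif(n, margin, width - 1 - margin),
                  y = runif(n, margin, height - 1 - margin)))
}
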