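#' Synthetic berry-scene specification
#'
#' Parameters of the seeded scene generator used for desk-scale testing of
#' the whole pipeline. Scenes follow a Thomas-process-like layout — cluster
#' centers uniform in frame, berries scattered around each center with a
#' per-cluster Gaussian spread — rendered as shaded disks on a textured
#' background, mimicking the statistical preconditions of field berry
#' images (tight clusters, several density levels, occlusion) rather than
#' their photographic appearance. Defaults target a 256 x 256 test-scale
#' scene with 30-200 berries, a scaled-down analogue of field images whose
#' per-image counts span roughly 206-1585.
#'
#' @param image_size `c(width, height)`, both divisible by 8.
#' @param n_clusters integer range `c(min, max)` of bunches per scene.
#' @param berries_per_cluster Poisson mean of berries per bunch.
#' @param cluster_sigma range of per-bunch Gaussian spread (pixels); the
#'   spread varies bunch to bunch so scenes contain several density levels.
#' @param berry_radius range of berry radii (pixels, >= 1).
#' @param berry_color base RGB in `[0, 1]`.
#' @param color_jitter sd of per-berry RGB jitter.
#' @param background_amplitude amplitude of the smooth background texture.
#' @param occlusion allow overlapping berries (`TRUE`, the field-realistic
#'   case) or resample to avoid overlaps.
#' @param count_range `c(min, max)` acceptable per-scene berry counts;
#'   scenes are rejection-resampled into this range.
#' @param max_retries bound on rejection resampling.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(256L, 256L), n_clusters = c(3L, 8L),
                       berries_per_cluster = 25, cluster_sigma = c(6, 16),
                       berry_radius = c(3, 6),
                       berry_color = c(0.45, 0.16, 0.35), color_jitter = 0.08,
                       background_amplitude = 0.15, occlusion = TRUE,
                       count_range = c(30L, 200L), max_retries = 20L) {
  if (length(n_clusters) == 1) n_clusters <- rep(n_clusters, 2)
  if (length(cluster_sigma) == 1) cluster_sigma <- rep(cluster_sigma, 2)
  if (length(berry_radius) == 1) berry_radius <- rep(berry_radius, 2)
  stopifnot(all(image_size %% 8 == 0), n_clusters[1] <= n_clusters[2],
            berry_radius[1] >= 1, berry_radius[1] <= berry_radius[2],
            count_range[1] <= count_range[2], berries_per_cluster >= 0)
  structure(list(image_size = as.integer(image_size),
                 n_clusters = as.integer(n_clusters),
                 berries_per_cluster = berries_per_cluster,
                 cluster_sigma = cluster_sigma, berry_radius = berry_radius,
                 berry_color = berry_color, color_jitter = color_jitter,
                 background_amplitude = background_amplitude,
                 occlusion = occlusion, count_range = count_range,
                 max_retries = as.integer(max_retries)),
            class = "scene_spec")
}

# bilinear upsample of a small matrix to H x W (background texture)
upsample_bilinear <- function(m, H, W) {
  yi <- seq(1, nrow(m), length.out = H)
  xi <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(yi), nrow(m) - 1); x0 <- pmin(floor(xi), ncol(m) - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1, drop = FALSE]
  c_ <- m[y0 + 1, x0, drop = FALSE]; d <- m[y0 + 1, x0 + 1, drop = FALSE]
  wa <- outer(1 - fy, 1 - fx); wb <- outer(1 - fy, fx)
  wc <- outer(fy, 1 - fx); wd <- outer(fy, fx)
  a * wa + b * wb + c_ * wc + d * wd
}

draw_scene_once <- function(spec) {
  W <- spec$image_size[1]; H <- spec$image_size[2]
  nc <- if (spec$n_clusters[1] == spec$n_clusters[2]) spec$n_clusters[1]
  else sample(spec$n_clusters[1]:spec$n_clusters[2], 1)
  centers <- cbind(x = runif(nc, 0, W), y = runif(nc, 0, H))
  sigmas <- runif(max(nc, 1), spec$cluster_sigma[1], spec$cluster_sigma[2])
  berries <- list()
  for (ci in seq_len(nc)) {
    nb <- stats::rpois(1, spec$berries_per_cluster)
    if (nb == 0) next
    bx <- centers[ci, "x"] + stats::rnorm(nb, sd = sigmas[ci])
    by <- centers[ci, "y"] + stats::rnorm(nb, sd = sigmas[ci])
    r <- runif(nb, spec$berry_radius[1], spec$berry_radius[2])
    keep <- bx >= 0 & bx < W & by >= 0 & by < H
    if (any(keep)) {
      berries[[length(berries) + 1]] <-
        cbind(x = bx[keep], y = by[keep], r = r[keep])
    }
  }
  berries <- if (length(berries)) do.call(rbind, berries)
  else matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "r")))
  if (!spec$occlusion && nrow(berries) > 1) {
    kept <- berries[1, , drop = FALSE]
    for (i in 2:nrow(berries)) {
      d2 <- (kept[, "x"] - berries[i, "x"])^2 + (kept[, "y"] - berries[i, "y"])^2
      if (all(d2 > (kept[, "r"] + berries[i, "r"])^2)) {
        kept <- rbind(kept, berries[i, , drop = FALSE])
      }
    }
    berries <- kept
  }
  berries
}

render_scene <- function(spec, berries) {
  W <- spec$image_size[1]; H <- spec$image_size[2]
  base <- c(0.33, 0.42, 0.26) # leafy background
  tex <- upsample_bilinear(matrix(runif(17 * 17, -1, 1), 17, 17), H, W)
  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(base[ch] + spec$background_amplitude * tex, 0), 1)
  }
  for (i in seq_len(nrow(berries))) {
    cx <- berries[i, "x"]; cy <- berries[i, "y"]; r <- berries[i, "r"]
    col <- pmin(pmax(spec$berry_color + stats::rnorm(3, sd = spec$color_jitter),
                     0), 1)
    rows <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
    cols <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
    r2 <- outer((rows - cy)^2, (cols - cx)^2, "+") / r^2
    inside <- r2 <= 1
    shade <- 0.45 + 0.55 * sqrt(pmax(1 - r2, 0))
    for (ch in 1:3) {
      patch <- img[rows + 1, cols + 1, ch]
      patch[inside] <- (col[ch] * shade)[inside]
      img[rows + 1, cols + 1, ch] <- patch
    }
  }
  img
}

#' Generate one synthetic berry scene
#'
#' Draws a clustered scene per [scene_spec()] and renders it. Scenes are
#' rejection-resampled until the berry count falls inside
#' `spec$count_range` (a hard guarantee); generation fails after
#' `spec$max_retries` attempts. Deterministic for a given seed: the same
#' seed yields a pixel-identical image and identical annotations.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed.
#' @param image_id identifier for the returned [point_set()].
#' @return List with `image` (`H x W x 3` array in `[0, 1]`) and `points`
#'   (a [point_set()]; one annotation per rendered berry center).
#' @export
generate_scene <- function(spec = scene_spec(), seed = 0L, image_id = "scene") {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    berries <- NULL
    for (attempt in seq_len(spec$max_retries)) {
      cand <- draw_scene_once(spec)
      if (nrow(cand) >= spec$count_range[1] &&
          nrow(cand) <= spec$count_range[2]) {
        berries <- cand
        break
      }
    }
    if (is.null(berries)) {
      stop(sprintf(
        "could not reach target count range [%d, %d] in %d attempts",
        spec$count_range[1], spec$count_range[2], spec$max_retries))
    }
    img <- render_scene(spec, berries)
    pts <- point_set(image_id, spec$image_size[1], spec$image_size[2],
                     berries[, c("x", "y"), drop = FALSE])
    list(image = img, points = pts)
  })
}

#' Generate a synthetic semi-supervised dataset on disk
#'
#' Writes `n_images` scenes as PNGs with a labeled/unlabeled partition:
#' labeled images get Labelme-style JSON and CSV annotations under
#' `annotations/`; unlabeled images' annotations are withheld in a
#' `sealed/` sidecar for post-hoc evaluation only. A `manifest.json`
#' records the partition, the scene settings, and the seed; re-reading it
#' reproduces the exact partition. The number of labeled images is
#' `max(1, floor(n_images * labeled_fraction))`.
#'
#' @param spec a [scene_spec()].
#' @param n_images number of scenes.
#' @param labeled_fraction fraction in (0, 1] carrying annotations.
#' @param dir output directory.
#' @param seed integer seed (drives per-image seeds and the partition).
#' @param force overwrite a non-empty existing directory.
#' @return The manifest list, invisibly.
#' @export
generate_dataset <- function(spec = scene_spec(), n_images, labeled_fraction,
                             dir, seed = 0L, force = FALSE) {
  if (!(labeled_fraction > 0 && labeled_fraction <= 1)) {
    stop("labeled_fraction must lie in (0, 1]")
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop("output directory ", dir, " is not empty (use force = TRUE)")
  }
  for (sub in c("images", "annotations", "sealed")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  ids <- sprintf("img_%03d", seq_len(n_images))
  n_labeled <- max(1L, floor(n_images * labeled_fraction))
  draws <- with_seed(seed, {
    list(image_seeds = sample.int(.Machine$integer.max - 1L, n_images),
         labeled_ids = sort(sample(ids, n_labeled)))
  })
  for (i in seq_len(n_images)) {
    sc <- generate_scene(spec, seed = draws$image_seeds[i], image_id = ids[i])
    png::writePNG(sc$image, file.path(dir, "images", paste0(ids[i], ".png")))
    if (ids[i] %in% draws$labeled_ids) {
      write_points_json(sc$points,
                        file.path(dir, "annotations", paste0(ids[i], ".json")))
      write_points_csv(sc$points,
                       file.path(dir, "annotations", paste0(ids[i], ".csv")))
    } else {
      write_points_csv(sc$points,
                       file.path(dir, "sealed", paste0(ids[i], ".csv")))
    }
  }
  manifest <- list(n_images = n_images, image_ids = ids,
                   labeled_ids = draws$labeled_ids,
                   unlabeled_ids = setdiff(ids, draws$labeled_ids),
                   labeled_fraction = labeled_fraction, seed = seed,
                   image_size = spec$image_size,
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a generated dataset back into memory
#'
#' @param dir dataset directory written by [generate_dataset()].
#' @param include_sealed also load the withheld annotations of unlabeled
#'   images (evaluation only; never feed these to training).
#' @return List with `labeled` and `unlabeled` record lists
#'   (`list(id, image, points)`; unlabeled `points` are `NULL` unless
#'   sealed annotations were requested) and the `manifest`.
#' @export
read_dataset <- function(dir, include_sealed = FALSE) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no dataset manifest at ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  w <- manifest$image_size[1]; h <- manifest$image_size[2]
  load_rec <- function(id, ann) {
    img <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    pts <- if (!is.null(ann)) read_points(ann, width = w, height = h,
                                          image_id = id)
    list(id = id, image = img, points = pts)
  }
  labeled <- lapply(manifest$labeled_ids, function(id) {
    load_rec(id, file.path(dir, "annotations", paste0(id, ".csv")))
  })
  unlabeled <- lapply(manifest$unlabeled_ids, function(id) {
    ann <- if (include_sealed) file.path(dir, "sealed", paste0(id, ".csv"))
    load_rec(id, ann)
  })
  list(labeled = labeled, unlabeled = unlabeled, manifest = manifest)
}
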