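# Synthetic single-cell MSI scenes with known ground truth: disk-shaped
# cells of two classes with class-specific lipid peaks, matrix-derived
# background ions, log-normal cell-to-cell variability, additive pixel
# noise, m/z jitter and optional per-peak ion mobility.

#' Default per-class lipid profiles
#'
#' Two cell populations modelled on a pancreatic cancer / stellate cell
#' contrast: shared phosphatidylcholine peaks, one class-exclusive
#' ether-PC marker (m/z 768.5853, absent from class A), and three
#' two-fold-shifted features. Negative mode uses a fatty-acid/LPE/PE/PS
#' panel (formula-derived m/z values); the DAN matrix base peak at
#' m/z 313.1428 is carried as a background ion. Intensities are mean ion
#' counts per pixel; `cv` is the log-normal cell-to-cell coefficient of
#' variation.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return named list of per-class data.frames (mz, mean, cv).
#' @export
default_class_profiles <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (polarity == "positive") {
    mz <- c(732.5537, 734.5676, 748.5827, 758.5685,
            760.5854, 768.5853, 782.5685, 786.5933)
    a <- c(4000, 1500, 1250, 3000, 6000,    0, 3000, 5000)
    b <- c(4000, 3000, 2500, 3000, 6000, 3000, 3000, 2500)
  } else {
    mz <- c(255.2330, 281.2486, 283.2643, 309.2799,
            478.2939, 506.3252, 744.5549, 788.5447)
    a <- c(12000, 15000, 10000, 5000, 4000, 3000, 6000, 5000)
    b <- c(6000, 5000, 10000, 2500, 4000, 3000, 6000, 5000)
  }
  list(A = data.frame(mz = mz, mean = a, cv = 0.2),
       B = data.frame(mz = mz, mean = b, cv = 0.2))
}

#' Default background (matrix-derived) ions
#'
#' Synthetic matrix-cluster masses inside the scan range; in negative
#' mode the DAN matrix base peak m/z 313.1428 dominates.
#'
#' @param polarity `"positive"` or `"negative"`.
#' @return data.frame (mz, mean).
#' @export
default_background_ions <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (polarity == "positive")
    data.frame(mz = c(412.3012, 428.7141, 445.1223, 472.4390,
                      515.3301, 548.6118, 602.0843, 655.2732),
               mean = rep(200, 8))
  else
    data.frame(mz = c(219.0801, 247.1302, 313.1428, 339.2011,
                      365.2288, 411.0712, 437.1925, 469.3108),
               mean = c(200, 200, 2000, 200, 200, 200, 200, 200))
}

#' Channel set matching the default synthetic scene
#' @param polarity `"positive"` or `"negative"`.
#' @return a [channel_set()] whose foreground channels are the 8 planted
#'   cell features and whose background channels are the 8 matrix ions.
#' @export
default_channels <- function(polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  channel_set(default_class_profiles(polarity)$A$mz,
              default_background_ions(polarity)$mz)
}

#' Synthetic scene specification
#'
#' Defaults describe the reference two-class acquisition used throughout
#' the package: a 160 x 160 px grid at 10 um raster with 52 cells per
#' class (104 total), disk radii 2-3 px, 20% cell-to-cell CV, additive
#' Gaussian pixel noise (sd 50 counts) and +/- 3 ppm m/z jitter, which
#' stays comfortably inside the 10 ppm extraction gates while exercising
#' the tolerance logic.
#'
#' @param width,height grid size, pixels.
#' @param pixel_size um per pixel.
#' @param polarity scene polarity.
#' @param n_cells named integer vector: cells per class; names must
#'   match `class_profiles`.
#' @param radius_range numeric length-2 disk radius bounds, pixels.
#' @param min_separation minimum edge-to-edge cell separation, pixels.
#' @param class_profiles per-class data.frames (mz, mean, cv, optional
#'   ook0); all classes share the mz panel.
#' @param background_ions data.frame (mz, mean, optional ook0).
#' @param noise_sd additive Gaussian pixel noise sd (counts).
#' @param mz_jitter_ppm uniform per-peak m/z jitter half-width (ppm).
#' @param mobility attach 1/K0 values to every peak?
#' @param seed integer RNG seed; a fixed seed makes the generated scene,
#'   and hence its imzML serialization, byte-identical across runs.
#' @return a `scene_spec`.
#' @export
scene_spec <- function(width = 160, height = 160, pixel_size = 10,
                       polarity = "positive",
                       n_cells = c(A = 52, B = 52),
                       radius_range = c(2, 3), min_separation = 3,
                       class_profiles = default_class_profiles(polarity),
                       background_ions = default_background_ions(polarity),
                       noise_sd = 50, mz_jitter_ppm = 3,
                       mobility = FALSE, seed = 1L) {
  stopifnot(width > 0, height > 0, all(n_cells >= 0),
            length(radius_range) == 2, radius_range[1] <= radius_range[2],
            radius_range[1] > 0,
            min_separation >= 0, noise_sd >= 0, mz_jitter_ppm >= 0)
  if (sum(n_cells) > 0 &&
      (is.null(names(n_cells)) || !all(names(n_cells) %in%
                                       names(class_profiles))))
    stop("names(n_cells) must match names(class_profiles)")
  for (cl in names(class_profiles))
    if (any(class_profiles[[cl]]$mean < 0))
      stop("class profile means must be >= 0")
  if (2 * radius_range[2] >= min(width, height))
    stop("cells do not fit inside the grid")
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 polarity = polarity, n_cells = n_cells,
                 radius_range = radius_range,
                 min_separation = min_separation,
                 class_profiles = class_profiles,
                 background_ions = background_ions,
                 noise_sd = noise_sd, mz_jitter_ppm = mz_jitter_ppm,
                 mobility = mobility, seed = as.integer(seed)),
            class = "scene_spec")
}

# deterministic pseudo-mobility for a feature m/z inside the 0.90-1.60
# scan range (roughly increasing with mass, as for singly charged lipids)
.default_ook0 <- function(mz) 0.95 + 0.6 * (mz - 200) / 800

# place disk cells by rejection sampling at >= min edge-to-edge separation
.place_cells <- function(spec) {
  classes <- rep(names(spec$n_cells), times = spec$n_cells)
  n <- length(classes)
  cx <- cy <- r <- numeric(n)
  max_tries <- 2000L * max(n, 1L)
  tries <- 0L; placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " cells at separation >= ",
           spec$min_separation, " in a ", spec$width, "x", spec$height,
           " grid after ", max_tries, " tries; reduce n_cells or ",
           "min_separation")
    ri <- runif(1, spec$radius_range[1], spec$radius_range[2])
    # a 4 px slide-edge margin (dropped on tiny grids) keeps cells inside
    # the grid even after a modest inter-run registration shift
    mx <- if (spec$width - 1 - 2 * ri > 10) 4 else 0
    my <- if (spec$height - 1 - 2 * ri > 10) 4 else 0
    xi <- runif(1, ri + mx, spec$width - 1 - ri - mx)
    yi <- runif(1, ri + my, spec$height - 1 - ri - my)
    if (placed > 0) {
      d <- sqrt((cx[seq_len(placed)] - xi)^2 + (cy[seq_len(placed)] - yi)^2)
      if (any(d < r[seq_len(placed)] + ri + spec$min_separation)) next
    }
    placed <- placed + 1L
    cx[placed] <- xi; cy[placed] <- yi; r[placed] <- ri
  }
  data.frame(cell_id = seq_len(n), class = classes,
             center_x = cx, center_y = cy, radius = r,
             stringsAsFactors = FALSE)
}

# render a scene for fixed cell geometry; assumes the RNG is positioned
# (draws cell factors first, then per-pixel noise in raster order)
.render_scene <- function(spec, cells) {
  n <- nrow(cells)
  feat_mz <- spec$class_profiles[[1]]$mz
  n_feat <- length(feat_mz)
  true_means <- matrix(0, max(n, 0), n_feat)
  for (i in seq_len(n)) {
    prof <- spec$class_profiles[[cells$class[i]]]
    cv <- prof$cv
    sdlog <- sqrt(log(1 + cv^2))
    fac <- ifelse(cv == 0, 1,
                  rlnorm(n_feat, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    true_means[i, ] <- prof$mean * fac
  }
  colnames(true_means) <- sprintf("%.4f", feat_mz)

  bg <- spec$background_ions
  bg_k0 <- if (!is.null(bg$ook0)) bg$ook0 else .default_ook0(bg$mz)
  prof_k0 <- lapply(spec$class_profiles, function(p)
    if (!is.null(p$ook0)) p$ook0 else .default_ook0(p$mz))

  owner <- matrix(0L, spec$height, spec$width)
  areas <- integer(n)
  for (i in seq_len(n)) {
    r <- cells$radius[i]
    c0 <- cells$center_x[i]; r0 <- cells$center_y[i]
    cols <- max(0, floor(c0 - r)):min(spec$width - 1, ceiling(c0 + r))
    rows <- max(0, floor(r0 - r)):min(spec$height - 1, ceiling(r0 + r))
    for (cc in cols) for (rr in rows) {
      if ((cc - c0)^2 + (rr - r0)^2 <= r^2) {
        owner[rr + 1L, cc + 1L] <- i
        areas[i] <- areas[i] + 1L
      }
    }
  }
  if (n > 0) cells$area <- areas

  n_px <- spec$width * spec$height
  coords <- cbind(col = rep(0:(spec$width - 1), times = spec$height),
                  row = rep(0:(spec$height - 1), each = spec$width))
  spectra <- vector("list", n_px)
  n_clip <- 0L; n_peak <- 0L
  for (k in seq_len(n_px)) {
    cc <- coords[k, 1]; rr <- coords[k, 2]
    own <- owner[rr + 1L, cc + 1L]
    if (own > 0L) {
      means <- c(bg$mean, unname(true_means[own, ]))
      mzs <- c(bg$mz, feat_mz)
      k0s <- c(bg_k0, prof_k0[[cells$class[own]]])
    } else {
      means <- bg$mean; mzs <- bg$mz; k0s <- bg_k0
    }
    present <- means > 0
    means <- means[present]; mzs <- mzs[present]; k0s <- k0s[present]
    intens <- means + if (spec$noise_sd > 0)
      rnorm(length(means), 0, spec$noise_sd) else 0
    n_peak <- n_peak + length(intens)
    clip <- intens < 0
    n_clip <- n_clip + sum(clip)
    intens[clip] <- 0
    jit <- if (spec$mz_jitter_ppm > 0)
      runif(length(mzs), -spec$mz_jitter_ppm, spec$mz_jitter_ppm) else 0
    mz_obs <- mzs * (1 + jit * 1e-6)
    so <- order(mz_obs)
    spectra[[k]] <- list(mz = mz_obs[so], intensity = intens[so],
                         ook0 = if (spec$mobility) k0s[so] else NULL)
  }
  ds <- msi_dataset(spec$width, spec$height, coords, spectra,
                    polarity = spec$polarity, pixel_size = spec$pixel_size)
  truth <- list(cells = cells, true_means = true_means,
                features = spec$class_profiles,
                clip_rate = if (n_peak > 0) n_clip / n_peak else 0)
  list(dataset = ds, truth = truth)
}

#' Simulate a synthetic single-cell MSI scene
#'
#' Disk-shaped cells are placed by rejection sampling at the requested
#' separation; pixels inside a cell receive the class profile peaks
#' scaled by a per-cell, per-feature log-normal factor (mean 1, the
#' given CV); all pixels receive the background ions; every peak gets
#' additive Gaussian noise clipped at 0 and uniform m/z jitter. With
#' `mobility = TRUE` each peak carries a 1/K0 value (profile `ook0`
#' column, or a deterministic mass-dependent default). A pixel is part
#' of a cell when its center lies within the disk radius, so ground
#' truth areas are the discretized pi r^2.
#'
#' @param spec a [scene_spec()].
#' @return list with `dataset` (an `msi_dataset`) and `truth`: `cells`
#'   table (cell_id, class, center, radius, area), `true_means`
#'   (cells x features matrix of planted per-cell means), `features`
#'   (per-class profile tables) and `clip_rate`, the fraction of peak
#'   intensities clipped at zero.
#' @export
simulate_scene <- function(spec = scene_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  cells <- .place_cells(spec)
  .render_scene(spec, cells)
}

#' Simulate paired dual-polarity acquisition runs
#'
#' Generates a positive-mode scene from `spec`, then a negative-mode
#' scene of the same cells with centers mapped through `transform`
#' (positive frame -> negative-run frame) and planted mean intensities
#' scaled by `signal_attenuation`, emulating the slight signal loss of a
#' second serial acquisition on the same cells. Ground truth records the
#' cell pairing (`paired_with`).
#'
#' @param spec a positive-mode [scene_spec()].
#' @param transform `registration_transform` mapping positive-frame
#'   coordinates into the negative-run frame (default identity).
#' @param signal_attenuation multiplier in (0, 1] applied to the
#'   negative-run planted means.
#' @param negative_profiles,negative_background profiles for the
#'   negative run (defaults: the bundled negative-mode panel).
#' @return list with `positive`, `negative` (each as from
#'   [simulate_scene()]) and `transform`.
#' @export
simulate_dual_runs <- function(spec = scene_spec(),
                               transform = identity_transform(),
                               signal_attenuation = 1,
                               negative_profiles =
                                 default_class_profiles("negative"),
                               negative_background =
                                 default_background_ions("negative")) {
  stopifnot(signal_attenuation > 0, signal_attenuation <= 1)
  pos <- simulate_scene(spec)
  cells <- pos$truth$cells
  centers_neg <- apply_transform(
    transform, as.matrix(cells[, c("center_x", "center_y")]))
  if (any(centers_neg[, 1] - cells$radius < 0) ||
      any(centers_neg[, 1] + cells$radius > spec$width - 1) ||
      any(centers_neg[, 2] - cells$radius < 0) ||
      any(centers_neg[, 2] + cells$radius > spec$height - 1))
    stop("transform maps cells outside the negative-run grid")
  neg_profiles <- lapply(negative_profiles, function(p) {
    p$mean <- p$mean * signal_attenuation
    p
  })
  neg_spec <- scene_spec(
    width = spec$width, height = spec$height, pixel_size = spec$pixel_size,
    polarity = "negative", n_cells = spec$n_cells,
    radius_range = spec$radius_range,
    min_separation = spec$min_separation,
    class_profiles = neg_profiles,
    background_ions = negative_background,
    noise_sd = spec$noise_sd, mz_jitter_ppm = spec$mz_jitter_ppm,
    mobility = spec$mobility, seed = spec$seed + 1L)
  cells_neg <- cells
  cells_neg$center_x <- centers_neg[, 1]
  cells_neg$center_y <- centers_neg[, 2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(neg_spec$seed)
  neg <- .render_scene(neg_spec, cells_neg)
  neg$truth$paired_with <- cells$cell_id
  list(positive = pos, negative = neg, transform = transform)
}

#' Match detected ROIs to ground-truth cells
#'
#' Assigns each detected ROI the planted cell whose center is nearest to
#' the ROI centroid (greedy over increasing distance, each truth cell
#' used once). Used to transfer class labels onto segmentation output
#' and to score recovery of planted scenes.
#'
#' @param rois ROI list from [segment_cells()].
#' @param truth_cells ground-truth cells table from [simulate_scene()].
#' @param max_dist maximum centroid-to-center distance (pixels).
#' @return data.frame (cell_id, truth_id, class, dist); truth_id NA for
#'   unmatched ROIs.
#' @export
match_rois_to_truth <- function(rois, truth_cells, max_dist = 3) {
  nr <- length(rois); nt <- nrow(truth_cells)
  out <- data.frame(cell_id = vapply(rois, `[[`, integer(1), "cell_id"),
                    truth_id = NA_integer_, class = NA_character_,
                    dist = NA_real_)
  if (nr == 0 || nt == 0) return(out)
  rc <- t(vapply(rois, `[[`, numeric(2), "centroid"))
  d <- sqrt(outer(rc[, 1], truth_cells$center_x, "-")^2 +
              outer(rc[, 2], truth_cells$center_y, "-")^2)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(cand)) {
    o <- order(d[cand], cand[, 1], cand[, 2])
    cand <- cand[o, , drop = FALSE]
    used_r <- logical(nr); used_t <- logical(nt)
    for (i in seq_len(nrow(cand))) {
      ri <- cand[i, 1]; ti <- cand[i, 2]
      if (!used_r[ri] && !used_t[ti]) {
        used_r[ri] <- TRUE; used_t[ti] <- TRUE
        out$truth_id[ri] <- truth_cells$cell_id[ti]
        out$class[ri] <- truth_cells$class[ti]
        out$dist[ri] <- d[ri, ti]
      }
    }
  }
  out
}
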