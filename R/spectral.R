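# Ion-image construction (ppm- and mobility-gated), peak picking,
# per-cell spectrum extraction/averaging, base-peak normalization,
# dual-polarity profile merging and feature-matrix assembly.

#' Build a ppm- and optionally mobility-gated ion image
#'
#' Every pixel's value is the sum of peak intensities with
#' |mz - center| / center * 1e6 <= tol_ppm and, when a mobility window is
#' given, 1/K0 inside the closed interval. Trapped ion mobility gating in
#' 1/K0 space resolves isobaric lipids that a pure m/z window cannot.
#' Grid positions without an acquired spectrum are NA (missing), not 0.
#' No normalization or denoising is applied.
#'
#' @param dataset an `msi_dataset`.
#' @param center_mz window center, Da (inside the dataset mass range).
#' @param tol_ppm half-width of the m/z window in ppm (default 10).
#' @param mobility_window optional numeric length-2 closed 1/K0 interval;
#'   requires mobility values in the dataset.
#' @return an `ion_image`: matrix (height x width) with attributes
#'   `center_mz`, `tol_ppm`, `mobility_window`.
#' @export
build_ion_image <- function(dataset, center_mz, tol_ppm = 10,
                            mobility_window = NULL) {
  stopifnot(inherits(dataset, "msi_dataset"))
  rng <- dataset$mass_range
  if (center_mz < rng[1] || center_mz > rng[2])
    stop("center_mz ", center_mz, " outside dataset mass range ",
         rng[1], "-", rng[2], " Da")
  if (!is.null(mobility_window)) {
    stopifnot(length(mobility_window) == 2)
    if (!msi_has_mobility(dataset))
      stop("mobility window requested but the dataset carries no 1/K0 values")
  }
  flat <- msi_flatten(dataset)
  tol <- center_mz * tol_ppm * 1e-6
  idx <- mz_window_idx(flat$mz, center_mz - tol, center_mz + tol)
  if (!is.null(mobility_window) && length(idx)) {
    k0 <- flat$ook0[idx]
    idx <- idx[!is.na(k0) & k0 >= mobility_window[1] &
                 k0 <= mobility_window[2]]
  }
  vals <- numeric(n_pixels(dataset))
  if (length(idx)) {
    part <- rowsum(flat$intensity[idx], flat$pixel[idx])
    vals[as.integer(rownames(part))] <- part[, 1]
  }
  img <- matrix(NA_real_, dataset$height, dataset$width)
  img[cbind(dataset$coords[, 2] + 1L, dataset$coords[, 1] + 1L)] <- vals
  structure(img, center_mz = center_mz, tol_ppm = tol_ppm,
            mobility_window = mobility_window,
            class = c("ion_image", "matrix", "array"))
}

#' Pick peaks from a spectrum
#'
#' Local maxima are centroided by intensity-weighted mean over a window
#' of width m/`resolution` (interpreted as the FWHM at that m/z);
#' centroids whose apex intensity falls below `intensity_threshold` are
#' discarded (inclusive boundary: an apex exactly at the threshold is
#' retained). Works on profile spectra and on already-centroided peak
#' lists alike.
#'
#' @param spectrum list with `mz`, `intensity` and optionally `ook0`.
#' @param resolution centroiding resolution (default 7000).
#' @param intensity_threshold minimum retained apex intensity
#'   (default 2000).
#' @return a `peak_list` data.frame with columns mz, intensity and, when
#'   present in the input, ook0.
#' @export
pick_peaks <- function(spectrum, resolution = 7000,
                       intensity_threshold = 2000) {
  stopifnot(resolution > 0, intensity_threshold >= 0)
  mz <- spectrum$mz; y <- spectrum$intensity
  n <- length(mz)
  empty <- peak_list(numeric(0), numeric(0),
                     if (!is.null(spectrum$ook0)) numeric(0) else NULL)
  if (n == 0) return(empty)
  # local maxima: strictly greater than left neighbour, >= right (plateaus
  # credited to their leftmost point); endpoints compare one-sided
  left_ok <- c(TRUE, y[-1] > y[-n])
  right_ok <- c(y[-n] >= y[-1], TRUE)
  apex <- which(left_ok & right_ok & y > 0)
  apex <- apex[y[apex] >= intensity_threshold]
  if (length(apex) == 0) return(empty)
  out_mz <- numeric(length(apex)); out_int <- numeric(length(apex))
  out_k0 <- rep(NA_real_, length(apex))
  for (i in seq_along(apex)) {
    a <- apex[i]
    half <- mz[a] / resolution / 2
    sel <- mz_window_idx(mz, mz[a] - half, mz[a] + half)
    wsum <- sum(y[sel])
    out_mz[i] <- if (wsum > 0) sum(mz[sel] * y[sel]) / wsum else mz[a]
    out_int[i] <- y[a]
    if (!is.null(spectrum$ook0)) out_k0[i] <- spectrum$ook0[a]
  }
  # windows of nearby apexes can converge to the same centroid; keep the
  # more intense one
  o <- order(out_mz)
  out_mz <- out_mz[o]; out_int <- out_int[o]; out_k0 <- out_k0[o]
  dup <- c(FALSE, diff(out_mz) <= 0)
  if (any(dup)) {
    keep <- !dup
    out_mz <- out_mz[keep]; out_int <- out_int[keep]; out_k0 <- out_k0[keep]
  }
  peak_list(out_mz, out_int,
            if (!is.null(spectrum$ook0)) out_k0 else NULL)
}

#' Construct a peak list
#' @param mz ascending m/z values.
#' @param intensity non-negative intensities.
#' @param ook0 optional 1/K0 values (NA allowed).
#' @return a `peak_list` data.frame.
#' @export
peak_list <- function(mz, intensity, ook0 = NULL) {
  if (length(mz) > 1 && any(diff(mz) <= 0)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (!is.null(ook0)) ook0 <- ook0[o]
  }
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity))
  if (!is.null(ook0)) df$ook0 <- as.numeric(ook0)
  class(df) <- c("peak_list", "data.frame")
  df
}

# single-linkage grouping of sorted m/z values: break where the ppm gap
# between consecutive values exceeds tol_ppm (relative to the smaller).
ppm_chain_groups <- function(mz_sorted, tol_ppm) {
  n <- length(mz_sorted)
  if (n == 0) return(integer(0))
  gaps <- diff(mz_sorted) / mz_sorted[-n] * 1e6
  cumsum(c(1L, as.integer(gaps > tol_ppm)))
}

#' Extract the averaged spectrum of a cell ROI
#'
#' Aligns the peaks of all pixel spectra of the ROI by single-linkage
#' grouping at `tol_ppm` and averages each consensus peak arithmetically
#' across the full cell area: pixels lacking the peak contribute 0, so
#' the result is area-weighted, not a mean over detecting pixels only.
#' Consensus m/z is the intensity-weighted mean of the grouped peaks.
#'
#' @param dataset an `msi_dataset`.
#' @param roi an ROI record from [segment_cells()] (needs `pixels`).
#' @param tol_ppm alignment tolerance (default 10).
#' @return a `peak_list` with attribute `n_pixels`.
#' @export
extract_cell_spectrum <- function(dataset, roi, tol_ppm = 10) {
  px <- roi$pixels
  if (is.null(px) || nrow(px) == 0) stop("empty ROI: no pixels to average")
  key <- dataset$coords[, 1] + as.numeric(dataset$coords[, 2]) * dataset$width
  want <- px[, 1] + as.numeric(px[, 2]) * dataset$width
  rows <- match(want, key)
  if (anyNA(rows))
    stop("ROI pixel (", px[which(is.na(rows))[1], 1], ",",
         px[which(is.na(rows))[1], 2], ") not present in the dataset")
  n_px <- length(rows)
  mz <- unlist(lapply(rows, function(i) dataset$spectra[[i]]$mz),
               use.names = FALSE)
  if (length(mz) == 0) {
    out <- peak_list(numeric(0), numeric(0))
    attr(out, "n_pixels") <- n_px
    return(out)
  }
  intensity <- unlist(lapply(rows, function(i) dataset$spectra[[i]]$intensity),
                      use.names = FALSE)
  k0 <- unlist(lapply(rows, function(i) {
    s <- dataset$spectra[[i]]
    if (is.null(s$ook0)) rep(NA_real_, length(s$mz)) else s$ook0
  }), use.names = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; k0 <- k0[o]
  grp <- ppm_chain_groups(mz, tol_ppm)
  wsum <- rowsum(intensity, grp)
  mzw <- rowsum(mz * intensity, grp)
  cons_mz <- ifelse(wsum[, 1] > 0, mzw[, 1] / wsum[, 1],
                    rowsum(mz, grp)[, 1] / rowsum(rep(1, length(mz)), grp)[, 1])
  cons_int <- wsum[, 1] / n_px   # zero-fill: divide by full cell area
  cons_k0 <- vapply(split(k0, grp), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  has_k0 <- any(!is.na(cons_k0))
  out <- peak_list(cons_mz, cons_int, if (has_k0) cons_k0 else NULL)
  attr(out, "n_pixels") <- n_px
  out
}

#' Normalize a peak list to a base peak
#'
#' Divides every intensity by the intensity of the peak matching
#' `base_mz` within `tol_ppm` (closest match when several qualify); the
#' base peak itself maps to 1. Matrix-derived base-peak normalization
#' puts per-cell intensities on a comparable relative scale.
#'
#' @param peaks a `peak_list`.
#' @param base_mz base peak m/z, Da (e.g. 313.1428, the negative-mode
#'   matrix base peak).
#' @param tol_ppm match tolerance (default 10).
#' @param cell_id optional identifier used in the error message.
#' @return the relative-intensity `peak_list`.
#' @export
normalize_to_base_peak <- function(peaks, base_mz, tol_ppm = 10,
                                   cell_id = NULL) {
  ppm <- abs(peaks$mz - base_mz) / base_mz * 1e6
  hit <- which(ppm <= tol_ppm)
  if (length(hit) == 0)
    stop("no base peak within ", tol_ppm, " ppm of m/z ", base_mz,
         if (!is.null(cell_id)) paste0(" in cell ", cell_id) else "")
  hit <- hit[which.min(ppm[hit])]
  base_int <- peaks$intensity[hit]
  if (base_int <= 0) stop("base peak has non-positive intensity")
  out <- peaks
  out$intensity <- peaks$intensity / base_int
  out
}

#' Assemble a per-cell profile
#' @param cell_id integer id.
#' @param positive,negative optional `peak_list`s (at least one).
#' @param n_pixels cell area used for averaging.
#' @param centroid numeric (x, y).
#' @param matched logical: paired across both polarities?
#' @export
cell_profile <- function(cell_id, positive = NULL, negative = NULL,
                         n_pixels = NA_integer_, centroid = c(NA, NA),
                         matched = NA) {
  if (is.null(positive) && is.null(negative))
    stop("a cell profile needs at least one polarity")
  structure(list(cell_id = cell_id, positive = positive,
                 negative = negative, n_pixels = n_pixels,
                 centroid = as.numeric(centroid), matched = matched),
            class = "cell_profile")
}

#' Merge dual-polarity acquisition runs per cell
#'
#' Serial positive- and negative-mode runs image the same cells; this
#' pairs their ROIs by greedy nearest-centroid matching after mapping
#' negative-run centroids into the positive frame with `transform`.
#' Matching is greedy over increasing distance (ties by smaller distance,
#' then smaller positive cell id, then smaller negative id), each cell
#' used at most once; pairs farther apart than `max_dist` are not made.
#' Unmatched cells are kept as single-polarity profiles with
#' `matched = FALSE`.
#'
#' @param pos_rois,neg_rois ROI lists from [segment_cells()] on each run.
#' @param pos_profiles,neg_profiles `peak_list`s parallel to the ROI
#'   lists (from [extract_cell_spectrum()]).
#' @param transform `registration_transform` mapping negative-run
#'   coordinates into the positive-run frame.
#' @param max_dist maximum centroid distance (pixels) for a pairing.
#' @return list of `cell_profile`s with a `match_summary` attribute
#'   (n_pos, n_neg, n_matched, match_rate).
#' @export
merge_dual_polarity <- function(pos_rois, neg_rois, pos_profiles,
                                neg_profiles, transform = identity_transform(),
                                max_dist = 3) {
  np <- length(pos_rois); nn <- length(neg_rois)
  stopifnot(length(pos_profiles) == np, length(neg_profiles) == nn)
  pos_c <- if (np) t(vapply(pos_rois, `[[`, numeric(2), "centroid")) else
    matrix(0, 0, 2)
  neg_c <- if (nn) t(vapply(neg_rois, `[[`, numeric(2), "centroid")) else
    matrix(0, 0, 2)
  if (nn) neg_c <- apply_transform(transform, neg_c)
  pairs <- NULL
  if (np && nn) {
    d <- sqrt(outer(pos_c[, 1], neg_c[, 1], "-")^2 +
                outer(pos_c[, 2], neg_c[, 2], "-")^2)
    cand <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand)) {
      o <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[o, , drop = FALSE]
      used_p <- logical(np); used_n <- logical(nn)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        p <- cand[i, 1]; q <- cand[i, 2]
        if (!used_p[p] && !used_n[q]) {
          used_p[p] <- TRUE; used_n[q] <- TRUE; keep[i] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(pairs)) pairs <- matrix(0L, 0, 2)
  profiles <- list(); id <- 0L
  matched_p <- logical(np); matched_n <- logical(nn)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, 1]; q <- pairs[i, 2]
    matched_p[p] <- TRUE; matched_n[q] <- TRUE
    id <- id + 1L
    profiles[[id]] <- cell_profile(
      id, positive = pos_profiles[[p]], negative = neg_profiles[[q]],
      n_pixels = pos_rois[[p]]$area, centroid = pos_rois[[p]]$centroid,
      matched = TRUE)
  }
  for (p in which(!matched_p)) {
    id <- id + 1L
    profiles[[id]] <- cell_profile(
      id, positive = pos_profiles[[p]], n_pixels = pos_rois[[p]]$area,
      centroid = pos_rois[[p]]$centroid, matched = FALSE)
  }
  for (q in which(!matched_n)) {
    id <- id + 1L
    profiles[[id]] <- cell_profile(
      id, negative = neg_profiles[[q]], n_pixels = neg_rois[[q]]$area,
      centroid = neg_c[q, ], matched = FALSE)
  }
  attr(profiles, "match_summary") <- list(
    n_pos = np, n_neg = nn, n_matched = nrow(pairs),
    match_rate = if (max(np, nn) > 0) nrow(pairs) / max(np, nn) else NA_real_)
  profiles
}

#' Build a cells x features matrix from per-cell profiles
#'
#' Peak m/z values are clustered across cells per polarity by
#' single-linkage at `align_tol_ppm`; clusters whose members carry
#' mobility values are further split at 1/K0 gaps larger than
#' `mobility_bin`. Each feature value is the cell's summed intensity in
#' the cluster; cells lacking the feature get 0. Features observed in
#' fewer than `min_frequency` of cells are dropped.
#'
#' @param profiles list of `cell_profile`s, or a list of plain
#'   `peak_list`s (taken as single-polarity profiles).
#' @param align_tol_ppm cross-cell alignment tolerance (default 10).
#' @param min_frequency minimum fraction of cells a feature must appear
#'   in (default 0.1).
#' @param mobility_bin 1/K0 gap splitting isobaric features
#'   (default 0.02 V s/cm^2).
#' @return a `feature_matrix`: numeric matrix (cells x features) with a
#'   `features` attribute data.frame (polarity, mz, ook0).
#' @export
build_feature_matrix <- function(profiles, align_tol_ppm = 10,
                                 min_frequency = 0.1, mobility_bin = 0.02) {
  stopifnot(length(profiles) >= 1)
  if (inherits(profiles[[1]], "peak_list")) {
    profiles <- lapply(seq_along(profiles), function(i)
      cell_profile(i, positive = profiles[[i]]))
  }
  n_cells <- length(profiles)
  cell_ids <- vapply(profiles, function(p) as.integer(p$cell_id), integer(1))
  rows <- list()
  for (pol in c("positive", "negative")) {
    for (i in seq_len(n_cells)) {
      pk <- profiles[[i]][[pol]]
      if (is.null(pk) || nrow(pk) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        cell = i, polarity = pol, mz = pk$mz, intensity = pk$intensity,
        ook0 = if (!is.null(pk$ook0)) pk$ook0 else NA_real_)
    }
  }
  if (length(rows) == 0) {
    m <- matrix(0, n_cells, 0, dimnames = list(cell_ids, NULL))
    attr(m, "features") <- data.frame(polarity = character(0),
                                      mz = numeric(0), ook0 = numeric(0))
    class(m) <- c("feature_matrix", "matrix", "array")
    return(m)
  }
  tab <- do.call(rbind, rows)
  feats <- list(); values <- list()
  for (pol in unique(tab$polarity)) {
    sub <- tab[tab$polarity == pol, ]
    o <- order(sub$mz)
    sub <- sub[o, ]
    grp <- ppm_chain_groups(sub$mz, align_tol_ppm)
    # split clusters at 1/K0 gaps when mobility is present
    final_grp <- grp
    offset <- 0L
    for (g in unique(grp)) {
      sel <- which(grp == g)
      k0 <- sub$ook0[sel]
      if (all(is.na(k0))) {
        final_grp[sel] <- offset + 1L; offset <- offset + 1L
      } else {
        ko <- order(k0, na.last = TRUE)
        kk <- k0[ko]
        known <- which(!is.na(kk))
        subgrp <- rep(1L, length(sel))
        if (length(known) > 1) {
          brks <- cumsum(c(1L, as.integer(diff(kk[known]) > mobility_bin)))
          subgrp[ko[known]] <- brks
        }
        # NAs join the first subgroup
        subgrp[ko[is.na(kk)]] <- 1L
        final_grp[sel] <- offset + subgrp
        offset <- offset + max(subgrp)
      }
    }
    for (g in sort(unique(final_grp))) {
      sel <- which(final_grp == g)
      wsum <- sum(sub$intensity[sel])
      cons_mz <- if (wsum > 0) sum(sub$mz[sel] * sub$intensity[sel]) / wsum
                 else mean(sub$mz[sel])
      k0v <- sub$ook0[sel][!is.na(sub$ook0[sel])]
      v <- numeric(n_cells)
      agg <- rowsum(sub$intensity[sel], sub$cell[sel])
      v[as.integer(rownames(agg))] <- agg[, 1]
      feats[[length(feats) + 1L]] <- data.frame(
        polarity = pol, mz = cons_mz,
        ook0 = if (length(k0v)) mean(k0v) else NA_real_)
      values[[length(values) + 1L]] <- v
    }
  }
  fdf <- do.call(rbind, feats)
  m <- do.call(cbind, values)
  freq <- colMeans(m > 0)
  keep <- freq >= min_frequency
  m <- m[, keep, drop = FALSE]
  fdf <- fdf[keep, , drop = FALSE]
  o <- order(fdf$polarity, fdf$mz)
  m <- m[, o, drop = FALSE]
  fdf <- fdf[o, , drop = FALSE]
  rownames(fdf) <- NULL
  colnames(m) <- paste0(substr(fdf$polarity, 1, 3), "_",
                        sprintf("%.4f", fdf$mz),
                        ifelse(is.na(fdf$ook0), "",
                               sprintf("@%.4f", fdf$ook0)))
  rownames(m) <- cell_ids
  attr(m, "features") <- fdf
  class(m) <- c("feature_matrix", "matrix", "array")
  m
}
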