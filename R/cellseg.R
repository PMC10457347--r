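# Automated cell detection from pixel spectra: summed foreground and
# background channel images, background subtraction, fixed-multiple
# thresholding, median filtering, connected-component labelling and
# area-based ROI filtering.

#' Foreground/background channel set
#'
#' Cell detection works on two summed channel images: 8 m/z values whose
#' signal is expected where cells sit (foreground) and 8 m/z values of
#' matrix-derived ions dominating cell-free regions (background). Each
#' channel is an m/z window of width +/- `tol_ppm`.
#'
#' @param foreground_mz,background_mz numeric vectors of exactly 8 m/z
#'   values (Da).
#' @param tol_ppm extraction tolerance in ppm (default 10).
#' @return a `channel_set`.
#' @export
channel_set <- function(foreground_mz, background_mz, tol_ppm = 10) {
  if (length(foreground_mz) != 8L)
    stop("'foreground_mz' must list exactly 8 m/z values")
  if (length(background_mz) != 8L)
    stop("'background_mz' must list exactly 8 m/z values")
  stopifnot(tol_ppm > 0)
  structure(list(foreground_mz = as.numeric(foreground_mz),
                 background_mz = as.numeric(background_mz),
                 tol_ppm = tol_ppm),
            class = "channel_set")
}

#' Segmentation parameters
#'
#' @param threshold_factor cells are pixels whose background-subtracted
#'   foreground sum reaches `threshold_factor` times the mean background
#'   channel sum (default 6).
#' @param median_kernel odd kernel size for the despeckling median filter
#'   (default 3).
#' @param area_min,area_max inclusive cell-area bounds in pixels; at a
#'   10 um raster the defaults 4 and 2000 px bracket mammalian cell
#'   footprints.
#' @param connectivity pixel adjacency for cell definition: 8
#'   (edges + diagonals, default) or 4.
#' @param subtract_background compare `fg - bg` against the threshold
#'   (default); `FALSE` compares the raw foreground sum instead.
#' @return a `seg_params`.
#' @export
seg_params <- function(threshold_factor = 6, median_kernel = 3,
                       area_min = 4, area_max = 2000, connectivity = 8,
                       subtract_background = TRUE) {
  stopifnot(threshold_factor > 0,
            median_kernel >= 1, median_kernel %% 2 == 1,
            area_min > 0, area_min <= area_max,
            connectivity %in% c(4, 8))
  structure(list(threshold_factor = threshold_factor,
                 median_kernel = as.integer(median_kernel),
                 area_min = as.integer(area_min),
                 area_max = as.integer(area_max),
                 connectivity = as.integer(connectivity),
                 subtract_background = isTRUE(subtract_background)),
            class = "seg_params")
}

#' Per-pixel summed channel images
#'
#' For every acquired pixel, sums all peak intensities falling inside any
#' of the 8 foreground windows (center +/- tol_ppm, closed interval) and,
#' separately, the 8 background windows. Pixels with no peak in a window
#' contribute 0 there. Grid positions never acquired are NA.
#'
#' @param dataset an `msi_dataset`.
#' @param channels a [channel_set()].
#' @return list of matrices `fg` and `bg` (height x width).
#' @export
channel_sums <- function(dataset, channels) {
  stopifnot(inherits(dataset, "msi_dataset"),
            inherits(channels, "channel_set"))
  rng <- dataset$mass_range
  all_mz <- c(channels$foreground_mz, channels$background_mz)
  if (any(all_mz < rng[1] | all_mz > rng[2]))
    stop("channel m/z outside the dataset mass range ",
         rng[1], "-", rng[2], " Da")
  flat <- msi_flatten(dataset)
  sum_windows <- function(centers) {
    acc <- numeric(n_pixels(dataset))
    for (c0 in centers) {
      tol <- c0 * channels$tol_ppm * 1e-6
      idx <- mz_window_idx(flat$mz, c0 - tol, c0 + tol)
      if (length(idx)) {
        part <- rowsum(flat$intensity[idx], flat$pixel[idx])
        acc[as.integer(rownames(part))] <-
          acc[as.integer(rownames(part))] + part[, 1]
      }
    }
    acc
  }
  fg <- matrix(NA_real_, dataset$height, dataset$width)
  bg <- fg
  ij <- cbind(dataset$coords[, 2] + 1L, dataset$coords[, 1] + 1L)
  fg[ij] <- sum_windows(channels$foreground_mz)
  bg[ij] <- sum_windows(channels$background_mz)
  list(fg = fg, bg = bg)
}

#' Threshold channel sums into a candidate cell mask
#'
#' A pixel is assigned as cell (1) when its background-subtracted
#' foreground sum is greater than or equal to `threshold_factor` times
#' the average background pixel intensity; the comparison is inclusive.
#' The average is the mean background-channel sum over all acquired
#' pixels of the region, a single-pass order-independent definition.
#' Negative subtracted sums are kept as-is; they simply fall below any
#' positive threshold.
#'
#' @param fg_sum,bg_sum matrices from [channel_sums()] (NA = pixel not
#'   acquired).
#' @param params a [seg_params()].
#' @return binary integer matrix (1 = candidate cell pixel).
#' @export
threshold_pixels <- function(fg_sum, bg_sum, params = seg_params()) {
  if (!all(dim(fg_sum) == dim(bg_sum)))
    stop("foreground and background grids differ in shape")
  mean_bg <- mean(bg_sum, na.rm = TRUE)
  if (is.nan(mean_bg)) mean_bg <- 0
  if (mean_bg == 0)
    warning("degenerate background model: mean background sum is 0, ",
            "every pixel with non-negative signal passes the threshold")
  value <- if (params$subtract_background) fg_sum - bg_sum else fg_sum
  out <- matrix(0L, nrow(fg_sum), ncol(fg_sum))
  out[!is.na(value) & value >= params$threshold_factor * mean_bg] <- 1L
  out
}

#' Median-filter a binary mask
#'
#' Each output pixel is the median of its kernel x kernel neighbourhood,
#' eliminating non-cellular single-pixel artifacts. Borders are padded
#' with 0: outside the acquisition region is background. For a binary
#' image the median equals the majority vote of the k^2 window.
#'
#' @param binary binary integer matrix.
#' @param kernel odd kernel size (>= 1).
#' @return filtered binary matrix, same shape.
#' @export
median_filter_mask <- function(binary, kernel = 3) {
  if (kernel %% 2 != 1 || kernel < 1) stop("'kernel' must be odd and >= 1")
  if (kernel == 1) return(binary)
  h <- nrow(binary); w <- ncol(binary)
  r <- (kernel - 1L) / 2L
  pad <- matrix(0L, h + 2L * r, w + 2L * r)
  pad[(r + 1L):(r + h), (r + 1L):(r + w)] <- binary
  # box sum via 2-D cumulative sums on the padded image
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed cumsum matrix
  cs <- t(cs)
  Z <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  Z[-1, -1] <- cs
  i0 <- seq_len(h); j0 <- seq_len(w)
  counts <- Z[i0 + kernel, j0 + kernel, drop = FALSE] -
    Z[i0, j0 + kernel, drop = FALSE] -
    Z[i0 + kernel, j0, drop = FALSE] + Z[i0, j0, drop = FALSE]
  out <- matrix(0L, h, w)
  out[counts >= (kernel * kernel + 1) / 2] <- 1L
  out
}

#' Label connected components as cells and extract ROIs
#'
#' Connected components of the binary mask under the configured
#' connectivity become cells; components whose pixel count falls outside
#' `[area_min, area_max]` are eliminated. Surviving cells are renumbered
#' 1..K in raster-scan order (row-major) of their first pixel, making the
#' labelling deterministic and platform-independent.
#'
#' @param binary binary integer matrix (post filtering).
#' @param params a [seg_params()].
#' @return list with `mask` (integer label matrix, 0 = background, class
#'   `cell_mask`) and `rois`, a list of ROI records (`cell_id`, `pixels`
#'   n x 2 matrix of 0-based (col, row), `area`, `centroid` = mean pixel
#'   coordinate (x, y)).
#' @export
label_cells <- function(binary, params = seg_params()) {
  h <- nrow(binary); w <- ncol(binary)
  raw_labels <- matrix(0L, h, w)
  if (params$connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L); dc <- c(0L, -1L, 1L, 0L)
  }
  nlab <- 0L
  # raster scan (row-major); flood fill each unlabelled foreground pixel
  for (row in seq_len(h)) {
    for (col in seq_len(w)) {
      if (binary[row, col] == 1L && raw_labels[row, col] == 0L) {
        nlab <- nlab + 1L
        stack <- matrix(c(row, col), 1, 2)
        raw_labels[row, col] <- nlab
        while (nrow(stack) > 0) {
          cur <- stack[nrow(stack), ]
          stack <- stack[-nrow(stack), , drop = FALSE]
          nr <- cur[1] + dr; nc <- cur[2] + dc
          ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
          nr <- nr[ok]; nc <- nc[ok]
          idx <- cbind(nr, nc)
          hit <- binary[idx] == 1L & raw_labels[idx] == 0L
          if (any(hit)) {
            idx <- idx[hit, , drop = FALSE]
            raw_labels[idx] <- nlab
            stack <- rbind(stack, idx)
          }
        }
      }
    }
  }
  # gather components, filter by area, renumber by first pixel raster order
  rois <- list(); mask <- matrix(0L, h, w)
  if (nlab > 0) {
    keep <- integer(0); first_pos <- numeric(0)
    comp_pixels <- vector("list", nlab)
    # pixel lists in raster order
    ord <- order(matrix(seq_len(h * w), h, w, byrow = FALSE))  # identity
    for (k in seq_len(nlab)) {
      lin <- which(raw_labels == k)  # column-major order
      rr <- ((lin - 1L) %% h) + 1L
      cc <- ((lin - 1L) %/% h) + 1L
      o <- order(rr, cc)             # raster (row-major) order
      comp_pixels[[k]] <- cbind(col = cc[o] - 1L, row = rr[o] - 1L)
      area <- length(lin)
      if (area >= params$area_min && area <= params$area_max) {
        keep <- c(keep, k)
        first_pos <- c(first_pos,
                       (rr[o][1] - 1) * w + (cc[o][1] - 1))
      }
    }
    keep <- keep[order(first_pos)]
    for (new_id in seq_along(keep)) {
      px <- comp_pixels[[keep[new_id]]]
      mask[cbind(px[, "row"] + 1L, px[, "col"] + 1L)] <- new_id
      rois[[new_id]] <- list(cell_id = new_id, pixels = px,
                             area = nrow(px),
                             centroid = c(x = mean(px[, "col"]),
                                          y = mean(px[, "row"])))
    }
  }
  class(mask) <- c("cell_mask", class(mask))
  list(mask = mask, rois = rois)
}

#' Segment cells in an MSI dataset
#'
#' Deterministic composition of the four detection steps: summed channel
#' images, background-subtracted thresholding at `threshold_factor` times
#' the mean background sum, median filtering, and connected-component
#' labelling with area bounds.
#'
#' @param dataset an `msi_dataset`.
#' @param channels a [channel_set()].
#' @param params a [seg_params()].
#' @return list with `mask`, `rois` (see [label_cells()]) and the
#'   intermediate `fg`/`bg` sum grids.
#' @export
segment_cells <- function(dataset, channels, params = seg_params()) {
  if (n_pixels(dataset) == 0) {
    mask <- matrix(0L, dataset$height, dataset$width)
    class(mask) <- c("cell_mask", class(mask))
    return(list(mask = mask, rois = list(), fg = mask * NA, bg = mask * NA))
  }
  sums <- channel_sums(dataset, channels)
  binary <- threshold_pixels(sums$fg, sums$bg, params)
  filtered <- median_filter_mask(binary, params$median_kernel)
  lab <- label_cells(filtered, params)
  c(lab, sums)
}

#' ROI summary table
#' @param rois ROI list from [label_cells()] or [segment_cells()].
#' @return data.frame with cell_id, area, centroid_x, centroid_y.
#' @export
roi_table <- function(rois) {
  if (length(rois) == 0)
    return(data.frame(cell_id = integer(0), area = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  data.frame(
    cell_id = vapply(rois, `[[`, integer(1), "cell_id"),
    area = vapply(rois, function(r) as.integer(r$area), integer(1)),
    centroid_x = vapply(rois, function(r) r$centroid[["x"]], numeric(1)),
    centroid_y = vapply(rois, function(r) r$centroid[["y"]], numeric(1)))
}
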