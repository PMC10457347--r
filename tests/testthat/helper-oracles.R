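# Brute-force oracles (naive loops, no vectorization) and small fixture
# builders shared across the test files.

# strip class and metadata attributes, keeping only the dim
plain_matrix <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

# build an msi_dataset from an explicit list of pixels:
#   pixels = list(list(col=, row=, mz=, intensity=, ook0=NULL), ...)
make_dataset <- function(width, height, pixels, polarity = "positive",
                         mass_range = NULL) {
  coords <- do.call(rbind, lapply(pixels, function(p) c(p$col, p$row)))
  if (is.null(coords)) coords <- matrix(integer(0), 0, 2)
  spectra <- lapply(pixels, function(p)
    list(mz = p$mz, intensity = p$intensity,
         ook0 = if (is.null(p$ook0)) NULL else p$ook0))
  msi_dataset(width, height, coords, spectra, polarity = polarity,
              mass_range = mass_range)
}

ppm_diff <- function(mz, ref) abs(mz - ref) / ref * 1e6

# naive per-pixel channel sums: nested loops over pixels, windows, peaks
naive_channel_sums <- function(dataset, channels) {
  fg <- matrix(NA_real_, dataset$height, dataset$width)
  bg <- fg
  for (i in seq_len(n_pixels(dataset))) {
    col <- dataset$coords[i, 1]; row <- dataset$coords[i, 2]
    sp <- dataset$spectra[[i]]
    s_fg <- 0; s_bg <- 0
    for (k in seq_along(sp$mz)) {
      for (c0 in channels$foreground_mz)
        if (ppm_diff(sp$mz[k], c0) <= channels$tol_ppm)
          s_fg <- s_fg + sp$intensity[k]
      for (c0 in channels$background_mz)
        if (ppm_diff(sp$mz[k], c0) <= channels$tol_ppm)
          s_bg <- s_bg + sp$intensity[k]
    }
    fg[row + 1, col + 1] <- s_fg
    bg[row + 1, col + 1] <- s_bg
  }
  list(fg = fg, bg = bg)
}

naive_threshold <- function(fg, bg, params) {
  mean_bg <- mean(bg, na.rm = TRUE)
  if (is.nan(mean_bg)) mean_bg <- 0
  out <- matrix(0L, nrow(fg), ncol(fg))
  for (r in seq_len(nrow(fg))) for (c in seq_len(ncol(fg))) {
    v <- if (params$subtract_background) fg[r, c] - bg[r, c] else fg[r, c]
    if (!is.na(v) && v >= params$threshold_factor * mean_bg)
      out[r, c] <- 1L
  }
  out
}

naive_median_filter <- function(binary, kernel) {
  if (kernel == 1) return(binary)
  h <- nrow(binary); w <- ncol(binary)
  r <- (kernel - 1) / 2
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- integer(0)
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      vals <- c(vals, if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        binary[ii, jj] else 0L)
    }
    out[i, j] <- as.integer(median(vals))
  }
  out
}

# independent labelling: iterative label propagation to convergence,
# then area filtering and raster-order renumbering
naive_label <- function(binary, params) {
  h <- nrow(binary); w <- ncol(binary)
  lab <- matrix(0L, h, w)
  lab[binary == 1L] <- seq_len(sum(binary))
  if (params$connectivity == 8) {
    nb <- expand.grid(di = -1:1, dj = -1:1)
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
  } else {
    nb <- data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (binary[i, j] != 1L) next
      for (k in seq_len(nrow(nb))) {
        ii <- i + nb$di[k]; jj <- j + nb$dj[k]
        if (ii >= 1 && ii <= h && jj >= 1 && jj <= w &&
            binary[ii, jj] == 1L && lab[ii, jj] < lab[i, j]) {
          lab[i, j] <- lab[ii, jj]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # area filter + renumber in raster-scan order of first pixel
  out <- matrix(0L, h, w)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  first_pos <- numeric(0); keep <- integer(0)
  for (id in ids) {
    npx <- sum(lab == id)
    if (npx >= params$area_min && npx <= params$area_max) {
      pos <- which(t(lab) == id) # row-major positions
      keep <- c(keep, id)
      first_pos <- c(first_pos, min(pos))
    }
  }
  keep <- keep[order(first_pos)]
  for (n in seq_along(keep)) out[lab == keep[n]] <- n
  out
}

naive_segment_mask <- function(dataset, channels, params) {
  s <- naive_channel_sums(dataset, channels)
  b <- suppressWarnings(naive_threshold(s$fg, s$bg, params))
  f <- naive_median_filter(b, params$median_kernel)
  naive_label(f, params)
}

naive_ion_image <- function(dataset, center, tol_ppm, window = NULL) {
  img <- matrix(NA_real_, dataset$height, dataset$width)
  for (i in seq_len(n_pixels(dataset))) {
    sp <- dataset$spectra[[i]]
    s <- 0
    for (k in seq_along(sp$mz)) {
      if (ppm_diff(sp$mz[k], center) > tol_ppm) next
      if (!is.null(window)) {
        k0 <- sp$ook0[k]
        if (is.na(k0) || k0 < window[1] || k0 > window[2]) next
      }
      s <- s + sp$intensity[k]
    }
    img[dataset$coords[i, 2] + 1, dataset$coords[i, 1] + 1] <- s
  }
  img
}

# random small dataset whose peaks scatter around a channel set
random_channel_dataset <- function(width, height, channels, seed,
                                   sprinkle_ppm = 20) {
  set.seed(seed)
  centers <- c(channels$foreground_mz, channels$background_mz)
  pixels <- list()
  for (col in 0:(width - 1)) for (row in 0:(height - 1)) {
    n <- sample(0:6, 1)
    if (n == 0) {
      pixels[[length(pixels) + 1]] <-
        list(col = col, row = row, mz = numeric(0), intensity = numeric(0))
      next
    }
    base <- sample(centers, n, replace = TRUE)
    mz <- sort(base * (1 + runif(n, -sprinkle_ppm, sprinkle_ppm) * 1e-6))
    mz <- mz[c(TRUE, diff(mz) > 0)]
    pixels[[length(pixels) + 1]] <-
      list(col = col, row = row, mz = mz,
           intensity = round(runif(length(mz), 0, 3000)))
  }
  make_dataset(width, height, pixels)
}

# tiny deterministic two-class scene for fast end-to-end tests
small_scene_spec <- function(seed, n_per_class = 8, width = 70,
                             height = 70, ...) {
  scene_spec(width = width, height = height,
             n_cells = c(A = n_per_class, B = n_per_class),
             seed = seed, ...)
}
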