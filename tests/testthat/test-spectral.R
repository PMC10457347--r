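# Ion images, peak picking, per-cell extraction, normalization,
# dual-polarity merging and feature-matrix assembly.

test_that("ion images gate by ppm and resolve isobars by mobility", {
  ds <- make_dataset(1, 1, list(
    list(col = 0, row = 0, mz = c(760.5854, 760.60),
         intensity = c(900, 50))))
  img <- build_ion_image(ds, 760.5854, tol_ppm = 10)
  expect_equal(img[1, 1], 900)  # second peak is 19 ppm away

  # isobar pair split by 1/K0 windows
  iso <- make_dataset(1, 1, list(
    list(col = 0, row = 0, mz = c(720.5497, 720.5866),
         intensity = c(800, 600), ook0 = c(1.4178, 1.4416))))
  both <- build_ion_image(iso, 720.568, tol_ppm = 40)
  expect_equal(both[1, 1], 1400)
  lo <- build_ion_image(iso, 720.568, 40, mobility_window = c(1.40, 1.43))
  expect_equal(lo[1, 1], 800)
  hi <- build_ion_image(iso, 720.568, 40, mobility_window = c(1.43, 1.45))
  expect_equal(hi[1, 1], 600)

  # zero tolerance keeps exact matches only
  exact <- build_ion_image(ds, 760.5854, tol_ppm = 0)
  expect_equal(exact[1, 1], 900)
  none <- build_ion_image(ds, 760.59, tol_ppm = 0)
  expect_equal(none[1, 1], 0)

  expect_error(build_ion_image(ds, 760.5854, 10, c(1.4, 1.5)), "1/K0")
  expect_error(build_ion_image(ds, 1, 10), "mass range")
})

test_that("unacquired grid positions are missing, not zero", {
  ds <- make_dataset(2, 1, list(
    list(col = 0, row = 0, mz = c(500), intensity = c(7))))
  img <- build_ion_image(ds, 500, 10)
  expect_equal(img[1, 1], 7)
  expect_true(is.na(img[1, 2]))
})

test_that("ion image totals match brute-force sums (conservation)", {
  sim <- simulate_scene(small_scene_spec(31, mobility = TRUE))
  for (center in c(760.5854, 786.5933, 412.3012)) {
    img <- build_ion_image(sim$dataset, center, 10)
    want <- naive_ion_image(sim$dataset, center, 10)
    expect_equal(plain_matrix(img), want)
  }
  win <- c(1.30, 1.40)
  imgw <- build_ion_image(sim$dataset, 760.5854, 10, win)
  expect_equal(plain_matrix(imgw), naive_ion_image(sim$dataset, 760.5854, 10, win))
})

test_that("narrowing a mobility window never increases pixel values", {
  sim <- simulate_scene(small_scene_spec(32, mobility = TRUE))
  wide <- build_ion_image(sim$dataset, 760.5854, 10, c(1.0, 1.6))
  narrow <- build_ion_image(sim$dataset, 760.5854, 10, c(1.30, 1.40))
  tight <- build_ion_image(sim$dataset, 760.5854, 10, c(1.36, 1.38))
  expect_true(all(narrow <= wide, na.rm = TRUE))
  expect_true(all(tight <= narrow, na.rm = TRUE))
})

test_that("peak picking centroids Gaussians and applies the threshold inclusively", {
  expect_equal(nrow(pick_peaks(list(mz = numeric(0),
                                    intensity = numeric(0)))), 0)

  tri <- list(mz = c(499.98, 500.00, 500.02), intensity = c(100, 2000, 100))
  expect_equal(nrow(pick_peaks(tri, 7000, 2000)), 1)  # apex 2000 retained
  tri$intensity[2] <- 1999
  expect_equal(nrow(pick_peaks(tri, 7000, 2000)), 0)  # apex 1999 discarded

  # two Gaussians 3 FWHM apart at resolution 7000 (FWHM 0.1 at m/z 700)
  fwhm <- 700 / 7000
  centers <- c(700.0, 700.0 + 3 * fwhm)
  grid <- seq(699.5, 700.9, by = 0.005)
  y <- 5000 * exp(-(grid - centers[1])^2 / (2 * (fwhm / 2.355)^2)) +
       4000 * exp(-(grid - centers[2])^2 / (2 * (fwhm / 2.355)^2))
  pk <- pick_peaks(list(mz = grid, intensity = y), 7000, 2000)
  expect_equal(nrow(pk), 2)
  expect_lt(abs(pk$mz[1] - centers[1]), 0.2 * fwhm)
  expect_lt(abs(pk$mz[2] - centers[2]), 0.2 * fwhm)
})

test_that("cell spectrum extraction averages over the full cell area", {
  # 1-pixel ROI: identity
  ds <- make_dataset(2, 1, list(
    list(col = 0, row = 0, mz = c(500.0, 600.0), intensity = c(800, 100)),
    list(col = 1, row = 0, mz = c(600.0), intensity = c(50))))
  roi1 <- list(cell_id = 1L, pixels = cbind(col = 0L, row = 0L),
               area = 1L, centroid = c(x = 0, y = 0))
  sp1 <- extract_cell_spectrum(ds, roi1)
  expect_equal(sp1$mz, c(500, 600))
  expect_equal(sp1$intensity, c(800, 100))

  # 2-pixel ROI, peak present in only one pixel: zero-fill mean
  roi2 <- list(cell_id = 2L, pixels = cbind(col = c(0L, 1L), row = c(0L, 0L)),
               area = 2L, centroid = c(x = 0.5, y = 0))
  sp2 <- extract_cell_spectrum(ds, roi2)
  expect_equal(sp2$intensity[sp2$mz == 500], 400)   # 800 / 2
  expect_equal(sp2$intensity[sp2$mz == 600], 75)    # (100 + 50) / 2

  expect_error(extract_cell_spectrum(
    ds, list(cell_id = 3L, pixels = matrix(integer(0), 0, 2))), "empty ROI")
})

test_that("extraction equals a naive per-feature pixel loop", {
  sim <- simulate_scene(small_scene_spec(33))
  seg <- segment_cells(sim$dataset, default_channels("positive"))
  roi <- seg$rois[[1]]
  got <- extract_cell_spectrum(sim$dataset, roi)
  feats <- default_class_profiles("positive")$A$mz
  for (f in feats) {
    # brute-force: mean over ROI pixels of summed intensity within 10 ppm
    tot <- 0
    for (i in seq_len(nrow(roi$pixels))) {
      sp <- msi_pixel(sim$dataset, roi$pixels[i, 1], roi$pixels[i, 2])
      sel <- abs(sp$mz - f) / f * 1e6 <= 10
      tot <- tot + sum(sp$intensity[sel])
    }
    want <- tot / nrow(roi$pixels)
    gsel <- abs(got$mz - f) / f * 1e6 <= 10
    if (want > 0) expect_equal(sum(got$intensity[gsel]), want,
                               tolerance = 1e-12)
  }

  # invariance to pixel ordering within the ROI
  roi_rev <- roi
  roi_rev$pixels <- roi$pixels[rev(seq_len(nrow(roi$pixels))), ]
  got_rev <- extract_cell_spectrum(sim$dataset, roi_rev)
  expect_equal(got$mz, got_rev$mz)
  expect_equal(got$intensity, got_rev$intensity)
})

test_that("base-peak normalization is exact, strict and idempotent", {
  pk <- peak_list(c(255.2330, 313.1428, 478.2939), c(500, 1000, 250))
  norm <- normalize_to_base_peak(pk, 313.1428)
  expect_equal(norm$intensity, c(0.5, 1, 0.25))

  # planted ratios recovered exactly
  ratios <- c(0.123456789, 1, 0.000777)
  pk2 <- peak_list(c(255.2330, 313.1428, 478.2939), ratios * 8123.77)
  norm2 <- normalize_to_base_peak(pk2, 313.1428)
  expect_equal(norm2$intensity, ratios, tolerance = 1e-12)

  # idempotence
  expect_equal(normalize_to_base_peak(norm, 313.1428)$intensity,
               norm$intensity)

  # absent base peak is an error naming the cell
  expect_error(normalize_to_base_peak(peak_list(500, 10), 313.1428,
                                      cell_id = 17), "cell 17")
})

make_rois_at <- function(centroids) {
  lapply(seq_len(nrow(centroids)), function(i)
    list(cell_id = i, pixels = NULL, area = 9L,
         centroid = c(x = centroids[i, 1], y = centroids[i, 2])))
}

test_that("dual-polarity merging pairs cells and flags the unmatched", {
  cen <- cbind(c(10, 30, 50), c(10, 20, 30))
  rois <- make_rois_at(cen)
  profs <- lapply(1:3, function(i) peak_list(500 + i, i))
  merged <- merge_dual_polarity(rois, rois, profs, profs,
                                identity_transform(), max_dist = 2)
  ms <- attr(merged, "match_summary")
  expect_equal(ms$n_matched, 3)
  expect_equal(ms$match_rate, 1)
  expect_true(all(vapply(merged, `[[`, logical(1), "matched")))
  # paired profiles carry matching ids (negative intensity encodes source)
  for (p in merged)
    expect_equal(p$positive$intensity, p$negative$intensity)

  # one centroid displaced beyond max_dist stays unmatched
  cen2 <- cen; cen2[2, ] <- cen2[2, ] + 5
  merged2 <- merge_dual_polarity(rois, make_rois_at(cen2), profs, profs,
                                 identity_transform(), max_dist = 2)
  ms2 <- attr(merged2, "match_summary")
  expect_equal(ms2$n_matched, 2)
  flags <- vapply(merged2, `[[`, logical(1), "matched")
  expect_equal(sum(!flags), 2)  # one unmatched per run
})

test_that("merging recovers planted pairings under a jittered similarity", {
  set.seed(101)
  n <- 40
  # centers on a jittered lattice, well separated
  gx <- rep(seq(10, 115, by = 15), times = 5)[1:n]
  gy <- rep(seq(10, 70, by = 15), each = 8)[1:n]
  pos_cen <- cbind(gx + runif(n, -2, 2), gy + runif(n, -2, 2))
  planted <- similarity_transform(scale = 1.01, rotation = 0.02,
                                  tx = 2.5, ty = -1.0)
  neg_cen <- apply_transform(planted, pos_cen) +
    matrix(rnorm(2 * n, 0, 0.3), n, 2)
  pos_profs <- lapply(1:n, function(i) peak_list(700, i))
  neg_profs <- lapply(1:n, function(i) peak_list(300, i))
  merged <- merge_dual_polarity(make_rois_at(pos_cen),
                                make_rois_at(neg_cen),
                                pos_profs, neg_profs,
                                invert_transform(planted), max_dist = 3)
  correct <- sum(vapply(merged, function(p)
    isTRUE(p$matched) &&
      p$positive$intensity == p$negative$intensity, logical(1)))
  expect_gte(correct, 39)

  # symmetric match count under the inverse transform
  merged_rev <- merge_dual_polarity(make_rois_at(neg_cen),
                                    make_rois_at(pos_cen),
                                    neg_profs, pos_profs,
                                    planted, max_dist = 3)
  expect_equal(attr(merged_rev, "match_summary")$n_matched,
               attr(merged, "match_summary")$n_matched)
})

test_that("feature matrices align peaks across cells", {
  # one cell: features are its peaks
  p1 <- peak_list(c(500.1, 600.2), c(10, 20))
  fm1 <- build_feature_matrix(list(p1), min_frequency = 0)
  expect_equal(dim(fm1), c(1L, 2L))
  expect_equal(unname(fm1[1, ]), c(10, 20))

  # two cells sharing one peak within 5 ppm merge into one feature
  pa <- peak_list(700.0000, 5)
  pb <- peak_list(700.0000 * (1 + 5e-6), 7)
  fm2 <- build_feature_matrix(list(pa, pb), align_tol_ppm = 10,
                              min_frequency = 0)
  expect_equal(ncol(fm2), 1)
  expect_equal(unname(fm2[, 1]), c(5, 7))

  # mobility bins split isobars into separate features
  pc <- peak_list(720.56, 100, ook0 = 1.4178)
  pd <- peak_list(720.56, 200, ook0 = 1.4416)
  fm3 <- build_feature_matrix(list(pc, pd), align_tol_ppm = 60,
                              min_frequency = 0)
  expect_equal(ncol(fm3), 2)
})

test_that("104 cells with 30 planted features yield a 104 x 30 matrix", {
  set.seed(55)
  feats <- sort(runif(30, 400, 950))
  profiles <- lapply(1:104, function(i) {
    jit <- feats * (1 + runif(30, -3e-6, 3e-6))
    peak_list(jit, rlnorm(30, log(1000), 0.2))
  })
  fm <- build_feature_matrix(profiles, align_tol_ppm = 10,
                             min_frequency = 0.1)
  expect_equal(dim(fm), c(104L, 30L))
  expect_true(all(is.finite(fm)))
})
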