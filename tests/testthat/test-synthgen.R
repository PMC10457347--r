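# Synthetic-scene generator: determinism, noiseless exactness, planted
# parameter recovery and dual-run pairing.

test_that("a fixed seed gives byte-identical imzML output", {
  dir <- withr::local_tempdir()
  sp <- scene_spec(width = 40, height = 40, n_cells = c(A = 3, B = 3),
                   seed = 9, mobility = TRUE)
  a <- simulate_scene(sp); b <- simulate_scene(sp)
  write_imzml(a$dataset, file.path(dir, "a.imzML"))
  write_imzml(b$dataset, file.path(dir, "b.imzML"))
  expect_identical(unname(tools::md5sum(file.path(dir, "a.imzML"))),
                   unname(tools::md5sum(file.path(dir, "b.imzML"))))
  expect_identical(unname(tools::md5sum(file.path(dir, "a.ibd"))),
                   unname(tools::md5sum(file.path(dir, "b.ibd"))))
  expect_identical(
    unname(tools::md5sum(file.path(dir, "a.imzML.mobility.csv"))),
    unname(tools::md5sum(file.path(dir, "b.imzML.mobility.csv"))))
  # different seeds differ
  c <- simulate_scene(scene_spec(width = 40, height = 40,
                                 n_cells = c(A = 3, B = 3), seed = 10))
  expect_false(identical(a$truth$cells$center_x, c$truth$cells$center_x))
})

test_that("a cell-free scene segments to zero ROIs", {
  sp <- scene_spec(width = 30, height = 30, n_cells = c(A = 0, B = 0),
                   seed = 2)
  sim <- simulate_scene(sp)
  expect_equal(nrow(sim$truth$cells), 0)
  seg <- segment_cells(sim$dataset, default_channels("positive"))
  expect_equal(length(seg$rois), 0)
})

test_that("the noiseless limit reproduces planted means exactly", {
  prof <- default_class_profiles("positive")
  prof$A$cv <- 0; prof$B$cv <- 0
  sp <- scene_spec(width = 60, height = 60, n_cells = c(A = 3, B = 3),
                   min_separation = 6, class_profiles = prof,
                   noise_sd = 0, seed = 21)
  sim <- simulate_scene(sp)
  expect_equal(sim$truth$clip_rate, 0)
  seg <- segment_cells(sim$dataset, default_channels("positive"))
  m <- match_rois_to_truth(seg$rois, sim$truth$cells, max_dist = 1)
  expect_true(all(!is.na(m$truth_id)))
  feat <- prof$A$mz
  for (i in seq_along(seg$rois)) {
    got <- extract_cell_spectrum(sim$dataset, seg$rois[[i]])
    planted <- sim$truth$true_means[m$truth_id[i], ]
    for (j in seq_along(feat)) {
      sel <- abs(got$mz - feat[j]) / feat[j] * 1e6 <= 10
      expect_equal(sum(got$intensity[sel]), unname(planted[j]),
                   tolerance = 1e-9)
    }
  }
})

test_that("group means recover planted means at CV 20% and n = 50", {
  sp <- scene_spec(width = 170, height = 170, n_cells = c(A = 50),
                   seed = 61)
  sim <- simulate_scene(sp)
  seg <- segment_cells(sim$dataset, default_channels("positive"))
  m <- match_rois_to_truth(seg$rois, sim$truth$cells)
  keep <- which(!is.na(m$truth_id))
  expect_gte(length(keep), 48)
  feat <- default_class_profiles("positive")$A
  prof_means <- matrix(0, length(keep), nrow(feat))
  for (k in seq_along(keep)) {
    got <- extract_cell_spectrum(sim$dataset, seg$rois[[keep[k]]])
    for (j in seq_len(nrow(feat))) {
      sel <- abs(got$mz - feat$mz[j]) / feat$mz[j] * 1e6 <= 10
      prof_means[k, j] <- sum(got$intensity[sel])
    }
  }
  # group mean of the extracted values should sit within 5% of the group
  # mean of the planted per-cell means for at least 95% of non-null
  # features (pipeline bias, separated from the log-normal sampling of
  # the cell factors themselves)
  planted <- colMeans(sim$truth$true_means[m$truth_id[keep], ])
  rel_bias <- abs(colMeans(prof_means) - planted) / pmax(planted, 1)
  ok <- rel_bias[planted > 0] < 0.05
  expect_gte(mean(ok), 0.95)
  # and the per-cell recovery itself is tight
  percell <- (prof_means - sim$truth$true_means[m$truth_id[keep], ]) /
    pmax(sim$truth$true_means[m$truth_id[keep], ], 1)
  expect_lt(max(abs(percell[, colMeans(prof_means) > 0])), 0.10)
})

test_that("scene structure separates foreground and background channels", {
  sim <- simulate_scene(small_scene_spec(41))
  sums <- channel_sums(sim$dataset, default_channels("positive"))
  inside <- matrix(FALSE, 70, 70)
  tr <- sim$truth$cells
  for (i in seq_len(nrow(tr))) {
    for (cc in 0:69) for (rr in 0:69) {
      if ((cc - tr$center_x[i])^2 + (rr - tr$center_y[i])^2 <=
          tr$radius[i]^2) inside[rr + 1, cc + 1] <- TRUE
    }
  }
  expect_gt(mean(sums$fg[inside]), 10 * mean(sums$fg[!inside]))
  expect_lt(abs(mean(sums$bg[inside]) - mean(sums$bg[!inside])),
            0.2 * mean(sums$bg[!inside]))
})

test_that("dual runs pair perfectly under the identity transform", {
  sp <- small_scene_spec(51)
  dual <- simulate_dual_runs(sp, identity_transform(),
                             signal_attenuation = 1)
  expect_identical(dual$negative$dataset$polarity, "negative")
  expect_equal(dual$negative$truth$paired_with,
               dual$positive$truth$cells$cell_id)
  pos_seg <- segment_cells(dual$positive$dataset,
                           default_channels("positive"))
  neg_seg <- segment_cells(dual$negative$dataset,
                           default_channels("negative"))
  pos_prof <- lapply(pos_seg$rois, function(r)
    extract_cell_spectrum(dual$positive$dataset, r))
  neg_prof <- lapply(neg_seg$rois, function(r)
    extract_cell_spectrum(dual$negative$dataset, r))
  merged <- merge_dual_polarity(pos_seg$rois, neg_seg$rois,
                                pos_prof, neg_prof,
                                identity_transform(), max_dist = 2)
  ms <- attr(merged, "match_summary")
  expect_equal(ms$n_matched, min(ms$n_pos, ms$n_neg))
  expect_equal(ms$match_rate, 1)
})

test_that("attenuation scales the negative-run planted means", {
  sp <- scene_spec(width = 50, height = 50, n_cells = c(A = 2, B = 2),
                   seed = 71)
  full <- simulate_dual_runs(sp, identity_transform(), 1)
  half <- simulate_dual_runs(sp, identity_transform(), 0.5)
  for (cl in c("A", "B"))
    expect_equal(half$negative$truth$features[[cl]]$mean,
                 full$negative$truth$features[[cl]]$mean / 2)
  # identical cell-level factors (same seed): true means exactly halved
  expect_equal(half$negative$truth$true_means,
               full$negative$truth$true_means / 2)
})

test_that("a translated second run is recovered via fitted registration", {
  sp <- scene_spec(width = 110, height = 110, n_cells = c(A = 15, B = 15),
                   seed = 81)
  planted <- similarity_transform(tx = 2.5, ty = -1.0)
  dual <- simulate_dual_runs(sp, planted, 0.8)
  pos_seg <- segment_cells(dual$positive$dataset,
                           default_channels("positive"))
  neg_seg <- segment_cells(dual$negative$dataset,
                           default_channels("negative"))
  # fit the registration from a few planted cell positions used as
  # control-point pairs (pen marks), mapping neg frame -> pos frame
  tr <- dual$positive$truth$cells
  src <- apply_transform(planted,
                         as.matrix(tr[1:5, c("center_x", "center_y")]))
  tf <- fit_registration(src, as.matrix(tr[1:5, c("center_x", "center_y")]))
  pos_prof <- lapply(pos_seg$rois, function(r)
    extract_cell_spectrum(dual$positive$dataset, r))
  neg_prof <- lapply(neg_seg$rois, function(r)
    extract_cell_spectrum(dual$negative$dataset, r))
  merged <- merge_dual_polarity(pos_seg$rois, neg_seg$rois,
                                pos_prof, neg_prof, tf, max_dist = 2)
  ms <- attr(merged, "match_summary")
  expect_gte(ms$n_matched / max(ms$n_pos, ms$n_neg), 0.95)
  expect_gte(ms$n_matched, 29)
})

test_that("impossible packing requests fail with guidance", {
  expect_error(simulate_scene(scene_spec(width = 20, height = 20,
                                         n_cells = c(A = 30, B = 30),
                                         seed = 1)),
               "reduce n_cells")
})
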