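# End-to-end classification benchmark on the reference two-class scene:
# simulate -> segment -> extract -> feature matrix -> 60/40 split ->
# SVM/RF/MLP held-out metrics, repeated over seeds.

#' Classification benchmark on synthetic two-class scenes
#'
#' Runs the full pipeline on the reference two-population scene (52
#' cells per class, one class-exclusive marker, three two-fold-shifted
#' features, 20% cell-to-cell CV) for a series of seeds and reports the
#' held-out accuracy, sensitivity and specificity of the SVM, random
#' forest and MLP classifiers under the 60/40 random split.
#'
#' @param n_seeds number of independent replicate scenes (default 10).
#' @param base_seed first seed; replicate r uses `base_seed + r - 1`.
#' @param spec_args optional list of [scene_spec()] argument overrides.
#' @param models classifier subset (default all three).
#' @return data.frame with one row per seed x model: seed, model,
#'   n_cells (detected), accuracy, sensitivity, specificity.
#' @export
run_classification_benchmark <- function(n_seeds = 10, base_seed = 1,
                                         spec_args = list(),
                                         models = c("svm", "random_forest",
                                                    "mlp")) {
  out <- list()
  for (r in seq_len(n_seeds)) {
    seed <- as.integer(base_seed + r - 1)
    spec <- do.call(scene_spec, c(spec_args, list(seed = seed)))
    sim <- simulate_scene(spec)
    seg <- segment_cells(sim$dataset, default_channels(spec$polarity))
    matched <- match_rois_to_truth(seg$rois, sim$truth$cells)
    keep <- which(!is.na(matched$class))
    profiles <- lapply(seg$rois[keep], function(roi)
      extract_cell_spectrum(sim$dataset, roi))
    fm <- build_feature_matrix(profiles)
    labels <- matched$class[keep]
    res <- train_and_evaluate(fm, labels, split_spec(0.6, seed),
                              models = models)
    for (m in names(res)) {
      cm <- res[[m]]
      out[[length(out) + 1L]] <- data.frame(
        seed = seed, model = m, n_cells = length(keep),
        accuracy = cm$accuracy, sensitivity = cm$sensitivity,
        specificity = cm$specificity)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
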