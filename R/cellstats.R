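# Statistical layer: random train/test split, supervised classification
# (SVM, random forest, MLP) with confusion-matrix metrics, UMAP
# embedding, per-feature group comparison, and ROI reproducibility (RSD).

#' Random train/test split specification
#' @param train_fraction fraction of cells assigned to training
#'   (default 0.6, the 6:4 split).
#' @param seed integer RNG seed.
#' @export
split_spec <- function(train_fraction = 0.6, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Randomly split labelled cells into training and testing sets
#'
#' Plain (non-stratified) random split; the training set has
#' `floor(train_fraction * n)` cells, so 104 cells at 0.6 give 62
#' training and 42 testing cells. Set `stratify = TRUE` to split within
#' each class instead.
#'
#' @param labels factor or vector of class labels, one per cell.
#' @param spec a [split_spec()].
#' @param stratify logical (default FALSE).
#' @return list with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, spec = split_spec(),
                             stratify = FALSE) {
  n <- length(labels)
  stopifnot(n >= 2)
  labels <- as.factor(labels)
  if (any(table(labels) < 2))
    stop("need at least 2 cells per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  if (stratify) {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      k <- floor(spec$train_fraction * length(idx))
      train <- c(train, sample(idx, k))
    }
    train <- sort(train)
  } else {
    k <- floor(spec$train_fraction * n)
    train <- sort(sample.int(n, k))
  }
  test <- setdiff(seq_len(n), train)
  if (length(setdiff(levels(labels), unique(labels[train]))) > 0 ||
      length(setdiff(levels(labels), unique(labels[test]))) > 0)
    warning("a class is absent from one partition; consider stratify = TRUE")
  list(train = train, test = test)
}

# save/restore global RNG state so seeded helpers do not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Confusion matrix with derived metrics
#'
#' Accuracy = (TP + TN) / (TP + TN + FP + FN),
#' Sensitivity = TP / (TP + FN), Specificity = TN / (TN + FP).
#' Ratios with a zero denominator are reported as NA, never 0.
#'
#' @param TP,TN,FP,FN non-negative integer counts.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  tot <- TP + TN + FP + FN
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    accuracy = if (tot > 0) (TP + TN) / tot else NA_real_,
    sensitivity = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
    specificity = if (TN + FP > 0) TN / (TN + FP) else NA_real_),
    class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix: TP", x$TP, "TN", x$TN, "FP", x$FP, "FN", x$FN, "\n")
  cat(sprintf("  accuracy %.4f  sensitivity %.4f  specificity %.4f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

# fit one classifier and predict test labels; features standardized for
# the MLP (nnet) using training-set statistics
.fit_predict <- function(model, x_train, y_train, x_test) {
  if (model == "svm") {
    fit <- e1071::svm(x_train, y_train, kernel = "radial")
    as.character(predict(fit, x_test))
  } else if (model == "random_forest") {
    fit <- randomForest::randomForest(x_train, y_train)
    as.character(predict(fit, x_test))
  } else if (model == "mlp") {
    mu <- colMeans(x_train)
    sg <- apply(x_train, 2, sd)
    sg[sg == 0 | is.na(sg)] <- 1
    xs <- scale(x_train, mu, sg)
    fit <- nnet::nnet(xs, nnet::class.ind(y_train), size = 8, decay = 0.01,
                      maxit = 500, trace = FALSE, softmax = TRUE)
    pred <- predict(fit, scale(x_test, mu, sg), type = "class")
    as.character(pred)
  } else stop("unknown model: ", model)
}

#' Train classifiers and evaluate on a held-out test set
#'
#' Splits the feature matrix with [split_train_test()], fits each
#' requested model on the training cells and computes the held-out
#' confusion matrix. The positive class for sensitivity/specificity is
#' the first factor level of `labels` unless given explicitly. Model
#' hyperparameters are the pinned defaults of the standard
#' implementations (e1071 radial SVM; randomForest with 500 trees; nnet
#' single-hidden-layer softmax, size 8, decay 0.01, standardized inputs).
#'
#' @param matrix numeric cells x features matrix.
#' @param labels class labels, one per row; exactly two classes.
#' @param spec a [split_spec()].
#' @param models character subset of `c("svm", "random_forest", "mlp")`.
#' @param positive positive class label (default: first factor level).
#' @return named list of `confusion_matrix` objects, one per model, with
#'   attribute `split`.
#' @export
train_and_evaluate <- function(matrix, labels, spec = split_spec(),
                               models = c("svm", "random_forest", "mlp"),
                               positive = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (!all(is.finite(matrix))) stop("feature matrix contains non-finite values")
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(positive)) positive <- levels(labels)[1]
  sp <- split_train_test(labels, spec)
  y_train <- droplevels(labels[sp$train])
  if (nlevels(y_train) < 2)
    stop("training partition contains a single class; reseed or stratify")
  x_train <- matrix[sp$train, , drop = FALSE]
  x_test <- matrix[sp$test, , drop = FALSE]
  y_test <- as.character(labels[sp$test])
  out <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (m in models) {
    set.seed(spec$seed)  # model-internal randomness (RF bagging, MLP init)
    pred <- .fit_predict(m, x_train, y_train, x_test)
    TP <- sum(pred == positive & y_test == positive)
    TN <- sum(pred != positive & y_test != positive)
    FP <- sum(pred == positive & y_test != positive)
    FN <- sum(pred != positive & y_test == positive)
    out[[m]] <- confusion_matrix(TP, TN, FP, FN)
  }
  attr(out, "split") <- sp
  attr(out, "positive") <- positive
  out
}

#' UMAP embedding of a feature matrix
#'
#' Two-dimensional Uniform Manifold Approximation and Projection of the
#' per-cell lipid profiles, delegated to the uwot implementation of the
#' published algorithm. Deterministic for a fixed seed (single-threaded
#' optimization). The contract is shape and per-seed determinism;
#' coordinate values are not comparable across library versions.
#'
#' @param matrix numeric cells x features matrix (>= 3 cells).
#' @param seed integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15, capped below
#'   the number of cells).
#' @return numeric matrix (cells x 2) of embedding coordinates.
#' @export
umap_embed <- function(matrix, seed = 1L, n_neighbors = 15) {
  n <- nrow(matrix)
  if (n < 3) stop("UMAP needs at least 3 cells")
  if (n_neighbors >= n)
    stop("n_neighbors (", n_neighbors, ") must be smaller than the number ",
         "of cells (", n, "); lower n_neighbors")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  emb <- uwot::umap(base::as.matrix(matrix), n_neighbors = n_neighbors,
                    n_components = 2, n_threads = 1, n_sgd_threads = 1,
                    batch = FALSE)
  rownames(emb) <- rownames(matrix)
  colnames(emb) <- c("x", "y")
  emb
}

#' Per-feature two-group comparison
#'
#' Equal-variance two-tailed Student's t-test per feature between groups
#' A and B on (typically base-peak-normalized) intensities, with
#' log2 fold change of group means and Benjamini-Hochberg adjusted
#' q-values alongside the raw p-values. Features with zero variance in
#' both groups and equal means get p = NA.
#'
#' @param a,b numeric matrices (cells x features) for the two groups,
#'   same columns; each group needs >= 2 cells.
#' @param var_equal use the pooled-variance Student test (default TRUE);
#'   FALSE switches to Welch.
#' @return data.frame: feature, mean_a, mean_b, log2fc, t, p, q.
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- base::as.matrix(a); b <- base::as.matrix(b)
  if (ncol(a) != ncol(b)) stop("groups must share the same features")
  if (nrow(a) < 2 || nrow(b) < 2) stop("each group needs at least 2 cells")
  nf <- ncol(a)
  res <- data.frame(
    feature = if (!is.null(colnames(a))) colnames(a) else
      paste0("f", seq_len(nf)),
    mean_a = colMeans(a), mean_b = colMeans(b),
    log2fc = NA_real_, t = NA_real_, p = NA_real_)
  res$log2fc <- log2(res$mean_a / res$mean_b)
  for (j in seq_len(nf)) {
    va <- stats::var(a[, j]); vb <- stats::var(b[, j])
    if (va == 0 && vb == 0) {
      if (res$mean_a[j] != res$mean_b[j]) {
        res$t[j] <- sign(res$mean_a[j] - res$mean_b[j]) * Inf
        res$p[j] <- 0
      }                                  # equal means: p stays NA
      next
    }
    ht <- t.test(a[, j], b[, j], var.equal = var_equal)
    res$t[j] <- unname(ht$statistic)
    res$p[j] <- ht$p.value
  }
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Relative standard deviation of replicate ROI means
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' times 100. Used for spot-to-spot reproducibility across replicate
#' imaging regions.
#'
#' @param mean_intensities numeric vector of per-ROI mean intensities
#'   (n >= 2).
#' @return RSD in percent; NA when the mean is 0.
#' @export
roi_rsd <- function(mean_intensities) {
  x <- as.numeric(mean_intensities)
  if (length(x) < 2) stop("RSD needs at least 2 replicate ROIs")
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * sd(x) / m
}
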