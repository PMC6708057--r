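#' Assign training labels to grid windows from ROI masks
#'
#' Applies the purity rule: a window enters training only if at least
#' `purity` of its pixels carry a single region label.  For the
#' segmentation task, windows that are at least `purity` inside the
#' definite-lung region (either lung, excluding projected heart and
#' diaphragm overlap) get label 1, windows at least `purity` inside the
#' definite-not-lung region (everything outside both lungs, heart and
#' diaphragm — the spine, mediastinum and the exterior of the rib cage) get
#' label 0, and all remaining, ambiguous windows are excluded (`NA`).  For
#' the pressure task every included lung window is labeled with the image's
#' pressure.
#'
#' @param grid A [make_window_grid()] over the mask grid.
#' @param rois A [roi_set()] (with derived masks) covering the same grid.
#' @param task `"segmentation"` or `"pressure"`.
#' @param purity Purity fraction in `(0.5, 1]` (default 0.95).
#' @param pressure Image pressure (required for the pressure task).
#' @return Integer vector, one element per window; `NA` marks excluded
#'   windows.
#' @export
assign_window_labels <- function(grid, rois,
                                 task = c("segmentation", "pressure"),
                                 purity = 0.95, pressure = NULL) {
  task <- match.arg(task)
  if (purity <= 0.5 || purity > 1) stop("purity must lie in (0.5, 1]")
  if (!all(dim(rois[[1]]) == c(grid$height, grid$width)))
    stop("ROI masks do not cover the grid's image")
  lung <- rois$right_lung | rois$left_lung
  lung_def <- lung & !rois$heart & !rois$diaphragm
  notlung_def <- !(lung | rois$heart | rois$diaphragm)
  npx <- grid$side^2
  org <- grid$origins + 1L
  f_lung <- window_sums(lung_def + 0, org, grid$side) / npx
  f_not <- window_sums(notlung_def + 0, org, grid$side) / npx
  lab <- rep(NA_integer_, grid$n_windows)
  if (task == "segmentation") {
    lab[f_lung >= purity] <- 1L
    lab[f_not >= purity] <- 0L
  } else {
    if (is.null(pressure)) stop("pressure task requires the image pressure")
    lab[f_lung >= purity] <- as.integer(pressure)
  }
  lab
}

#' Exactly balance class labels by seeded downsampling
#'
#' Each class is downsampled without replacement to the minority-class
#' count, so training labels are balanced exactly; rows with `NA` labels
#' (excluded windows) are dropped.
#'
#' @param ds A data frame with a `label` column.
#' @param seed Integer seed making the downsampling deterministic.
#' @return The balanced data frame.
#' @export
balance_labels <- function(ds, seed = 1L) {
  ds <- ds[!is.na(ds$label), , drop = FALSE]
  counts <- table(ds$label)
  if (length(counts) < 2) stop("balancing requires at least two classes")
  if (any(counts == 0)) stop("a class has zero rows")
  m <- min(counts)
  set.seed(as.integer(seed))
  keep <- unlist(lapply(names(counts), function(cl) {
    idx <- which(ds$label == cl)
    if (length(idx) > m) sort(sample(idx, m)) else idx
  }), use.names = FALSE)
  ds[sort(keep), , drop = FALSE]
}

#' Transform predictors to z-scores on a per-mouse basis
#'
#' Within each mouse's rows, each predictor column is centered to mean 0
#' and scaled to population standard deviation 1.  Zero-variance columns
#' map to 0.  Standardization uses only the mouse's own rows, so training
#' and validation mice never share statistics.
#'
#' @param ds A data frame with a `mouse_id` column and predictor columns.
#' @param columns Predictor columns to standardize (default
#'   [feature_columns()]).
#' @return The data frame with standardized predictors.
#' @export
zscore_per_mouse <- function(ds, columns = feature_columns()) {
  for (m in unique(ds$mouse_id)) {
    rows <- ds$mouse_id == m
    if (sum(rows) < 2) stop("per-mouse z-scoring needs >= 2 windows per mouse")
    for (cl in columns) {
      x <- ds[rows, cl]
      mu <- mean(x)
      sdv <- sqrt(mean((x - mu)^2))
      ds[rows, cl] <- if (sdv > 0) (x - mu) / sdv else 0
    }
  }
  ds
}

#' Train the window-texture random forest
#'
#' Random forest with `n_trees` trees (default 128) and the standard
#' classification defaults otherwise (sqrt(p) candidate predictors per
#' split, unlimited depth), on balanced, standardized training rows.
#'
#' @param ds Balanced, standardized data frame with `label` and predictor
#'   columns.
#' @param n_trees Number of trees.
#' @param seed Integer seed; predictions are deterministic given it.
#' @param columns Predictor columns.
#' @return A `randomForest` classifier.
#' @export
train_forest <- function(ds, n_trees = 128, seed = 1L,
                         columns = feature_columns()) {
  y <- factor(ds$label)
  if (nlevels(y) < 2) stop("training requires at least two classes")
  set.seed(as.integer(seed))
  randomForest::randomForest(x = ds[, columns, drop = FALSE], y = y,
                             ntree = n_trees)
}

#' Leave-one-mouse-out cross-validation
#'
#' For each mouse in turn: balance the training labels of all other mice
#' (seeded), train the forest, and score the held-out mouse's included
#' windows.  Per-mouse standardization should be applied to `ds` beforehand
#' (it uses only each mouse's own rows, so no information crosses the
#' train/validation split); [lomo_cv()] applies it when `standardize` is
#' `TRUE`.  Validation rows never enter training, by construction.
#'
#' @param ds Labeled cohort feature table: predictor columns plus
#'   `mouse_id`, `pressure`, `label` (NA = excluded).
#' @param task Label of the task, recorded in the report.
#' @param n_trees Trees per forest.
#' @param seed Master seed; per-fold sub-seeds are derived from it.
#' @param standardize Apply [zscore_per_mouse()] first (default TRUE).
#' @param columns Predictor columns.
#' @return An object of class `lomo_cv` with per-fold confusion matrices
#'   and accuracies, their mean and standard error (`sd/sqrt(n_folds)`),
#'   the pooled confusion matrix, and per-row hold-out predictions.
#' @export
lomo_cv <- function(ds, task = "segmentation", n_trees = 128, seed = 1L,
                    standardize = TRUE, columns = feature_columns()) {
  mice <- unique(ds$mouse_id)
  if (length(mice) < 2) stop("leave-one-mouse-out requires >= 2 mice")
  if (standardize) ds <- zscore_per_mouse(ds, columns)
  lev <- sort(unique(ds$label[!is.na(ds$label)]))
  folds <- list()
  for (i in seq_along(mice)) {
    m <- mice[i]
    train <- ds[ds$mouse_id != m & !is.na(ds$label), , drop = FALSE]
    test <- ds[ds$mouse_id == m & !is.na(ds$label), , drop = FALSE]
    if (length(unique(train$label)) < 2 || nrow(test) == 0) {
      warning(sprintf("fold %s skipped: training split lacks a class", m))
      next
    }
    train <- balance_labels(train, seed = derive_seed(seed, i))
    rf <- train_forest(train, n_trees = n_trees,
                       seed = derive_seed(seed, 1000L + i), columns = columns)
    pred <- stats::predict(rf, test[, columns, drop = FALSE])
    truth <- factor(test$label, levels = lev)
    pred <- factor(as.character(pred), levels = lev)
    cm <- table(truth = truth, predicted = pred)
    fold <- list(
      mouse_id = m, confusion = cm,
      accuracy = sum(diag(cm)) / sum(cm),
      train_counts = table(train$label),
      predictions = data.frame(mouse_id = m,
                               win_row = test$win_row, win_col = test$win_col,
                               pressure = test$pressure,
                               truth = test$label,
                               predicted = as.integer(as.character(pred))))
    # secondary accuracy over every window of the held-out mouse, ambiguous
    # ones scored against a majority-rule truth, when the table provides one
    if (!is.null(ds$majority_label)) {
      all_test <- ds[ds$mouse_id == m, , drop = FALSE]
      pall <- stats::predict(rf, all_test[, columns, drop = FALSE])
      fold$accuracy_all <- mean(as.character(pall) ==
                                  as.character(all_test$majority_label))
    }
    folds[[as.character(m)]] <- fold
  }
  if (length(folds) == 0) stop("no usable folds")
  acc <- vapply(folds, `[[`, numeric(1), "accuracy")
  pooled <- Reduce(`+`, lapply(folds, `[[`, "confusion"))
  structure(list(task = task, levels = lev, folds = folds,
                 accuracy = acc, mean_accuracy = mean(acc),
                 se_accuracy = stats::sd(acc) / sqrt(length(acc)),
                 confusion = pooled, n_trees = n_trees, seed = seed),
            class = "lomo_cv")
}

#' @export
print.lomo_cv <- function(x, ...) {
  cat(sprintf("Leave-one-mouse-out CV (%s task, %d trees)\n",
              x$task, x$n_trees))
  cat(sprintf("  %d folds, accuracy %.3f +- %.4f (mean +- SE)\n",
              length(x$folds), x$mean_accuracy, x$se_accuracy))
  invisible(x)
}

#' @export
summary.lomo_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold accuracy:\n")
  print(round(object$accuracy, 4))
  cat("\nPooled confusion matrix:\n")
  print(object$confusion)
  invisible(object)
}

#' Plurality vote over per-window class predictions
#'
#' The region-level class call is the most frequent per-window prediction;
#' ties are broken by the lowest class value so the call is deterministic.
#'
#' @param window_predictions Non-empty vector of predicted class labels
#'   (coercible to numeric, e.g. pressures).
#' @return The winning class, as numeric.
#' @export
plurality_vote <- function(window_predictions) {
  if (length(window_predictions) == 0) stop("no window predictions to vote on")
  tab <- table(window_predictions)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  min(winners)
}

#' Ensemble-averaged row-normalized confusion probabilities
#'
#' Each fold's confusion matrix is row-normalized (true class conditioned)
#' and the matrices are averaged over folds; every row of the result sums
#' to 1.  Empty rows yield `NaN` with a warning.
#'
#' @param cv A [lomo_cv()] report.
#' @return Square matrix of confusion probabilities (rows = true class).
#' @export
confusion_probabilities <- function(cv) {
  stopifnot(inherits(cv, "lomo_cv"))
  mats <- lapply(cv$folds, function(f) {
    cm <- as.matrix(f$confusion)
    rs <- rowSums(cm)
    if (any(rs == 0)) warning("empty confusion row in a fold; NaN produced")
    sweep(cm, 1L, rs, `/`)
  })
  Reduce(`+`, mats) / length(mats)
}

#' Distances from misclassified windows to the nearest known-lung window
#'
#' For every misclassified evaluation window, the Euclidean distance (in
#' pixels) between its center and the center of the nearest window known to
#' be lung, together with a Gaussian-kernel smoothed density and a matching
#' randomized null in which windows are drawn uniformly from the whole
#' grid.  The null sample is deliberately large (`n_null` draws, decoupled
#' from the usually small misclassification count) so that its median is a
#' low-variance estimate of the population value.
#'
#' @param predictions,truth Equal-length class vectors for the evaluated
#'   windows.
#' @param eval_idx Grid window indices (1-based) of the evaluated windows.
#' @param grid The [make_window_grid()].
#' @param lung_idx Grid window indices known to be lung (non-empty).
#' @param seed Seed for the randomized null.
#' @param n_null Number of uniform null draws (at least the number of
#'   misclassified windows).
#' @return A list of class `misclass_distances` with `distances`,
#'   `null_distances`, `density`, `null_density` (or `NULL`, flagged via
#'   `empty`, when there are no misclassifications).
#' @export
misclassification_distances <- function(predictions, truth, eval_idx, grid,
                                        lung_idx, seed = 1L, n_null = 1000L) {
  stopifnot(length(predictions) == length(truth),
            length(predictions) == length(eval_idx))
  if (length(lung_idx) == 0) stop("at least one known-lung window is required")
  lung_ctr <- grid$centers[lung_idx, , drop = FALSE]
  nearest_lung <- function(idx) {
    ctr <- grid$centers[idx, , drop = FALSE]
    vapply(seq_len(nrow(ctr)), function(i) {
      sqrt(min((lung_ctr[, 1L] - ctr[i, 1L])^2 +
                 (lung_ctr[, 2L] - ctr[i, 2L])^2))
    }, numeric(1))
  }
  mis <- eval_idx[predictions != truth]
  if (length(mis) == 0) {
    return(structure(list(distances = numeric(0), null_distances = numeric(0),
                          density = NULL, null_density = NULL, empty = TRUE),
                     class = "misclass_distances"))
  }
  d <- nearest_lung(mis)
  set.seed(as.integer(seed))
  rnd <- sample(grid$n_windows, max(n_null, length(mis)), replace = TRUE)
  d0 <- nearest_lung(rnd)
  # a kernel density needs >= 2 points and nonzero spread
  dens <- function(x) {
    if (length(x) >= 2 && stats::sd(x) > 0) {
      stats::density(x, kernel = "gaussian")
    } else {
      NULL
    }
  }
  structure(list(distances = d, null_distances = d0,
                 density = dens(d), null_density = dens(d0),
                 empty = FALSE),
            class = "misclass_distances")
}

#' @export
print.misclass_distances <- function(x, ...) {
  if (x$empty) {
    cat("misclass_distances: no misclassifications (density undefined)\n")
  } else {
    cat(sprintf(
      "misclass_distances: %d misclassified windows, median %.1f px (null %.1f px)\n",
      length(x$distances), stats::median(x$distances),
      stats::median(x$null_distances)))
  }
  invisible(x)
}

#' @export
plot.misclass_distances <- function(x, ...) {
  if (x$empty) stop("no misclassifications; density undefined")
  if (is.null(x$density) || is.null(x$null_density))
    stop("too few distinct distances for a density estimate")
  yl <- range(0, x$density$y, x$null_density$y)
  plot(x$density, main = "Misclassification distance to nearest lung window",
       xlab = "distance (px)", ylim = yl, ...)
  graphics::lines(x$null_density, lty = 2)
  graphics::legend("topright", legend = c("observed", "randomized null"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Enumerate the per-pressure segmentation experiments of a study design
#'
#' One segmentation experiment per (pressure, held-out mouse) cell: with 8
#' mice and 4 pressures, 32 experiments of 8 folds per pressure.
#'
#' @param n_mice Number of mice.
#' @param pressures Pressure levels.
#' @return Data frame with columns `pressure` and `holdout_mouse`.
#' @export
segmentation_experiments <- function(n_mice = 8, pressures = c(6, 8, 10, 12)) {
  expand.grid(holdout_mouse = sprintf("m%02d", seq_len(n_mice)),
              pressure = pressures, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("pressure", "holdout_mouse")]
}
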