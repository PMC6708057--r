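# tiny synthetic ROI layout on a 64x64 grid: lung block left, exterior right
tiny_rois <- function() {
  blank <- matrix(FALSE, 64, 64)
  rib <- blank; rib[1:64, 1:40] <- TRUE
  rl <- blank; rl[1:64, 1:32] <- TRUE
  ll <- blank
  heart <- blank
  dia <- blank
  derive_rois(roi_set(rib, rl, ll, heart, dia))
}

test_that("purity rule labels pure windows and excludes ambiguous ones", {
  rois <- tiny_rois()
  grid <- make_window_grid(64, 64)
  lab <- assign_window_labels(grid, rois, "segmentation", purity = 0.95)
  # window at col origin 0 lies fully inside the lung
  expect_equal(lab[grid$origins[, 2] == 0][1], 1L)
  # windows fully outside the rib cage (col origin 32: cols 33..64, not lung)
  full_out <- grid$origins[, 2] == 32
  expect_true(all(lab[full_out] == 0L))
  # window straddling the lung edge at col origin 16 covers cols 17..48:
  # 16 of 32 columns lung -> 50% purity -> excluded
  expect_true(all(is.na(lab[grid$origins[, 2] == 16])))
  expect_error(assign_window_labels(grid, rois, "segmentation", purity = 0.4),
               "purity")

  # 96% lung is included, 94% is excluded: shrink the lung edge per-row
  blank <- matrix(FALSE, 64, 64)
  rib <- blank; rib[, 1:40] <- TRUE
  rl96 <- blank; rl96[, 1:31] <- TRUE   # window cols 1:32 -> 31/32 = 96.9%
  r96 <- derive_rois(roi_set(rib, rl96, blank, blank, blank))
  lab96 <- assign_window_labels(grid, r96, "segmentation")
  expect_equal(lab96[1], 1L)
  rl94 <- blank; rl94[, 1:30] <- TRUE   # 30/32 = 93.75%
  r94 <- derive_rois(roi_set(rib, rl94, blank, blank, blank))
  lab94 <- assign_window_labels(grid, r94, "segmentation")
  expect_true(is.na(lab94[1]))

  # pressure task: included lung windows carry the image pressure
  labp <- assign_window_labels(grid, rois, "pressure", pressure = 12)
  expect_equal(labp[grid$origins[, 2] == 0][1], 12L)
  expect_true(all(is.na(labp[full_out])))
})

test_that("label balancing downsamples every class to the minority count", {
  ds <- data.frame(label = rep(c(0L, 1L), c(100, 60)), x = rnorm(160))
  b <- balance_labels(ds, seed = 1)
  expect_equal(as.integer(table(b$label)), c(60L, 60L))
  b2 <- balance_labels(ds, seed = 1)
  expect_identical(b, b2)                       # deterministic under seed
  expect_false(identical(b, balance_labels(ds, seed = 2)))
  ds4 <- data.frame(label = rep(c(6L, 8L, 10L, 12L), c(50, 40, 30, 20)))
  b4 <- balance_labels(ds4, seed = 3)
  expect_true(all(table(b4$label) == 20))
  already <- data.frame(label = rep(c(0L, 1L), each = 30))
  expect_equal(nrow(balance_labels(already, seed = 1)), 60)
  expect_error(balance_labels(data.frame(label = rep(1L, 5))), "two classes")
})

test_that("per-mouse z-scores have exact zero mean and unit population sd", {
  ds <- data.frame(mouse_id = rep(c("a", "b"), each = 3),
                   identity_loc = c(1, 2, 3, 11, 12, 13))
  z <- zscore_per_mouse(ds, "identity_loc")
  expect_equal(z$identity_loc[1:3], c(-1, 0, 1) * sqrt(1.5),
               tolerance = 1e-12)
  # two mice differing only by an offset standardize identically
  expect_equal(z$identity_loc[1:3], z$identity_loc[4:6], tolerance = 1e-12)
  cds <- data.frame(mouse_id = rep("a", 4), identity_loc = rep(5, 4))
  expect_true(all(zscore_per_mouse(cds, "identity_loc")$identity_loc == 0))
  set.seed(10)
  big <- fx_gaussian_ds()
  zb <- zscore_per_mouse(big)
  for (m in unique(zb$mouse_id)) {
    sub <- zb[zb$mouse_id == m, feature_columns()]
    expect_true(all(abs(colMeans(sub)) < 1e-9))
    psd <- sqrt(colMeans(sweep(sub, 2, colMeans(sub))^2))
    expect_true(all(abs(psd - 1) < 1e-9))
  }
})

test_that("the forest separates well-separated clouds and not permuted labels", {
  ds <- fx_gaussian_ds(n_per_class = 200, separation = 5)
  train_idx <- seq_len(300)
  rf <- train_forest(ds[train_idx, ], seed = 1)
  pred <- predict(rf, ds[-train_idx, feature_columns()])
  expect_gte(mean(pred == ds$label[-train_idx]), 0.99)

  set.seed(12)
  null_ds <- ds
  null_ds$label <- sample(null_ds$label)
  rfn <- train_forest(null_ds[train_idx, ], seed = 2)
  predn <- predict(rfn, null_ds[-train_idx, feature_columns()])
  accn <- mean(predn == null_ds$label[-train_idx])
  expect_gte(accn, 0.4)
  expect_lte(accn, 0.6)

  rf2 <- train_forest(ds[train_idx, ], seed = 1)
  expect_identical(predict(rf2, ds[-train_idx, feature_columns()]), pred)
  expect_error(train_forest(ds[ds$label == 1, ]), "two classes")
})

test_that("leave-one-mouse-out folds are exclusive, balanced and complete", {
  ds <- fx_gaussian_ds(n_per_class = 240, separation = 5, n_mice = 8)
  cv <- lomo_cv(ds, task = "segmentation", n_trees = 64, seed = 5)
  expect_length(cv$folds, 8)
  for (f in cv$folds) {
    # validation rows all belong to the held-out mouse
    expect_true(all(f$predictions$mouse_id == f$mouse_id))
    # training labels balanced exactly
    expect_equal(length(unique(f$train_counts)), 1L)
    # accuracy equals the confusion trace ratio
    expect_equal(f$accuracy, sum(diag(f$confusion)) / sum(f$confusion))
  }
  expect_equal(cv$mean_accuracy, mean(cv$accuracy))
  expect_equal(cv$se_accuracy, sd(cv$accuracy) / sqrt(8))
  expect_gte(cv$mean_accuracy, 0.99)  # separable clouds
  expect_error(lomo_cv(ds[ds$mouse_id == "m01", ]), "2 mice")
})

test_that("two identical separable mice give near-perfect fold accuracies", {
  ds1 <- fx_gaussian_ds(n_per_class = 150, separation = 5, n_mice = 1,
                        seed = 44)
  ds2 <- ds1
  ds2$mouse_id <- "m02"
  cv <- lomo_cv(rbind(ds1, ds2), n_trees = 64, seed = 6)
  expect_length(cv$folds, 2)
  expect_true(all(cv$accuracy >= 0.99))
})

test_that("plurality vote picks the modal class with low-pressure tie break", {
  expect_equal(plurality_vote(rep(c(6, 8, 10, 12), c(10, 5, 3, 2))), 6)
  expect_equal(plurality_vote(rep(c(6, 8), c(5, 5))), 6)
  expect_equal(plurality_vote(rep(12, 7)), 12)
  expect_equal(plurality_vote(rep(c(12, 8), c(5, 5))), 8)
  expect_error(plurality_vote(integer(0)), "no window predictions")
})

test_that("confusion probabilities are row-normalized fold averages", {
  fake_cv <- function(mats) {
    structure(list(task = "pressure",
                   folds = lapply(mats, function(m) list(confusion = m))),
              class = "lomo_cv")
  }
  perfect <- diag(c(10, 20, 30, 40))
  dimnames(perfect) <- list(truth = c(6, 8, 10, 12),
                            predicted = c(6, 8, 10, 12))
  cp <- confusion_probabilities(fake_cv(list(perfect, perfect)))
  expect_equal(unname(cp), diag(4))
  expect_true(all(abs(rowSums(cp) - 1) < 1e-12))
  # uniform random predictions approach 0.25 everywhere (Monte Carlo)
  set.seed(13)
  truth <- rep(c(6, 8, 10, 12), each = 1000)
  pred <- sample(c(6, 8, 10, 12), 4000, TRUE)
  cmr <- table(truth, pred)
  cpr <- confusion_probabilities(fake_cv(list(cmr)))
  expect_true(all(abs(cpr - 0.25) < 0.05))
})

test_that("misclassification distances follow the window geometry", {
  grid <- make_window_grid(128, 128)
  lung_idx <- which(grid$origins[, 1] == 0)  # top row of windows is lung
  # a misclassified window that is itself lung: distance 0
  d0 <- misclassification_distances(predictions = 0, truth = 1,
                                    eval_idx = lung_idx[1], grid = grid,
                                    lung_idx = lung_idx, seed = 1)
  expect_equal(d0$distances, 0)
  # one stride below a lung window: 16 px
  below <- which(grid$origins[, 1] == 16 & grid$origins[, 2] == 0)
  d1 <- misclassification_distances(0, 1, below, grid, lung_idx, seed = 1)
  expect_equal(d1$distances, 16)
  # no misclassifications: flagged, no density
  dn <- misclassification_distances(c(1, 1), c(1, 1), c(1, 2), grid,
                                    lung_idx, seed = 1)
  expect_true(dn$empty)
  expect_null(dn$density)
  expect_error(misclassification_distances(1, 0, 1, grid, integer(0)),
               "known-lung")
})

test_that("the study design enumerates 32 segmentation experiments", {
  ex <- segmentation_experiments(8, c(6, 8, 10, 12))
  expect_equal(nrow(ex), 32)
  expect_equal(as.integer(table(ex$pressure)), rep(8L, 4))
})
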