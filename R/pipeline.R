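#' Run configuration with study-pinned defaults
#'
#' A flat list of every tunable of the pipeline, defaulting to the pinned
#' analysis values: 32-px windows at stride 16, 0.01th/99.9th percentile
#' clips, bandpass sigma 2/8, 95% purity, 128 trees, pressures
#' {6, 8, 10, 12} cmH2O.  All randomness is funneled through the named
#' seeds.
#'
#' @param input_dir,output_dir Paths for the disk-based commands.
#' @param image_side Phantom image side in pixels.
#' @param n_mice Cohort size.
#' @param pressures Pressure set.
#' @param window_side,stride Window lattice parameters.
#' @param lo_pct,hi_pct Percentile clip fractions.
#' @param sigma_low,sigma_high Bandpass bounds (frequency-bin units).
#' @param n_angles,kernel_len Orientation-bank parameters.
#' @param purity Labeling purity fraction.
#' @param n_trees Forest size.
#' @param task `"segmentation"` or `"pressure"`.
#' @param seeds Named integer seeds (`cohort`, `balance`, `forest`,
#'   `kmeans`, `null`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = ".", output_dir = ".",
                       image_side = 512, n_mice = 8,
                       pressures = c(6, 8, 10, 12),
                       window_side = 32, stride = 16,
                       lo_pct = 0.0001, hi_pct = 0.999,
                       sigma_low = 2, sigma_high = 8,
                       n_angles = 12, kernel_len = 9,
                       purity = 0.95, n_trees = 128,
                       task = "segmentation",
                       seeds = c(cohort = 1L, balance = 2L, forest = 3L,
                                 kmeans = 4L, null = 5L)) {
  structure(as.list(environment()), class = "run_config")
}

#' Per-window labeled feature table of a whole cohort
#'
#' Runs feature extraction and window labeling on every image of a phantom
#' cohort and binds the results with mouse and pressure metadata — the
#' in-memory equivalent of the feature-extraction command.
#'
#' @param cohort A [generate_cohort()] result (list of `phantom_mouse`).
#' @param task Labeling task, `"segmentation"` or `"pressure"`.
#' @param purity Purity fraction for window labels.
#' @param global_range Grayscale range common to the study.
#' @param ... Passed to [build_feature_table()].
#' @return A `data.frame`: 11 predictors, window coordinates, `mouse_id`,
#'   `pressure`, `label` (NA = excluded), and `window_index` into the grid.
#' @export
cohort_features <- function(cohort, task = "segmentation", purity = 0.95,
                            global_range = c(0, 65535), ...) {
  tabs <- lapply(cohort, function(mouse) {
    grid <- make_window_grid(nrow(mouse$image), ncol(mouse$image))
    ft <- build_feature_table(mouse$image, grid, global_range, ...)
    ft$mouse_id <- mouse$spec$mouse_id
    ft$pressure <- mouse$spec$pressure
    ft$label <- assign_window_labels(grid, mouse$rois, task, purity,
                                     pressure = mouse$spec$pressure)
    if (task == "segmentation") {
      # majority-rule truth over the outer-envelope lung (overlap included),
      # used to also score the ambiguous windows excluded from training
      lung_env <- mouse$rois$right_lung | mouse$rois$left_lung
      f_env <- window_sums(lung_env + 0, grid$origins + 1L, grid$side) /
        grid$side^2
      ft$majority_label <- as.integer(f_env >= 0.5)
    }
    ft$window_index <- seq_len(grid$n_windows)
    ft
  })
  do.call(rbind, tabs)
}

#' Simulate command: write a phantom cohort to disk
#'
#' @param config A [run_config()].
#' @return Invisibly, the vector of files written.
#' @export
cmd_simulate <- function(config) {
  cohort <- generate_cohort(n_mice = config$n_mice,
                            pressures = config$pressures,
                            master_seed = config$seeds[["cohort"]],
                            image_side = config$image_side)
  files <- unlist(lapply(cohort, write_phantom, dir = config$output_dir))
  message(sprintf("wrote %d images to %s", length(cohort), config$output_dir))
  invisible(files)
}

#' Features command: one feature CSV per image on disk
#'
#' Reads each phantom TIFF and its masks from `input_dir`, extracts the
#' feature table, and writes one CSV per image into `output_dir`.  Images
#' with missing masks are skipped with a message and the run continues.
#'
#' @param config A [run_config()].
#' @return Invisibly, the vector of CSVs written.
#' @export
cmd_features <- function(config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tifs <- list.files(config$input_dir, pattern = "\\.tif$", full.names = TRUE)
  written <- character(0)
  for (tf in tifs) {
    stem <- sub("\\.tif$", "", basename(tf))
    meta <- file.path(config$input_dir, paste0(stem, ".json"))
    masks <- list.files(config$input_dir,
                        pattern = paste0("^", stem, "_roi_.*\\.png$"),
                        full.names = TRUE)
    mask_names <- sub(paste0("^", stem, "_roi_"), "",
                      sub("\\.png$", "", basename(masks)))
    need <- c("rib_cage", "right_lung", "left_lung", "heart", "diaphragm")
    if (!file.exists(meta) || !all(need %in% mask_names)) {
      message("skipping ", stem, ": missing sidecar or masks")
      next
    }
    img <- read_gray_tiff(tf)
    sp <- jsonlite::read_json(meta, simplifyVector = TRUE)
    rois <- lapply(masks, read_mask_png)
    names(rois) <- mask_names
    rois <- derive_rois(do.call(roi_set, rois[need]))
    grid <- make_window_grid(nrow(img), ncol(img),
                             config$window_side, config$stride)
    ft <- build_feature_table(img, grid,
                              n_angles = config$n_angles,
                              kernel_len = config$kernel_len,
                              sigma_low = config$sigma_low,
                              sigma_high = config$sigma_high)
    ft$mouse_id <- sp$mouse_id
    ft$pressure <- sp$pressure
    ft$label <- assign_window_labels(grid, rois, config$task, config$purity,
                                     pressure = sp$pressure)
    ft$window_index <- seq_len(grid$n_windows)
    out <- file.path(config$output_dir, paste0(stem, "_features.csv"))
    utils::write.csv(ft, out, row.names = FALSE)
    written <- c(written, out)
  }
  invisible(written)
}

#' Classify command: leave-one-mouse-out CV from feature CSVs
#'
#' Pools the feature CSVs of `input_dir`, runs [lomo_cv()], and writes the
#' report as JSON plus the pooled confusion matrix as CSV.
#'
#' @param config A [run_config()].
#' @return The [lomo_cv()] report, invisibly.
#' @export
cmd_classify <- function(config) {
  csvs <- list.files(config$input_dir, pattern = "_features\\.csv$",
                     full.names = TRUE)
  if (length(csvs) == 0) stop("no feature CSVs in ", config$input_dir)
  ds <- do.call(rbind, lapply(csvs, utils::read.csv))
  if (length(unique(ds$mouse_id)) < 2)
    stop("leave-one-mouse-out needs >= 2 mice")
  cv <- lomo_cv(ds, task = config$task, n_trees = config$n_trees,
                seed = config$seeds[["forest"]])
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- list(task = cv$task, n_folds = length(cv$folds),
              accuracy = unname(cv$accuracy),
              mean_accuracy = cv$mean_accuracy,
              se_accuracy = cv$se_accuracy)
  jsonlite::write_json(rep, file.path(config$output_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame.matrix(cv$confusion),
                   file.path(config$output_dir, "confusion.csv"))
  invisible(cv)
}
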