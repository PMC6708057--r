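# Lazily computed, cached fixtures shared across test files.  Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# One default phantom mouse (512 px, 10 cmH2O, seed 7).
fx_mouse <- function() {
  fixture("mouse", function() generate_mouse(phantom_spec(seed = 7)))
}

# Its feature table and grid.
fx_mouse_features <- function() {
  fixture("mouse_features", function() {
    m <- fx_mouse()
    grid <- make_window_grid(nrow(m$image), ncol(m$image))
    list(grid = grid, ft = build_feature_table(m$image, grid), mouse = m)
  })
}

# Labeled segmentation feature table for an 8-mouse cohort at one pressure
# and a given flat gain level (near-flat gain map; the map must be strictly
# increasing in pressure, but only pressure 6 is generated).
fx_seg_features <- function(gain) {
  key <- sprintf("seg_features_%g", gain)
  fixture(key, function() {
    tg <- c(`6` = gain, `8` = gain * 1.001, `10` = gain * 1.002,
            `12` = gain * 1.003)
    coh <- generate_cohort(n_mice = 8, pressures = 6, master_seed = 101,
                           texture_gain = tg)
    cohort_features(coh, task = "segmentation")
  })
}

fx_seg_cv <- function(gain) {
  key <- sprintf("seg_cv_%g", gain)
  fixture(key, function() {
    lomo_cv(fx_seg_features(gain), task = "segmentation", n_trees = 128,
            seed = 7)
  })
}

# Full 8-mouse x 4-pressure cohort, pressure-task features (default gains).
fx_pressure_features <- function() {
  fixture("pressure_features", function() {
    coh <- generate_cohort(n_mice = 8, pressures = c(6, 8, 10, 12),
                           master_seed = 202)
    cohort_features(coh, task = "pressure")
  })
}

fx_pressure_cv <- function() {
  fixture("pressure_cv", function() {
    lomo_cv(fx_pressure_features(), task = "pressure", n_trees = 128,
            seed = 9)
  })
}

# Synthetic two-class gaussian feature data (for classifier plumbing tests).
fx_gaussian_ds <- function(n_per_class = 200, separation = 5, n_mice = 4,
                           seed = 33) {
  set.seed(seed)
  p <- length(feature_columns())
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  lab <- rep(c(0L, 1L), each = n_per_class)
  x[lab == 1L, 1:3] <- x[lab == 1L, 1:3] + separation
  ds <- as.data.frame(x)
  names(ds) <- feature_columns()
  ds$label <- lab
  ds$mouse_id <- rep_len(sprintf("m%02d", seq_len(n_mice)), n)
  ds$pressure <- 10L
  ds$win_row <- seq_len(n)
  ds$win_col <- seq_len(n)
  ds
}

# Fresh scratch directory for disk round-trip tests.
withr_like_tempdir <- function() {
  d <- tempfile("lungtexture-test-")
  dir.create(d)
  d
}

# Brute-force Kendall tau-b oracle: O(n^2) concordant/discordant pair count
# with tie adjustment.
kendall_tau_oracle <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  npairs <- n * (n - 1) / 2
  (conc - disc) / sqrt((npairs - tx) * (npairs - ty))
}

# Construct an orientation PDF object directly from probabilities.
make_pdf <- function(p, n_angles = length(p)) {
  structure(list(angles = lungtexture:::orientation_bin_centers(n_angles),
                 p = p / sum(p)),
            class = "orientation_pdf")
}
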