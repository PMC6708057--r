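#' Lattice of square analysis windows over an image
#'
#' Overlapping square windows (default 32 px at stride 16) whose per-window
#' statistics form the predictor table.  Origins are 0-based (top-left
#' corner), windows are half-open `[r, r+side) x [c, c+side)` and only
#' windows fully inside the image are kept; the lattice is enumerated in
#' row-major order (columns fastest).
#'
#' @param height,width Image dimensions in pixels.
#' @param side Window side in pixels (default 32).
#' @param stride Stride between window origins in pixels (default 16).
#' @return A list of class `window_grid` with `origins` (n x 2 integer
#'   matrix of 0-based row/col corners), `centers` (origin + side/2),
#'   `n_rows`, `n_cols`, and the generating parameters.
#' @examples
#' make_window_grid(1984, 1984)$n_windows  # 15129
#' @export
make_window_grid <- function(height, width, side = 32, stride = 16) {
  stopifnot(stride >= 1)
  if (side > min(height, width))
    stop("window side exceeds an image dimension")
  r0 <- seq(0L, height - side, by = stride)
  c0 <- seq(0L, width - side, by = stride)
  origins <- cbind(row = rep(r0, each = length(c0)),
                   col = rep(c0, times = length(r0)))
  structure(list(side = as.integer(side), stride = as.integer(stride),
                 height = as.integer(height), width = as.integer(width),
                 origins = origins, centers = origins + side / 2,
                 n_rows = length(r0), n_cols = length(c0),
                 n_windows = nrow(origins)),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("window_grid: %d windows (%d x %d) of %d px at stride %d over %d x %d\n",
              x$n_windows, x$n_rows, x$n_cols, x$side, x$stride,
              x$height, x$width))
  invisible(x)
}

#' Identity feature mode: normalize to the common grayscale range
#'
#' Affine rescale from the grayscale range common to all images of a study
#' to `[0, 1]`.
#'
#' @param img Numeric matrix.
#' @param global_range Length-2 numeric `(min, max)` with `max > min`.
#' @return Matrix of the same shape with values in `[0, 1]` for in-range
#'   input.
#' @export
identity_mode <- function(img, global_range = c(0, 65535)) {
  if (diff(global_range) <= 0) stop("degenerate global grayscale range")
  (img - global_range[1]) / diff(global_range)
}

# Otsu threshold by exhaustive between-class variance maximization over
# `levels` candidate cuts of [0, 1]; delegated to EBImage.
local_otsu_binarize <- function(identity, block = 32, levels = 256) {
  n <- nrow(identity); p <- ncol(identity)
  out <- matrix(FALSE, n, p)
  rb <- unique(c(seq(1L, n, by = block), n + 1L))
  cb <- unique(c(seq(1L, p, by = block), p + 1L))
  for (i in seq_len(length(rb) - 1L)) {
    for (j in seq_len(length(cb) - 1L)) {
      rows <- rb[i]:(rb[i + 1L] - 1L)
      cols <- cb[j]:(cb[j + 1L] - 1L)
      tile <- identity[rows, cols, drop = FALSE]
      if (diff(range(tile)) < 1e-12) next   # flat tile: no structure
      thr <- EBImage::otsu(tile, range = c(0, 1), levels = levels)
      out[rows, cols] <- tile > thr
    }
  }
  out
}

# Shift a logical matrix by (dr, dc), filling exposed borders with FALSE.
shift_logical <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  rs <- seq_len(n) - dr; cs <- seq_len(p) - dc
  rok <- rs >= 1 & rs <= n; cok <- cs >= 1 & cs <= p
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Zhang-Suen morphological thinning to single-pixel-wide structures.
thin_binary <- function(bw) {
  bw <- bw > 0
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours clockwise from north: p2..p9
      p2 <- shift_logical(bw, -1,  0); p3 <- shift_logical(bw, -1,  1)
      p4 <- shift_logical(bw,  0,  1); p5 <- shift_logical(bw,  1,  1)
      p6 <- shift_logical(bw,  1,  0); p7 <- shift_logical(bw,  1, -1)
      p8 <- shift_logical(bw,  0, -1); p9 <- shift_logical(bw, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (pass == 1L) {
        cond <- bw & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- bw & B >= 2 & B <= 6 & A == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        bw[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  bw
}

#' Skeleton feature mode: local Otsu binarization plus thinning
#'
#' Binarizes the identity-mode image with a locally adaptive Otsu threshold
#' (square tiles of `otsu_side` pixels) and thins the foreground to
#' single-pixel width.  The window mean of this mode measures the sparsity
#' of local structure.
#'
#' @param identity Identity-mode matrix with values in `[0, 1]`.
#' @param otsu_side Side of the square local-threshold tile (default 32).
#' @return Numeric 0/1 matrix; a constant input yields an empty skeleton.
#' @export
skeleton_mode <- function(identity, otsu_side = 32) {
  bw <- local_otsu_binarize(identity, block = otsu_side)
  thin_binary(bw) + 0
}

#' Gradient feature mode: magnitude of the spatial gradient
#'
#' Euclidean norm of the two first-order central differences of the
#' identity-mode image, with edge-replicated borders.  An extensive measure
#' of window heterogeneity.
#'
#' @param identity Identity-mode matrix.
#' @return Matrix of gradient magnitudes.
#' @export
gradient_mode <- function(identity) {
  pd <- pad_replicate(identity, 1L)
  n <- nrow(identity); p <- ncol(identity)
  gr <- (pd[3:(n + 2L), 2:(p + 1L)] - pd[seq_len(n), 2:(p + 1L)]) / 2
  gc <- (pd[2:(n + 1L), 3:(p + 2L)] - pd[2:(n + 1L), seq_len(p)]) / 2
  sqrt(gr^2 + gc^2)
}

#' Laplacian feature mode: Laplacian after Gaussian blurring
#'
#' 5-point discrete Laplacian of the identity-mode image after a Gaussian
#' blur of standard deviation `blur_sigma` (default 1 px).  Linear in the
#' input; highlights even relatively weak edges.
#'
#' @param identity Identity-mode matrix.
#' @param blur_sigma Gaussian blur standard deviation in pixels (> 0).
#' @return Matrix of Laplacian responses.
#' @export
laplacian_mode <- function(identity, blur_sigma = 1) {
  stopifnot(blur_sigma > 0)
  laplacian5(gaussian_blur(identity, blur_sigma))
}

#' Windowed location/dispersion statistics of a feature mode
#'
#' For every window of the grid computes either the median and the
#' interquartile range (linear-interpolation quantiles) or the mean and the
#' population standard deviation of the mode raster.
#'
#' @param mode_img Feature-mode matrix.
#' @param grid A [make_window_grid()] fitting `mode_img`.
#' @param stat_pair `"median_iqr"` or `"mean_sd"`.
#' @return Numeric matrix with one row per window and columns `loc`, `disp`.
#' @export
window_stats <- function(mode_img, grid, stat_pair = c("median_iqr", "mean_sd")) {
  stat_pair <- match.arg(stat_pair)
  side <- grid$side
  org <- grid$origins + 1L    # to 1-based
  if (stat_pair == "mean_sd") {
    npx <- side^2
    s1 <- window_sums(mode_img, org, side)
    s2 <- window_sums(mode_img^2, org, side)
    mu <- s1 / npx
    va <- pmax(0, s2 / npx - mu^2)
    out <- cbind(loc = mu, disp = sqrt(va))
  } else {
    qs <- vapply(seq_len(nrow(org)), function(i) {
      w <- mode_img[org[i, 1L]:(org[i, 1L] + side - 1L),
                    org[i, 2L]:(org[i, 2L] + side - 1L)]
      stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    }, numeric(3))
    out <- cbind(loc = qs[2L, ], disp = qs[3L, ] - qs[1L, ])
  }
  out
}

# Radial frequency (in DFT bin units) of every bin of an n x n spectrum,
# with the DC bin at [1, 1].
radial_frequency <- function(n) {
  k <- 0:(n - 1L)
  k <- pmin(k, n - k)
  kr <- matrix(k, n, n)
  sqrt(kr^2 + t(kr)^2)
}

# Gaussian bandpass weight in frequency space: difference of Gaussians,
# clamped at zero, with the DC bin forced to 0.
bandpass_weight <- function(n, sigma_low = 2, sigma_high = 8) {
  r <- radial_frequency(n)
  B <- exp(-r^2 / (2 * sigma_high^2)) - exp(-r^2 / (2 * sigma_low^2))
  B[B < 0] <- 0
  B[1L, 1L] <- 0
  B
}

#' Bandpass log-power sum of an identity-mode window
#'
#' Discrete Fourier power spectrum of a square window, weighted by a
#' Gaussian bandpass annulus that suppresses the constant and
#' high-frequency components, summarized as `sum(log(1 + weighted power))`.
#'
#' @param window Square numeric matrix (one grid window).
#' @param sigma_low,sigma_high Bandpass bounds in frequency-bin units
#'   (defaults 2 and 8).
#' @return Scalar spectral power summary; 0 for a constant window.
#' @export
power_sum <- function(window, sigma_low = 2, sigma_high = 8) {
  n <- nrow(window)
  stopifnot(n == ncol(window))
  P <- Mod(stats::fft(window))^2
  sum(log1p(bandpass_weight(n, sigma_low, sigma_high) * P))
}

# power_sum over every window of a grid.
power_sum_grid <- function(identity, grid, sigma_low = 2, sigma_high = 8) {
  side <- grid$side
  B <- bandpass_weight(side, sigma_low, sigma_high)
  org <- grid$origins + 1L
  vapply(seq_len(nrow(org)), function(i) {
    w <- identity[org[i, 1L]:(org[i, 1L] + side - 1L),
                  org[i, 2L]:(org[i, 2L] + side - 1L)]
    sum(log1p(B * Mod(stats::fft(w))^2))
  }, numeric(1))
}

# Oriented line-detection kernel: 1-D Gaussian profile across the line
# (sd sigma_across), constant along it over length kernel_len, zero-mean.
# angle_deg is the direction of the line structure, 0 = horizontal.
orientation_kernel <- function(angle_deg, kernel_len = 9, sigma_across = 1.5) {
  r <- (kernel_len - 1) / 2
  dr <- matrix(seq(-r, r), kernel_len, kernel_len)  # row offset (down)
  dc <- t(dr)                                       # col offset (right)
  th <- angle_deg * pi / 180
  u <- dc * cos(th) + dr * sin(th)   # along-line coordinate
  v <- -dc * sin(th) + dr * cos(th)  # across-line coordinate
  k <- exp(-v^2 / (2 * sigma_across^2)) * (abs(u) <= r + 0.5)
  sup <- k > 1e-8
  k[sup] <- k[sup] - mean(k[sup])
  k[!sup] <- 0
  k
}

# Bin centers in degrees for n uniform angle bins over (-90, 90].
orientation_bin_centers <- function(n_angles) {
  a <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  ifelse(a > 90, a - 180, a)
}

#' Texture orientation PDF of a Laplacian-mode window
#'
#' Directional-filter orientation estimation: the window is convolved with a
#' bank of oriented zero-mean line-detection kernels (Gaussian profile
#' across the line, `kernel_len` pixels along it) at `n_angles` uniform
#' angles over 180 degrees; the energy (sum of squared response) per angle,
#' normalized to unit total, is the orientation probability distribution.
#' Angles are taken mod 180 degrees and reported as bin centers in
#' `(-90, 90]`, 0 = horizontal.  A constant window has zero energy at every
#' angle and returns the uniform PDF.
#'
#' @param laplacian_window Square numeric matrix (Laplacian-mode window).
#' @param n_angles Number of angle bins (>= 4; default 12).
#' @param kernel_len Kernel length along the line in pixels (default 9).
#' @return A list of class `orientation_pdf` with `angles` (bin centers,
#'   degrees) and `p` (probabilities summing to 1).
#' @export
orientation_pdf <- function(laplacian_window, n_angles = 12, kernel_len = 9) {
  stopifnot(n_angles >= 4)
  centers <- orientation_bin_centers(n_angles)
  raw <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  e <- vapply(raw, function(a) {
    resp <- conv2_replicate(laplacian_window, orientation_kernel(a, kernel_len))
    sum(resp^2)
  }, numeric(1))
  floor_e <- 1e-20 * max(1, sum(laplacian_window^2))
  tot <- sum(e)
  p <- if (tot <= floor_e) rep(1 / n_angles, n_angles) else e / tot
  structure(list(angles = centers, p = p), class = "orientation_pdf")
}

# Orientation energies for every grid window at once: the Laplacian mode is
# filtered globally by each oriented kernel and squared responses are summed
# per window via integral images.  Returns an n_windows x n_angles matrix.
orientation_energy_grid <- function(laplacian_img, grid, n_angles = 12,
                                    kernel_len = 9) {
  raw <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  org <- grid$origins + 1L
  E <- matrix(0, nrow(org), n_angles)
  for (j in seq_len(n_angles)) {
    resp <- conv2_replicate(laplacian_img, orientation_kernel(raw[j], kernel_len))
    E[, j] <- window_sums(resp^2, org, grid$side)
  }
  E
}

orientation_pdf_from_energy <- function(e, n_angles) {
  tot <- sum(e)
  if (tot <= 0) rep(1 / n_angles, n_angles) else e / tot
}

#' Horizontality of a texture orientation PDF
#'
#' `2 * P(-45 < angle <= 45) - 1`: values near +1 indicate strongly
#' horizontal texture, near -1 strongly vertical, near 0 no strong
#' orientation.  A bin straddling +-45 degrees contributes the fraction of
#' its width inside the interval.
#'
#' @param pdf An [orientation_pdf()], or a bare probability vector with an
#'   `angles` attribute layout matching [orientation_pdf()].
#' @return Scalar in `[-1, 1]`.
#' @export
horizontality <- function(pdf) {
  2 * horizontal_mass(pdf$p, pdf$angles) - 1
}

# Probability mass within (-45, 45], straddling bins taken fractionally.
# Bins may wrap around +-90 (mod 180); wrapping pieces lie outside the
# target interval so only the principal piece matters.
horizontal_mass <- function(p, centers) {
  w <- 180 / length(p)
  frac <- vapply(centers, function(cn) {
    lo <- cn - w / 2; hi <- cn + w / 2
    seg <- function(a, b) max(0, min(b, 45) - max(a, -45))
    inside <- 0
    if (hi > 90) {                    # wraps past +90
      inside <- seg(lo, 90) + seg(-90, hi - 180)
    } else if (lo <= -90) {           # wraps past -90
      inside <- seg(-90, hi) + seg(lo + 180, 90)
    } else {
      inside <- seg(lo, hi)
    }
    inside / w
  }, numeric(1))
  sum(p * frac)
}

#' Modal texture orientation
#'
#' The bin center (degrees, in `(-90, 90]`) of the maximal bin of the
#' orientation PDF; ties are broken by the smallest angle.
#'
#' @param pdf An [orientation_pdf()].
#' @return Scalar angle in degrees.
#' @export
orientation <- function(pdf) {
  mode_angle(pdf$p, pdf$angles)
}

mode_angle <- function(p, centers) {
  mx <- max(p)
  min(centers[p >= mx - 1e-12])
}

#' Predictor column names of the feature table, in canonical order
#' @return Character vector of the 11 predictor column names.
#' @export
feature_columns <- function() {
  c("identity_loc", "identity_disp", "skeleton_loc", "skeleton_disp",
    "gradient_loc", "gradient_disp", "laplacian_loc", "laplacian_disp",
    "power_sum", "orientation", "horizontality")
}

#' Build the per-window feature table of an image
#'
#' Computes the four feature modes globally (identity, skeleton, gradient,
#' Laplacian), summarizes each over the window grid with its statistic pair
#' (identity and Laplacian: median/IQR, robust against rib outliers;
#' skeleton and gradient: mean/sd), and adds the bandpass log-power sum and
#' the orientation and horizontality of the Laplacian mode — 11 predictors
#' per window.
#'
#' @param img Intensity-standardized image matrix.
#' @param grid A [make_window_grid()]; defaults to the canonical 32/16
#'   lattice over `img`.
#' @param global_range Grayscale range common to all images of the study.
#' @param stat_pairs Named character vector assigning `"median_iqr"` or
#'   `"mean_sd"` to each mode.
#' @param n_angles,kernel_len Orientation-bank parameters.
#' @param sigma_low,sigma_high Bandpass bounds in frequency-bin units.
#' @return A `data.frame` of class `feature_table`: one row per window with
#'   the 11 predictors plus window origin (`win_row`, `win_col`, 0-based)
#'   and center coordinates.
#' @export
build_feature_table <- function(img,
                                grid = make_window_grid(nrow(img), ncol(img)),
                                global_range = c(0, 65535),
                                stat_pairs = c(identity = "median_iqr",
                                               skeleton = "mean_sd",
                                               gradient = "mean_sd",
                                               laplacian = "median_iqr"),
                                n_angles = 12, kernel_len = 9,
                                sigma_low = 2, sigma_high = 8) {
  idn <- identity_mode(img, global_range)
  ske <- skeleton_mode(idn, otsu_side = grid$side)
  grd <- gradient_mode(idn)
  lap <- laplacian_mode(idn)

  s_id <- window_stats(idn, grid, stat_pairs[["identity"]])
  s_sk <- window_stats(ske, grid, stat_pairs[["skeleton"]])
  s_gr <- window_stats(grd, grid, stat_pairs[["gradient"]])
  s_la <- window_stats(lap, grid, stat_pairs[["laplacian"]])
  pw <- power_sum_grid(idn, grid, sigma_low, sigma_high)

  E <- orientation_energy_grid(lap, grid, n_angles, kernel_len)
  centers <- orientation_bin_centers(n_angles)
  ori <- numeric(nrow(E)); hor <- numeric(nrow(E))
  for (i in seq_len(nrow(E))) {
    p <- orientation_pdf_from_energy(E[i, ], n_angles)
    ori[i] <- mode_angle(p, centers)
    hor[i] <- 2 * horizontal_mass(p, centers) - 1
  }

  out <- data.frame(
    identity_loc = s_id[, 1L], identity_disp = s_id[, 2L],
    skeleton_loc = s_sk[, 1L], skeleton_disp = s_sk[, 2L],
    gradient_loc = s_gr[, 1L], gradient_disp = s_gr[, 2L],
    laplacian_loc = s_la[, 1L], laplacian_disp = s_la[, 2L],
    power_sum = pw, orientation = ori, horizontality = hor,
    win_row = grid$origins[, 1L], win_col = grid$origins[, 2L],
    center_row = grid$centers[, 1L], center_col = grid$centers[, 2L])
  class(out) <- c("feature_table", "data.frame")
  out
}
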