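#' Default pressure-to-gain map for phantom speckle amplitude
#'
#' Dimensionless speckle edge-amplitude gain at each ventilation pressure
#' (cmH2O).  Strictly increasing, with a threefold change between the 6 and
#' 12 cmH2O extremes so the texture statistic separates pressures much more
#' strongly than the mean grayscale level does.
#'
#' @return Named numeric vector over pressures 6, 8, 10, 12.
#' @export
default_texture_gain <- function() {
  c(`6` = 1.0, `8` = 1.5, `10` = 2.1, `12` = 3.0)
}

#' Phantom specification for one synthetic mouse image
#'
#' Collects every parameter of the synthetic textured phantom: a lung region
#' of band-limited speckle whose edge amplitude increases with ventilation
#' pressure, dark multiplicative rib bands that cross the lung without
#' interrupting its texture, a dark blurred heart disc overlapping the medial
#' left lung, a smooth exterior, and a cranial-caudal orientation gradient
#' (isotropic texture at the apex, vertically oriented texture at the base)
#' within the lungs.  Geometry defaults are expressed as fractions of
#' `image_side` so phantoms scale from desk-size (512 px) to full detector
#' size (1984 px).
#'
#' @param mouse_id Character identifier.
#' @param pressure Ventilation pressure in cmH2O; one of 6, 8, 10, 12.
#' @param image_side Side of the square image in pixels (default 512).
#' @param texture_gain Named numeric vector mapping each pressure to a
#'   dimensionless speckle gain; must be strictly increasing in pressure.
#' @param texture_amp Base speckle amplitude in intensity units at gain 1.
#' @param anisotropy_profile Function of normalized cranial-caudal position
#'   `t` in `[0, 1]` (0 = apex) returning the weight in `[0, 1]` of the
#'   vertically oriented texture component; the default `function(t) t`
#'   yields isotropic texture apically and vertical texture basally.
#' @param rib_count Number of rib bands crossing the rib cage.
#' @param rib_width_px Full width of a rib band in pixels.
#' @param heart_center Heart disc center `(row, col)` in pixels.
#' @param heart_radius Heart disc radius in pixels.
#' @param diaphragm_height Height of the diaphragm band in pixels.
#' @param noise_sd Standard deviation of the additive detector noise.
#' @param brightness_offset Additive global intensity offset (per-mouse
#'   nuisance used by [generate_cohort()]).
#' @param lung_scale Multiplicative jitter on lung semi-axes (per-mouse
#'   nuisance).
#' @param seed Integer seed; identical specs generate bit-identical output.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_mouse()], [generate_cohort()]
#' @export
phantom_spec <- function(mouse_id = "m1",
                         pressure = 10,
                         image_side = 512,
                         texture_gain = default_texture_gain(),
                         texture_amp = 1500,
                         anisotropy_profile = function(t) t,
                         rib_count = 7,
                         rib_width_px = round(0.045 * image_side),
                         heart_center = round(c(0.60, 0.52) * image_side),
                         heart_radius = round(0.13 * image_side),
                         diaphragm_height = round(0.12 * image_side),
                         noise_sd = 150,
                         brightness_offset = 0,
                         lung_scale = 1,
                         seed = 1L) {
  spec <- structure(list(
    mouse_id = as.character(mouse_id), pressure = as.integer(pressure),
    image_side = as.integer(image_side), texture_gain = texture_gain,
    texture_amp = texture_amp, anisotropy_profile = anisotropy_profile,
    rib_count = as.integer(rib_count), rib_width_px = as.integer(rib_width_px),
    heart_center = as.numeric(heart_center), heart_radius = as.numeric(heart_radius),
    diaphragm_height = as.numeric(diaphragm_height), noise_sd = noise_sd,
    brightness_offset = brightness_offset, lung_scale = lung_scale,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (!pressure %in% c(6L, 8L, 10L, 12L))
      stop("pressure must be one of 6, 8, 10, 12 cmH2O")
    if (image_side < 64) stop("image_side too small for the window lattice")
    g <- texture_gain[as.character(c(6, 8, 10, 12))]
    if (anyNA(g) || any(diff(g) <= 0))
      stop("texture_gain must be strictly increasing over pressures 6,8,10,12")
    if (!is.function(anisotropy_profile))
      stop("anisotropy_profile must be a function")
    if (heart_center[1] - heart_radius < 1 || heart_center[1] + heart_radius > image_side ||
        heart_center[2] - heart_radius < 1 || heart_center[2] + heart_radius > image_side)
      stop("heart geometry lies outside the image bounds")
    if (diaphragm_height <= 0 || diaphragm_height >= image_side)
      stop("diaphragm geometry lies outside the image bounds")
    if (rib_width_px <= 0 || rib_count < 1)
      stop("invalid rib geometry")
    if (lung_scale <= 0 || lung_scale > 1.1)
      stop("lung_scale out of bounds (lungs must stay inside the rib cage)")
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: mouse %s, %d cmH2O, %dx%d px, seed %d\n",
              x$mouse_id, x$pressure, x$image_side, x$image_side, x$seed))
  invisible(x)
}

# Elliptical indicator mask on an image_side x image_side grid.
ellipse_mask <- function(side, center_frac, semi_frac) {
  rr <- matrix(seq_len(side), side, side)
  cc <- t(rr)
  ((rr - center_frac[1] * side) / (semi_frac[1] * side))^2 +
    ((cc - center_frac[2] * side) / (semi_frac[2] * side))^2 <= 1
}

disc_mask <- function(side, center, radius) {
  rr <- matrix(seq_len(side), side, side)
  cc <- t(rr)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Band-limited Gaussian noise field, unit variance.  `f0` is the radial band
# center in cycles/pixel and `bw` the radial bandwidth.  `conc > 0`
# concentrates spectral energy at angle `axis_angle` (radians, in frequency
# space), producing spatially oriented texture.
bandpass_field <- function(n, f0, bw, conc = 0, axis_angle = 0) {
  w <- matrix(stats::rnorm(n * n), n)
  W <- stats::fft(w)
  half <- floor(n / 2)
  fx <- c(0:half, if (n > 2 * half + 1) integer(0), -(n - half - 1):-1) / n
  fx <- fx[seq_len(n)]
  FR <- matrix(fx, n, n)      # frequency along rows (vertical spatial freq.)
  FC <- t(FR)                 # frequency along columns (horizontal)
  r <- sqrt(FR^2 + FC^2)
  B <- exp(-(r - f0)^2 / (2 * bw^2))
  if (conc > 0) {
    th <- atan2(FR, FC)
    B <- B * exp(conc * (cos(2 * (th - axis_angle)) - 1))
  }
  B[1, 1] <- 0
  x <- Re(stats::fft(W * B, inverse = TRUE)) / (n * n)
  x / stats::sd(x)
}

# Radial band center (cycles/pixel) encoding pressure in the speckle scale,
# secondary to the amplitude encoding.
pressure_band_center <- function(pressure) 0.10 + 0.0075 * (pressure - 6)

#' Generate one synthetic phantom mouse image with ground-truth masks
#'
#' Renders the phantom described by a [phantom_spec()]: smooth background,
#' speckled lung fields with pressure-dependent amplitude and band center,
#' a cranial-caudal blend from isotropic to vertically oriented speckle,
#' multiplicative rib bands, a dark Gaussian-blurred heart disc, and
#' additive detector noise, quantized to 16-bit.  The speckle is rectified
#' band-limited Gaussian noise: its edges give the Laplacian feature mode a
#' positively skewed response whose window median grows linearly with the
#' speckle gain, while mean-centering keeps the mean lung intensity nearly
#' constant across pressures.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_mouse` with elements `image` (integer
#'   matrix, 16-bit range), `rois` (a [roi_set()] including derived masks),
#'   and `spec`.
#' @export
generate_mouse <- function(spec) {
  validate_phantom_spec(spec)
  side <- spec$image_side
  set.seed(spec$seed)

  rib_cage   <- ellipse_mask(side, c(0.55, 0.50), c(0.38, 0.34))
  right_lung <- ellipse_mask(side, c(0.52, 0.33),
                             c(0.29, 0.145) * spec$lung_scale)
  left_lung  <- ellipse_mask(side, c(0.54, 0.66),
                             c(0.27, 0.135) * spec$lung_scale)
  heart      <- disc_mask(side, spec$heart_center, spec$heart_radius)
  rr <- matrix(seq_len(side), side, side)
  dia_top <- round(0.82 * side)
  diaphragm <- rib_cage & rr >= dia_top & rr < dia_top + spec$diaphragm_height
  # ground truth respects the nesting the analysis assumes
  right_lung <- right_lung & rib_cage
  left_lung  <- left_lung & rib_cage

  lung <- right_lung | left_lung

  gain <- spec$texture_gain[[as.character(spec$pressure)]]
  f0 <- pressure_band_center(spec$pressure)
  iso  <- bandpass_field(side, f0, 0.035)
  vert <- bandpass_field(side, f0, 0.035, conc = 6, axis_angle = 0)

  lung_rows <- range(which(rowSums(lung) > 0))
  t_cc <- (rr - lung_rows[1]) / max(1, diff(lung_rows))
  t_cc <- pmin(1, pmax(0, t_cc))
  w <- matrix(vapply(as.vector(t_cc), spec$anisotropy_profile, numeric(1)),
              side, side)
  w[w < 0] <- 0
  w[w > 1] <- 1
  # rectified (edge-like, positively skewed) speckle, mean-centred; the
  # isotropic and vertical components are blended after rectification so
  # their orientation energies mix linearly along the cranial-caudal axis
  r_iso <- abs(iso) - sqrt(2 / pi)
  r_vert <- abs(vert) - sqrt(2 / pi)
  tex <- ((1 - w) * r_iso + w * r_vert) / sqrt((1 - w)^2 + w^2)

  # the lung carries only a weak brightness step: the separating signal is
  # the texture, which passes through ribs, not the mean intensity
  img <- 24000 + 3000 * (rr / side) + spec$brightness_offset
  img <- img + lung * (500 + spec$texture_amp * gain * tex)

  # multiplicative rib bands across the rib cage (texture passes through)
  rib_rows <- range(which(rowSums(rib_cage) > 0))
  centers <- seq(rib_rows[1] + 0.08 * diff(rib_rows),
                 rib_rows[2] - 0.15 * diff(rib_rows),
                 length.out = spec$rib_count)
  rib_depth <- matrix(0, side, side)
  sig <- spec$rib_width_px / 2
  for (ctr in centers)
    rib_depth <- rib_depth + exp(-(rr - ctr)^2 / (2 * sig^2))
  img <- img * (1 - 0.12 * rib_depth * rib_cage)

  # dark blurred heart (multiplicative, like an attenuating organ)
  hsoft <- gaussian_blur(heart + 0, 0.02 * side)
  img <- img * (1 - 0.22 * hsoft)

  img <- img + matrix(stats::rnorm(side * side, 0, spec$noise_sd), side)
  img <- round(pmin(pmax(img, 0), 65535))
  dim(img) <- c(side, side)
  storage.mode(img) <- "integer"

  rois <- derive_rois(roi_set(rib_cage = rib_cage, right_lung = right_lung,
                              left_lung = left_lung, heart = heart,
                              diaphragm = diaphragm))
  structure(list(image = img, rois = rois, spec = spec),
            class = "phantom_mouse")
}

#' @export
print.phantom_mouse <- function(x, ...) {
  cat(sprintf("phantom_mouse: %s at %d cmH2O, %dx%d px\n", x$spec$mouse_id,
              x$spec$pressure, nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Generate a seeded cohort of phantom mice
#'
#' Emulates the study design of several mice each imaged at several
#' ventilation pressures.  Per-mouse sub-seeds, brightness offsets, lung-size
#' jitter and texture-amplitude jitter are derived deterministically from
#' `master_seed`, so per-mouse z-scoring of predictors is a non-trivial
#' operation on the resulting cohort.
#'
#' @param n_mice Number of mice (>= 2; leave-one-mouse-out is otherwise
#'   undefined).
#' @param pressures Non-empty subset of `c(6, 8, 10, 12)`; one image is
#'   generated per (mouse, pressure) cell.
#' @param master_seed Integer master seed.
#' @param image_side Image side in pixels.
#' @param texture_gain Pressure-to-gain map passed to every spec.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A list of class `phantom_cohort` of `phantom_mouse` objects.
#' @export
generate_cohort <- function(n_mice = 8, pressures = c(6, 8, 10, 12),
                            master_seed = 1L, image_side = 512,
                            texture_gain = default_texture_gain(), ...) {
  if (n_mice < 2) stop("n_mice must be >= 2 (leave-one-mouse-out undefined)")
  pressures <- as.integer(pressures)
  if (length(pressures) == 0 || !all(pressures %in% c(6L, 8L, 10L, 12L)))
    stop("pressures must be a non-empty subset of {6, 8, 10, 12}")
  set.seed(as.integer(master_seed))
  offs  <- stats::rnorm(n_mice, 0, 1200)
  lsc   <- stats::runif(n_mice, 0.96, 1.04)
  ampj  <- stats::runif(n_mice, 0.90, 1.10)
  out <- vector("list", n_mice * length(pressures))
  k <- 0L
  for (i in seq_len(n_mice)) {
    for (p in pressures) {
      k <- k + 1L
      sp <- phantom_spec(mouse_id = sprintf("m%02d", i), pressure = p,
                         image_side = image_side, texture_gain = texture_gain,
                         brightness_offset = offs[i], lung_scale = lsc[i],
                         seed = derive_seed(master_seed, i * 1000L + p), ...)
      sp$texture_amp <- sp$texture_amp * ampj[i]
      out[[k]] <- generate_mouse(sp)
    }
  }
  structure(out, class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  ids <- unique(vapply(x, function(m) m$spec$mouse_id, ""))
  prs <- sort(unique(vapply(x, function(m) m$spec$pressure, 0L)))
  cat(sprintf("phantom_cohort: %d images, %d mice, pressures {%s} cmH2O\n",
              length(x), length(ids), paste(prs, collapse = ", ")))
  invisible(x)
}
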