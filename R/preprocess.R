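#' Named set of region-of-interest masks over one image grid
#'
#' The five base anatomical masks are outer envelopes: the rib cage contains
#' the lungs, and the lungs may contain projected ribs.  Derived masks are
#' added by [derive_rois()].
#'
#' @param rib_cage,right_lung,left_lung,heart,diaphragm Logical matrices of
#'   identical dimensions.
#' @param ... Additional named logical masks of the same dimensions.
#' @return A list of class `roi_set`.
#' @export
roi_set <- function(rib_cage, right_lung, left_lung, heart, diaphragm, ...) {
  masks <- list(rib_cage = rib_cage, right_lung = right_lung,
                left_lung = left_lung, heart = heart, diaphragm = diaphragm, ...)
  dims <- lapply(masks, dim)
  if (length(unique(dims)) != 1L)
    stop("all ROI masks must share the image dimensions")
  if (!all(vapply(masks, is.logical, TRUE)))
    masks <- lapply(masks, function(m) m > 0)
  if (any(masks$right_lung & !masks$rib_cage) ||
      any(masks$left_lung & !masks$rib_cage))
    stop("lung masks must lie inside the rib cage")
  structure(masks, class = "roi_set")
}

#' Derive the set-arithmetic ROI products used for labeling
#'
#' Adds `lung_heart_overlap` (pixels of either lung also covered by the
#' projected heart) and `outside_ribcage` (the complement of the rib cage).
#' The heart base mask itself is not used as a training region; it is kept
#' in the set only so the overlap can be recomputed.
#'
#' @param base A [roi_set()] with the five base masks.
#' @return The `roi_set` with the two derived masks added.
#' @export
derive_rois <- function(base) {
  stopifnot(inherits(base, "roi_set"))
  lung <- base$right_lung | base$left_lung
  base$lung_heart_overlap <- lung & base$heart
  base$outside_ribcage <- !base$rib_cage
  base
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set over a", paste(dim(x[[1]]), collapse = "x"), "grid:\n")
  for (nm in names(x))
    cat(sprintf("  %-18s %d px\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Intensity histogram over the full bit-depth range
#'
#' One bin per integer grayscale value by default, so that exact histogram
#' specification can reproduce a template distribution to quantization.
#'
#' @param img Integer-valued matrix.
#' @param bit_depth 8 or 16; bins cover `0:(2^bit_depth - 1)`.
#' @return A list of class `intensity_histogram` with `values` (bin lower
#'   edges, equal to the integer grayscale values), `counts`, and `total`.
#' @export
intensity_histogram <- function(img, bit_depth = 16) {
  stopifnot(bit_depth %in% c(8, 16))
  nlev <- 2L^bit_depth
  v <- as.integer(round(as.vector(img)))
  if (any(v < 0 | v >= nlev)) stop("intensities outside the bit-depth range")
  counts <- tabulate(v + 1L, nbins = nlev)
  structure(list(values = 0:(nlev - 1L), counts = counts, total = length(v)),
            class = "intensity_histogram")
}

#' Clip intensity outliers at fixed percentiles
#'
#' Pixels below the low-percentile rank value are raised to it and pixels
#' above the high-percentile rank value lowered to it; all interior pixels
#' are unchanged.  Rank-based quantiles: the low cut is the sorted value at
#' rank `ceiling(lo_pct * n)` (at least 1) and the high cut the value at
#' rank `floor(hi_pct * n)`.
#'
#' @param img Numeric matrix.
#' @param lo_pct,hi_pct Percentile fractions, `0 <= lo_pct < hi_pct <= 1`
#'   (defaults 0.0001 and 0.999, i.e. the 0.01th and 99.9th percentiles).
#' @return The clipped matrix.
#' @export
clip_percentiles <- function(img, lo_pct = 0.0001, hi_pct = 0.999) {
  stopifnot(lo_pct < hi_pct, lo_pct >= 0, hi_pct <= 1)
  v <- sort(as.vector(img))
  n <- length(v)
  lo <- v[max(1L, ceiling(lo_pct * n))]
  hi <- v[max(1L, floor(hi_pct * n))]
  out <- pmin(hi, pmax(lo, img))
  dim(out) <- dim(img)
  out
}

#' Exact rank-based histogram specification
#'
#' Remaps pixel intensities so the output's empirical distribution equals a
#' template distribution up to quantization, preserving pixel rank order.
#' Ties are broken by raster order (column-major, the native matrix order),
#' making the mapping exact and deterministic rather than approximate.
#' Matching an image to its own full-resolution histogram is the identity,
#' and matching twice to the same template equals matching once.
#'
#' @param img Integer-valued matrix.
#' @param template An [intensity_histogram()] with positive total count.
#' @return Matrix of the same shape whose sorted values follow the template.
#' @export
histogram_match <- function(img, template) {
  stopifnot(inherits(template, "intensity_histogram"), template$total > 0)
  n <- length(img)
  keep <- template$counts > 0
  tv <- template$values[keep]
  tc <- template$counts[keep]
  if (length(tv) == 1L) {         # degenerate single-level template
    out <- matrix(tv, nrow(img), ncol(img))
    storage.mode(out) <- "integer"
    return(out)
  }
  cum <- cumsum(as.numeric(tc))
  total <- cum[length(cum)]
  r <- rank(as.vector(img), ties.method = "first")
  target <- ceiling(r * total / n)            # rank in the expanded template
  idx <- findInterval(target - 0.5, c(0, cum)) # smallest bin with cdf >= target
  out <- matrix(tv[idx], nrow(img), ncol(img))
  storage.mode(out) <- "integer"
  out
}
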