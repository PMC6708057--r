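#' Geometric magnification of a projection imaging system
#'
#' For a point source, the magnification of a propagation-based system is
#' `(SOD + ODD) / SOD`, where SOD is the source-to-object distance and ODD
#' the object-to-detector distance.  Units cancel; both distances must be
#' given in the same unit.
#'
#' @param sod Source-to-object distance (> 0).
#' @param odd Object-to-detector distance (>= 0).
#' @return The dimensionless magnification factor.
#' @examples
#' magnification(59, 177)  # 4x bench-top geometry
#' @export
magnification <- function(sod, odd) {
  stopifnot(is.numeric(sod), is.numeric(odd), sod > 0, odd >= 0)
  (sod + odd) / sod
}

## --- low-level raster helpers (matrices indexed [row, col], row 1 = top) ---

# Pad a matrix by edge replication with margin r on every side.
pad_replicate <- function(m, r) {
  n <- nrow(m); p <- ncol(m)
  m[c(rep(1L, r), seq_len(n), rep(n, r)), c(rep(1L, r), seq_len(p), rep(p, r)),
    drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel k (odd length),
# edge-replicated borders.  Used for Gaussian blurs.
sep_conv <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m); p <- ncol(m)
  pad <- pad_replicate(m, r)
  v <- matrix(0, n, p + 2L * r)
  for (i in seq_along(k)) v <- v + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
  h <- matrix(0, n, p)
  for (j in seq_along(k)) h <- h + k[j] * v[, j:(j + p - 1L), drop = FALSE]
  h
}

# Discrete Gaussian kernel, radius ceiling(4*sigma), normalized to sum 1.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Gaussian blur with edge replication.
gaussian_blur <- function(m, sigma) sep_conv(m, gaussian_kernel(sigma))

# 5-point discrete Laplacian with edge replication.
laplacian5 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  pd <- pad_replicate(m, 1L)
  pd[seq_len(n), 2:(p + 1L)] + pd[3:(n + 2L), 2:(p + 1L)] +
    pd[2:(n + 1L), seq_len(p)] + pd[2:(n + 1L), 3:(p + 2L)] - 4 * m
}

# 2-D convolution of a raster with an arbitrary small kernel,
# edge-replicated borders, output the same size as the input.
conv2_replicate <- function(m, kern) {
  kr <- (nrow(kern) - 1L) / 2L
  kc <- (ncol(kern) - 1L) / 2L
  n <- nrow(m); p <- ncol(m)
  pad <- m[c(rep(1L, kr), seq_len(n), rep(n, kr)),
           c(rep(1L, kc), seq_len(p), rep(p, kc)), drop = FALSE]
  out <- matrix(0, n, p)
  for (i in seq_len(nrow(kern))) {
    for (j in seq_len(ncol(kern))) {
      w <- kern[i, j]
      if (w != 0)
        out <- out + w * pad[i:(i + n - 1L), j:(j + p - 1L), drop = FALSE]
    }
  }
  out
}

# Summed-area table with a zero top/left guard row/column, so that the sum
# over rows a..b, cols c..d is S[b+1,d+1] - S[a,d+1] - S[b+1,c] + S[a,c].
integral_image <- function(m) {
  cs <- apply(m, 2L, cumsum)            # cumulative down rows
  cs <- t(apply(cs, 1L, cumsum))        # then across columns
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- cs
  S
}

# Window sums over a grid (1-based origins) using an integral image.
window_sums <- function(m, origins, side) {
  S <- integral_image(m)
  a <- origins[, 1L]; cc <- origins[, 2L]
  b <- a + side - 1L; d <- cc + side - 1L
  S[cbind(b + 1L, d + 1L)] - S[cbind(a, d + 1L)] -
    S[cbind(b + 1L, cc)] + S[cbind(a, cc)]
}

#' Derive a reproducible sub-seed from a base seed and an index
#'
#' Deterministic mixing of a base seed with a stage index, kept within the
#' positive signed 32-bit integer range, so that every random stage of a
#' run can draw an independent stream from one master seed.
#'
#' @param seed Integer base seed.
#' @param index Integer stage index.
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}
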