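# enumeration oracle for window origins
enumerate_origins <- function(H, W, side, stride) {
  out <- list()
  for (r in seq(0, H, by = stride)) {
    if (r + side > H) break
    for (cc in seq(0, W, by = stride)) {
      if (cc + side > W) break
      out[[length(out) + 1]] <- c(r, cc)
    }
  }
  do.call(rbind, out)
}

test_that("window grid counts and origins match exhaustive enumeration", {
  g <- make_window_grid(1984, 1984)
  expect_equal(g$n_windows, 15129)
  expect_equal(make_window_grid(32, 32)$n_windows, 1)
  g64 <- make_window_grid(64, 48)
  expect_equal(g64$n_windows, 6)
  expect_equal(unname(g64$origins), unname(enumerate_origins(64, 48, 32, 16)))
  expect_error(make_window_grid(20, 100), "side exceeds")
  set.seed(5)
  for (i in 1:10) {
    H <- sample(40:300, 1); W <- sample(40:300, 1)
    side <- sample(8:32, 1); stride <- sample(1:16, 1)
    if (side > min(H, W)) next
    g <- make_window_grid(H, W, side, stride)
    oracle <- enumerate_origins(H, W, side, stride)
    expect_equal(g$n_windows, nrow(oracle))
    expect_equal(unname(g$origins), unname(oracle))
    expect_true(all(g$origins %% stride == 0))
    expect_equal(g$n_windows,
                 (floor((H - side) / stride) + 1) * (floor((W - side) / stride) + 1))
  }
})

test_that("identity mode maps the global range onto [0, 1]", {
  img <- matrix(c(0, 32767.5, 65535), 1, 3)
  out <- identity_mode(img, c(0, 65535))
  expect_equal(as.vector(out), c(0, 0.5, 1))
  expect_error(identity_mode(img, c(5, 5)), "degenerate")
})

test_that("skeleton mode thins a bright bar to its one-pixel midline", {
  img <- matrix(0.1, 32, 32)
  img[15:17, 5:28] <- 0.9
  sk <- skeleton_mode(img)
  expect_true(all(sk %in% c(0, 1)))
  # single-pixel width: no skeleton pixel has a full 3x3 foreground block
  fg <- which(sk == 1, arr.ind = TRUE)
  interior <- fg[fg[, 1] > 1 & fg[, 1] < 32 & fg[, 2] > 1 & fg[, 2] < 32, ,
                 drop = FALSE]
  for (i in seq_len(nrow(interior))) {
    r <- interior[i, 1]; cc <- interior[i, 2]
    expect_lt(sum(sk[(r - 1):(r + 1), (cc - 1):(cc + 1)]), 9)
  }
  # midline position; thinning may erode a few pixels from the bar ends
  expect_true(all(fg[, 1] == 16))
  expect_gte(nrow(fg), 18)
  expect_lte(nrow(fg), 24)
  # oracle: exhaustive Otsu threshold search reproduces the binarization
  otsu_oracle <- function(x, levels = 256) {
    edges <- seq(0, 1, length.out = levels + 1)
    h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                  nbins = levels)
    best <- -Inf; thr <- 0
    for (k in 1:(levels - 1)) {
      w0 <- sum(h[1:k]); w1 <- sum(h) - w0
      if (w0 == 0 || w1 == 0) next
      mids <- (edges[-1] + edges[-(levels + 1)]) / 2
      m0 <- sum(h[1:k] * mids[1:k]) / w0
      m1 <- sum(h[(k + 1):levels] * mids[(k + 1):levels]) / w1
      v <- w0 * w1 * (m0 - m1)^2
      if (v > best) { best <- v; thr <- edges[k + 1] }
    }
    thr
  }
  thr <- otsu_oracle(as.vector(img))
  expect_true(all((img > thr) == (img > 0.5)))  # bar/background split
})

test_that("constant images yield an empty skeleton and denser texture a denser one", {
  expect_equal(sum(skeleton_mode(matrix(0.5, 32, 32))), 0)
  img_bar <- matrix(0.1, 32, 32); img_bar[15:17, 5:28] <- 0.9
  checker <- matrix(0.1, 32, 32)
  blk <- rep(rep(c(TRUE, FALSE), each = 8), times = 2)
  checker[outer(blk, blk, `==`)] <- 0.9
  expect_gt(mean(skeleton_mode(checker)), mean(skeleton_mode(img_bar)))
})

test_that("gradient mode matches central-difference hand computations", {
  expect_true(all(gradient_mode(matrix(3, 8, 8)) == 0))
  ramp <- matrix(rep(1:10, times = 10), 10, 10)  # slope 1 per pixel down rows
  g <- gradient_mode(ramp)
  expect_true(all(g[2:9, ] == 1))
  step <- matrix(rep(c(0, 0, 0, 4, 4, 4), each = 6), 6, 6)
  gs <- gradient_mode(step)
  expect_equal(max(gs), 4 / 2)  # central difference across a height-4 step
})

test_that("Laplacian mode annihilates affine images and integrates to zero", {
  expect_true(all(abs(laplacian_mode(matrix(7, 16, 16))) < 1e-12))
  # interior margin clears the blur radius (4 sigma) plus the stencil
  ramp <- matrix(rep(1:32, each = 32), 32, 32)
  L <- laplacian_mode(ramp)
  expect_true(all(abs(L[7:26, 7:26]) < 1e-9))
  spot <- matrix(0, 33, 33); spot[17, 17] <- 1
  Ls <- laplacian_mode(spot)
  expect_lt(abs(sum(Ls)), 1e-9)
  expect_lt(Ls[17, 17], 0)  # negative curvature at the peak
})

test_that("window statistics agree with closed forms and a sort oracle", {
  g1 <- make_window_grid(32, 32)
  const <- matrix(3.5, 32, 32)
  expect_equal(unname(window_stats(const, g1, "median_iqr")[1, ]), c(3.5, 0))
  tiled <- matrix(rep(c(1, 2, 3, 4), 256), 32, 32)
  ms <- window_stats(tiled, g1, "mean_sd")
  expect_equal(unname(ms[1, ]), c(2.5, sqrt(1.25)))
  set.seed(6)
  img <- matrix(runif(64 * 64), 64, 64)
  g <- make_window_grid(64, 64)
  mi <- window_stats(img, g, "median_iqr")
  for (i in seq_len(g$n_windows)) {
    w <- sort(img[(g$origins[i, 1] + 1):(g$origins[i, 1] + 32),
                  (g$origins[i, 2] + 1):(g$origins[i, 2] + 32)])
    # linear-interpolation quantile oracle on the sorted values
    qq <- function(p) {
      h <- (length(w) - 1) * p
      lo <- floor(h)
      w[lo + 1] * (1 - (h - lo)) + w[lo + 2 - (h == lo)] * (h - lo)
    }
    expect_equal(unname(mi[i, 1]), qq(0.5))
    expect_equal(unname(mi[i, 2]), qq(0.75) - qq(0.25))
  }
})

test_that("bandpass power sum passes band frequencies and matches a naive DFT", {
  expect_equal(power_sum(matrix(2, 32, 32)), 0)
  xs <- matrix(seq_len(32) - 1, 32, 32)
  sin4 <- sin(2 * pi * 4 * xs / 32)
  sin15 <- sin(2 * pi * 15 * xs / 32)
  expect_gt(power_sum(sin4), power_sum(sin15))
  # naive double-loop DFT oracle on an 8x8 window
  set.seed(7)
  w8 <- matrix(rnorm(64), 8, 8)
  naive <- 0
  for (u in 0:7) for (v in 0:7) {
    re <- 0; im <- 0
    for (r in 0:7) for (cc in 0:7) {
      ph <- -2 * pi * (u * r + v * cc) / 8
      re <- re + w8[r + 1, cc + 1] * cos(ph)
      im <- im + w8[r + 1, cc + 1] * sin(ph)
    }
    fu <- min(u, 8 - u); fv <- min(v, 8 - v)
    rad <- sqrt(fu^2 + fv^2)
    B <- max(0, exp(-rad^2 / (2 * 64)) - exp(-rad^2 / 8))
    if (u == 0 && v == 0) B <- 0
    naive <- naive + log1p(B * (re^2 + im^2))
  }
  expect_equal(power_sum(w8), naive, tolerance = 1e-8)
})

test_that("orientation PDF locates stripe direction and degenerates to uniform", {
  xs <- matrix(seq_len(32), 32, 32)        # varies down rows
  stripes_h <- sin(2 * pi * xs / 6)        # horizontal stripes
  pdf_h <- orientation_pdf(stripes_h)
  expect_equal(orientation(pdf_h), 0)
  pdf_v <- orientation_pdf(t(stripes_h))   # rotated 90 degrees
  expect_equal(orientation(pdf_v), 90)
  pdf_c <- orientation_pdf(matrix(5, 32, 32))
  expect_equal(pdf_c$p, rep(1 / 12, 12))
  expect_equal(sum(pdf_h$p), 1)
  expect_true(all(pdf_h$p >= 0))
})

test_that("horizontality endpoints, tie rules and bounds hold", {
  delta <- function(angle) {
    p <- numeric(12)
    cen <- lungtexture:::orientation_bin_centers(12)
    p[cen == angle] <- 1
    make_pdf(p)
  }
  expect_equal(horizontality(delta(0)), 1)
  expect_equal(horizontality(delta(90)), -1)
  expect_equal(horizontality(make_pdf(rep(1, 12))), 0)
  expect_equal(orientation(delta(30)), 30)
  expect_equal(orientation(make_pdf(rep(1, 12))), -75)  # smallest bin center
  bimodal <- numeric(12)
  cen <- lungtexture:::orientation_bin_centers(12)
  bimodal[cen == 60] <- 0.55
  bimodal[cen == -60] <- 0.45   # 120 degrees mod 180
  expect_equal(orientation(make_pdf(bimodal)), 60)
  set.seed(8)
  for (i in 1:25) {
    p <- runif(12)
    h <- horizontality(make_pdf(p))
    expect_gte(h, -1)
    expect_lte(h, 1)
  }
})

test_that("feature table has 11 predictors and offset-invariant derivative modes", {
  set.seed(9)
  img <- matrix(sample(2000:3000, 128 * 96, TRUE), 128, 96)
  grid <- make_window_grid(128, 96)
  ft <- build_feature_table(img, grid)
  expect_equal(nrow(ft), grid$n_windows)
  expect_true(all(feature_columns() %in% names(ft)))
  expect_length(feature_columns(), 11)
  ft2 <- build_feature_table(img + 1000L, grid)
  deriv <- c("gradient_loc", "gradient_disp", "laplacian_loc",
             "laplacian_disp", "power_sum", "orientation", "horizontality")
  for (cl in deriv) expect_equal(ft2[[cl]], ft[[cl]], tolerance = 1e-9)
  expect_equal(ft2$identity_loc - ft$identity_loc,
               rep(1000 / 65535, nrow(ft)), tolerance = 1e-9)
})

test_that("a constant image produces all-zero dispersion and texture predictors", {
  img <- matrix(12000L, 64, 64)
  ft <- build_feature_table(img)
  expect_true(all(ft$identity_disp == 0))
  expect_true(all(ft$gradient_loc == 0 & ft$gradient_disp == 0))
  expect_true(all(abs(ft$laplacian_loc) < 1e-12 & ft$laplacian_disp < 1e-12))
  expect_true(all(ft$power_sum == 0))
  expect_true(all(ft$horizontality == 0))
  expect_true(all(ft$skeleton_loc == 0))
})
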