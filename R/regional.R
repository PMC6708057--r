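# 4-connected component labeling on a logical window-lattice matrix.
# Strided windows overlap, so 8-connectivity would over-merge; the lattice
# is treated with 4-connectivity throughout.
label_components4 <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% n + 1L
      cc <- (q - 1L) %/% n + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1L]; c2 <- cc + d[2L]
        if (rr >= 1L && rr <= n && c2 >= 1L && c2 <= p) {
          q2 <- (c2 - 1L) * n + rr
          if (mask[q2] && lab[q2] == 0L) {
            lab[q2] <- cur
            queue <- c(queue, q2)
          }
        }
      }
    }
  }
  lab
}

#' Post-process a window-level lung mask
#'
#' Fill-holes followed by a region-size exclusion filter, both with
#' 4-connectivity on the window lattice: holes (background components not
#' touching the lattice border) inside positive regions are filled, then
#' positive connected regions smaller than `min_region` windows are
#' removed.  Applied to classifier output, this removes small isolated
#' misclassifications and typically raises segmentation accuracy.
#'
#' @param window_mask Logical (or 0/1) matrix on the window lattice
#'   (`n_rows x n_cols` of the grid).
#' @param min_region Minimum surviving region size in windows.
#' @return Logical matrix of the same shape.
#' @export
postprocess_lung_mask <- function(window_mask, min_region = 5) {
  m <- window_mask > 0
  # fill holes: background components not connected to the border
  bg <- label_components4(!m)
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_ids <- border_ids[border_ids != 0L]
  filled <- m | (bg != 0L & !(bg %in% border_ids))
  dim(filled) <- dim(m)
  # size filter on positive components
  fg <- label_components4(filled)
  sizes <- tabulate(fg[fg > 0L])
  keep <- which(sizes >= min_region)
  out <- fg %in% keep
  dim(out) <- dim(m)
  out
}

#' Cranial-caudal k-means regionalization of lung windows
#'
#' Standard k-means on the spatial window-center coordinates (multiple
#' random restarts, seeded), with clusters relabeled 1..k by increasing
#' mean row — region 1 is the most cranial (upper), region k the most
#' caudal (lower).  With the default k = 3 the regions are the upper,
#' middle and lower lung.
#'
#' @param centers Numeric matrix of window centers `(row, col)` within a
#'   lung mask.
#' @param k Number of regions (default 3).
#' @param seed Integer seed.
#' @param nstart Number of k-means restarts (best objective kept).
#' @return A list of class `region_partition` with `region` (integer in
#'   1..k per center, 1 = upper), `centers`, `k`, and the within-cluster
#'   sum of squares of the selected solution.
#' @export
kmeans_regions <- function(centers, k = 3, seed = 1L, nstart = 10) {
  centers <- as.matrix(centers)
  if (nrow(centers) < k) stop("fewer centers than regions requested")
  if (k == 1) {
    return(structure(list(region = rep(1L, nrow(centers)), centers = centers,
                          k = 1L, tot_withinss = sum(scale(centers, scale = FALSE)^2)),
                     class = "region_partition"))
  }
  set.seed(as.integer(seed))
  km <- stats::kmeans(centers, centers = k, nstart = nstart, iter.max = 100)
  ord <- order(tapply(centers[, 1L], km$cluster, mean))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  structure(list(region = relab[km$cluster], centers = centers, k = as.integer(k),
                 tot_withinss = km$tot.withinss),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("region_partition: %d windows in %d regions (1 = upper)\n",
              length(x$region), x$k))
  print(table(region = x$region))
  invisible(x)
}

#' Per-region summaries of (standardized) horizontality
#'
#' Five-number summaries of the horizontality column per spatial region,
#' plus the standardized position of the vertical-horizontal threshold
#' (raw h = 0): if the column was standardized as `(h - mean) / sd`, the
#' threshold line sits at `-mean/sd`.
#'
#' @param h Horizontality values, one per partitioned window (raw or
#'   standardized).
#' @param partition A [kmeans_regions()] partition of the same windows.
#' @param h_mean,h_sd Mean and sd used for standardization (defaults 0 and
#'   1, i.e. `h` unstandardized and threshold at 0).
#' @return A list of class `regional_horizontality` with `summary` (matrix
#'   of five-number summaries per region), `threshold`, and `empty`
#'   (regions with no windows, flagged).
#' @export
regional_horizontality <- function(h, partition, h_mean = 0, h_sd = 1) {
  stopifnot(inherits(partition, "region_partition"),
            length(h) == length(partition$region))
  regions <- seq_len(partition$k)
  smry <- t(vapply(regions, function(r) {
    x <- h[partition$region == r]
    if (length(x) == 0) rep(NA_real_, 5) else stats::fivenum(x)
  }, numeric(5)))
  dimnames(smry) <- list(region = paste0("R", regions),
                         c("min", "q1", "median", "q3", "max"))
  empty <- regions[tabulate(partition$region, partition$k) == 0]
  structure(list(summary = smry, threshold = (0 - h_mean) / h_sd,
                 empty = empty),
            class = "regional_horizontality")
}

#' @export
print.regional_horizontality <- function(x, ...) {
  cat("Per-region horizontality (region 1 = upper):\n")
  print(round(x$summary, 4))
  cat(sprintf("vertical-horizontal threshold (standardized h = 0): %.4f\n",
              x$threshold))
  if (length(x$empty)) cat("empty regions:", x$empty, "\n")
  invisible(x)
}

#' Rank correlation of texture orientation with window intensity
#'
#' Kendall's tau-b (tie-adjusted; windowed medians tie frequently at 16-bit
#' quantization) between the horizontality and the median window intensity,
#' quantifying how far the orientation texture signal is decorrelated from
#' plain attenuation.
#'
#' @param h Horizontality column.
#' @param m Identity-mode median column of the same windows.
#' @return Kendall's tau-b.
#' @export
texture_intensity_decorrelation <- function(h, m) {
  stopifnot(length(h) == length(m), length(h) >= 2)
  if (stats::sd(h) == 0 || stats::sd(m) == 0)
    stop("tau undefined for a constant column")
  stats::cor(h, m, method = "kendall")
}
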