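#' Write a 16-bit grayscale TIFF
#'
#' @param img Integer matrix in `[0, 65535]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(img, path) {
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF
#'
#' @param path Input path.
#' @return Integer matrix in `[0, 65535]`.
#' @export
read_gray_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  out <- round(m * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Write an ROI mask as an 8-bit PNG (0/255)
#' @param mask Logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) + 0, path)
  invisible(path)
}

#' Read an ROI mask from an 8-bit PNG
#' @param path Input path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' Write a phantom mouse to disk
#'
#' One 16-bit TIFF image, one 8-bit PNG per ROI mask, and a JSON sidecar
#' with the spec fields and pressure.
#'
#' @param mouse A `phantom_mouse`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_phantom <- function(mouse, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_p%02d", mouse$spec$mouse_id, mouse$spec$pressure)
  files <- file.path(dir, paste0(stem, ".tif"))
  write_gray_tiff(mouse$image, files)
  for (nm in names(mouse$rois)) {
    f <- file.path(dir, sprintf("%s_roi_%s.png", stem, nm))
    write_mask_png(mouse$rois[[nm]], f)
    files <- c(files, f)
  }
  side <- file.path(dir, paste0(stem, ".json"))
  sp <- mouse$spec
  sp$anisotropy_profile <- deparse(sp$anisotropy_profile)
  jsonlite::write_json(unclass(sp), side, auto_unbox = TRUE, digits = NA)
  invisible(c(files, side))
}
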