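#' Read an RGB image
#'
#' Reads PNG or JPEG rasters into an `H x W x 3` array of intensities in
#' `[0, 1]`, row 1 at the top of the image. Gray images are replicated to
#' three channels; alpha channels are dropped.
#'
#' @param path Path to a `.png`, `.jpg`/`.jpeg` file.
#' @return An `H x W x 3` numeric array (class `dgf_image`).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(switch(ext,
                        png = png::readPNG(path),
                        jpg = ,
                        jpeg = jpeg::readJPEG(path),
                        stop("unsupported image format: .", ext, call. = FALSE)),
                 error = function(e) stop("failed to decode ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  as_rgb_image(px)
}

as_rgb_image <- function(px) {
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3L] != 3L) stop("expected 1, 3 or 4 channels", call. = FALSE)
  px[px < 0] <- 0; px[px > 1] <- 1
  structure(px, class = c("dgf_image", "array"))
}

#' @export
print.dgf_image <- function(x, ...) {
  cat(sprintf("<dgf_image %d x %d>\n", dim(x)[1L], dim(x)[2L]))
  invisible(x)
}

#' Write an RGB image to PNG
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  png::writePNG(unclass(image), path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Standard luminance weighting `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image `H x W x 3` array (or an `H x W` matrix, returned unchanged).
#' @return `H x W` matrix in `[0, 1]`.
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Write a binary mask as a single-channel PNG with values {0, 255}
#' @param mask 0/1 matrix.
#' @param path Output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  ok <- tryCatch({ png::writePNG(matrix(as.numeric(mask), nrow(mask)), path); TRUE },
                 error = function(e) stop("cannot write mask to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a binary mask PNG written by [write_mask()]
#'
#' Any strictly positive pixel maps to 1.
#'
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  m <- matrix(0L, nrow(px), ncol(px))
  m[px > 0.5] <- 1L
  m
}

#' Rectangular window
#'
#' Closed pixel-index window `[row0, row1] x [col0, col1]`, 1-based inclusive
#' bounds.
#'
#' @param row0,col0 Top-left pixel indices.
#' @param row1,col1 Bottom-right pixel indices (inclusive).
#' @return A `dgf_window` object.
#' @export
dgf_window <- function(row0, col0, row1, col1) {
  if (row1 < row0 || col1 < col0) stop("degenerate window", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 row1 = as.integer(row1), col1 = as.integer(col1)),
            class = "dgf_window")
}

#' @export
print.dgf_window <- function(x, ...) {
  cat(sprintf("<dgf_window rows %d..%d, cols %d..%d>\n",
              x$row0, x$row1, x$col0, x$col1))
  invisible(x)
}

window_area <- function(w) (w$row1 - w$row0 + 1L) * (w$col1 - w$col0 + 1L)

#' Crop an image (or matrix) to a window
#' @param image `H x W(x 3)` array or matrix.
#' @param window A [dgf_window()] within bounds.
#' @return The cropped array of the same kind.
#' @export
crop <- function(image, window) {
  d <- dim(image)
  if (window$row0 < 1L || window$col0 < 1L || window$row1 > d[1L] || window$col1 > d[2L])
    stop("window out of image bounds", call. = FALSE)
  if (length(d) == 3L)
    as_rgb_image(image[window$row0:window$row1, window$col0:window$col1, , drop = FALSE])
  else image[window$row0:window$row1, window$col0:window$col1, drop = FALSE]
}
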