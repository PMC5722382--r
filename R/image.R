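# Grayscale image and binary mask containers.

#' Construct an 8-bit grayscale image
#'
#' Wraps a numeric matrix as an 8-bit intensity raster. Values in [0, 1]
#' are rescaled to [0, 255]; values already in [0, 255] are rounded and
#' clamped. Multi-channel arrays are converted to grayscale by the Rec. 709
#' luminance weights.
#'
#' @param pixels Numeric matrix (rows = image rows) or h x w x 3 array.
#' @return A \code{gray_image}: integer matrix with intensities in [0, 255].
#' @export
as_gray_image <- function(pixels) {
  if (inherits(pixels, "gray_image")) return(pixels)
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    d3 <- dim(pixels)[3L]
    w <- if (d3 >= 3L) c(0.2126, 0.7152, 0.0722) else rep(1 / d3, d3)
    pixels <- Reduce(`+`, lapply(seq_len(min(d3, 3L)),
                                 function(k) w[k] * pixels[, , k]))
  }
  if (!is.matrix(pixels)) stopf("pixels must be a matrix or 3-d array")
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stopf("image must be at least 8 x 8 pixels (got %d x %d)",
          nrow(pixels), ncol(pixels))
  mx <- max(pixels)
  if (mx <= 1 + 1e-9) pixels <- pixels * 255
  px <- round(pixels)
  px[px < 0] <- 0; px[px > 255] <- 255
  storage.mode(px) <- "integer"
  structure(px, class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d, intensity range [%d, %d]>\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read a grayscale raster image
#'
#' Reads a PNG or TIFF (lossless) raster and converts it to an 8-bit
#' grayscale image. JPEG input is rejected with an informative error:
#' lossy compression corrupts the narrow intensity classes the two-level
#' segmentation relies on.
#'
#' @param path File path.
#' @return A \code{gray_image}.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) stopf("cannot read image: no such file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = stopf("JPEG input is not supported: lossy compression blurs the intensity classes; use PNG or TIFF"),
    stopf("unsupported image format '.%s' (use PNG or TIFF)", ext)
  )
  as_gray_image(px)
}

#' Write a grayscale image or binary mask to PNG
#'
#' @param x A \code{gray_image} or \code{binary_mask}.
#' @param path Output PNG path.
#' @return Invisibly, \code{path}.
#' @export
write_gray <- function(x, path) {
  m <- if (inherits(x, "binary_mask")) {
    v <- matrix(0, nrow(x), ncol(x)); v[x] <- 1; v
  } else {
    unclass(x) / 255
  }
  png::writePNG(m, path)
  invisible(path)
}

new_binary_mask <- function(pixels, role = c("T1_INVERTED", "T2", "COMPOSITE")) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.logical(pixels))
    stopf("binary mask pixels must be a logical matrix")
  structure(pixels, class = "binary_mask", role = role)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d, role %s, %d foreground px>\n",
              nrow(x), ncol(x), attr(x, "role"), sum(x)))
  invisible(x)
}

#' Role of a binary mask
#' @param mask A \code{binary_mask}.
#' @return One of "T1_INVERTED", "T2", "COMPOSITE".
#' @export
mask_role <- function(mask) attr(mask, "role")
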