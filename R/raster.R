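# Raster image helpers.  Images are numeric matrices (grayscale) or
# h x w x c arrays with values in [0, 1]; row = v + 1, column = u + 1 under
# the package's 0-based pixel convention.

image_dims <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L)
    stopf("'image' must be a matrix or a h x w x c array")
  c(height = d[1L], width = d[2L],
    channels = if (length(d) >= 3L) d[3L] else 1L)
}

#' Read an image file
#'
#' Reads PNG or TIFF rasters as numeric arrays in \code{[0, 1]}.  A trailing
#' alpha channel is dropped; a single-channel result is returned as a matrix.
#'
#' @param path Image file (.png, .tif/.tiff).
#' @return Numeric matrix (grayscale) or h x w x 3 array.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    pv_error("missing_input", "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    pv_error("bad_format", "unsupported image format '.%s' (PNG/TIFF only)", ext)
  )
  d <- dim(img)
  if (length(d) == 3L) {
    if (d[3L] == 2L) img <- img[, , 1L]          # gray + alpha
    else if (d[3L] == 4L) img <- img[, , 1:3]    # rgb + alpha
    else if (d[3L] == 1L) img <- img[, , 1L]
  }
  img
}

#' Write an image file
#'
#' Writes a matrix/array image (values clamped to \code{[0, 1]}) as PNG.
#'
#' @param image Numeric matrix or h x w x c array.
#' @param path Output path (.png).
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Sample an image at continuous pixel positions
#'
#' Bilinear interpolation at 0-based continuous positions \code{(u, v)};
#' positions outside the image are clamped to the border.
#'
#' @param image Numeric matrix or h x w x c array.
#' @param u,v Numeric vectors of equal length, 0-based pixel coordinates.
#' @param method \code{"bilinear"} (default) or \code{"nearest"}.
#' @return For a grayscale image a numeric vector; otherwise an n x c matrix.
#' @export
sample_bilinear <- function(image, u, v, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  dm <- image_dims(image)
  h <- dm[1L]; w <- dm[2L]; nc <- dm[3L]
  u <- pmin(pmax(as.numeric(u), 0), w - 1)
  v <- pmin(pmax(as.numeric(v), 0), h - 1)
  grab <- function(ri, ci) {
    # ri, ci: 1-based row/col integer vectors
    if (nc == 1L && is.matrix(image)) return(image[cbind(ri, ci)])
    sapply(seq_len(nc), function(k) image[cbind(ri, ci, k)])
  }
  if (method == "nearest") {
    vals <- grab(round(v) + 1, round(u) + 1)
  } else {
    u0 <- floor(u); v0 <- floor(v)
    u1 <- pmin(u0 + 1, w - 1); v1 <- pmin(v0 + 1, h - 1)
    fu <- u - u0; fv <- v - v0
    g00 <- grab(v0 + 1, u0 + 1); g01 <- grab(v0 + 1, u1 + 1)
    g10 <- grab(v1 + 1, u0 + 1); g11 <- grab(v1 + 1, u1 + 1)
    vals <- g00 * (1 - fu) * (1 - fv) + g01 * fu * (1 - fv) +
            g10 * (1 - fu) * fv + g11 * fu * fv
  }
  if (nc > 1L && !is.matrix(vals)) vals <- matrix(vals, ncol = nc)
  vals
}

# Mean over channels; identity for grayscale matrices.
as_gray <- function(image) {
  d <- dim(image)
  if (length(d) == 3L) {
    g <- image[, , 1L]
    if (d[3L] > 1L) {
      for (k in 2:d[3L]) g <- g + image[, , k]
      g <- g / d[3L]
    }
    g
  } else image
}
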