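# Pinhole camera with Brown-Conrady lens distortion.
#
# Pixel convention used throughout the package: 0-based, origin at the
# top-left corner of the image, u = column index (rightward), v = row index
# (downward), with pixel centers at integer coordinates.  The camera frame is
# right-handed with +z along the optical axis into the scene; 3D units are mm.

#' Camera intrinsics
#'
#' Container for the intrinsic parameters of a calibrated pinhole camera:
#' focal lengths, principal point, Brown-Conrady distortion coefficients and
#' image size.  Projection follows \code{u = fx*x/z + u0},
#' \code{v = fy*y/z + v0} once distortion has been removed
#' (see \code{\link{undistort_image}}).
#'
#' @param fx,fy Focal lengths, pixels. Must be positive.
#' @param u0,v0 Principal point (column, row), pixels; must lie inside the
#'   image.
#' @param dist Distortion coefficients \code{c(k1, k2, p1, p2, k3)}
#'   (radial k1, k2, k3; tangential p1, p2), dimensionless. Defaults to zero
#'   (an ideal pinhole).
#' @param width,height Image size in pixels.
#' @return An object of class \code{"camera_intrinsics"}.
#' @examples
#' cam <- camera_intrinsics(800, 800, 320, 240, width = 640, height = 480)
#' project_points(c(0, 0, 100), cam)  # optical axis -> principal point
#' @export
camera_intrinsics <- function(fx, fy, u0, v0, dist = numeric(5),
                              width, height) {
  check_scalar(fx, "fx", positive = TRUE)
  check_scalar(fy, "fy", positive = TRUE)
  check_scalar(u0, "u0")
  check_scalar(v0, "v0")
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  if (!is.numeric(dist) || length(dist) != 5L || any(!is.finite(dist)))
    stopf("'dist' must be 5 finite coefficients (k1, k2, p1, p2, k3)")
  if (u0 < 0 || u0 >= width || v0 < 0 || v0 >= height)
    stopf("principal point (%g, %g) must lie inside the %g x %g image",
          u0, v0, width, height)
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         u0 = as.numeric(u0), v0 = as.numeric(v0),
         dist = as.numeric(dist),
         width = as.integer(width), height = as.integer(height)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("camera_intrinsics: %d x %d px, fx=%g fy=%g, pp=(%g, %g)\n",
              x$width, x$height, x$fx, x$fy, x$u0, x$v0))
  if (any(x$dist != 0))
    cat("  dist (k1,k2,p1,p2,k3):", format(x$dist), "\n")
  else cat("  no distortion\n")
  invisible(x)
}

#' Read / write a calibration file
#'
#' Calibration files are JSON with keys \code{fx}, \code{fy}, \code{u0},
#' \code{v0}, \code{dist} (array of 5) and \code{width}, \code{height}.
#'
#' @param path File path.
#' @return \code{read_calibration} returns a
#'   \code{\link{camera_intrinsics}} object.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    pv_error("missing_input", "calibration file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fx", "fy", "u0", "v0", "width", "height")
  miss <- setdiff(need, names(j))
  if (length(miss))
    pv_error("bad_format", "calibration file %s lacks keys: %s",
             path, paste(miss, collapse = ", "))
  dist <- if (is.null(j$dist)) numeric(5) else as.numeric(j$dist)
  camera_intrinsics(j$fx, j$fy, j$u0, j$v0, dist, j$width, j$height)
}

#' @param cam A \code{\link{camera_intrinsics}} object.
#' @rdname read_calibration
#' @export
write_calibration <- function(cam, path) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  jsonlite::write_json(unclass(cam), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Project 3D camera-frame points to pixel coordinates
#'
#' Ideal pinhole projection \code{u = fx*x/z + u0}, \code{v = fy*y/z + v0}.
#' Distortion is not applied: the model describes images that have been
#' undistorted (\code{\link{undistort_image}}).
#'
#' @param points Length-3 vector or n x 3 matrix of \code{(x, y, z)} in mm.
#'   All \code{z} must be strictly positive.
#' @param cam A \code{\link{camera_intrinsics}} object.
#' @return n x 2 matrix with columns \code{u}, \code{v} (continuous pixels).
#' @export
project_points <- function(points, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  p <- as_point_matrix(points, 3L)
  if (any(!is.finite(p)))
    stopf("points must be finite")
  z <- p[, 3L]
  if (any(z <= 0))
    pv_error("behind_camera",
             "cannot project: %d point(s) at or behind the camera (z <= 0)",
             sum(z <= 0))
  cbind(u = cam$fx * p[, 1L] / z + cam$u0,
        v = cam$fy * p[, 2L] / z + cam$v0)
}

#' Back-project pixels to 3D points at a given depth
#'
#' Inverse of \code{\link{project_points}} at the stated depth along the
#' optical axis: \code{x = (u - u0)/fx * z}, \code{y = (v - v0)/fy * z}.
#'
#' @param pixels Length-2 vector or n x 2 matrix of \code{(u, v)}.
#' @param depth_z Depth(s) in mm, strictly positive (scalar or length n).
#' @param cam A \code{\link{camera_intrinsics}} object.
#' @return n x 3 matrix of camera-frame points, mm.
#' @export
backproject_pixels <- function(pixels, depth_z, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  px <- as_pixel_matrix(pixels)
  if (any(!is.finite(depth_z)) || any(depth_z <= 0))
    stopf("'depth_z' must be finite and > 0")
  z <- rep_len(as.numeric(depth_z), nrow(px))
  cbind(x = (px[, 1L] - cam$u0) / cam$fx * z,
        y = (px[, 2L] - cam$v0) / cam$fy * z,
        z = z)
}

#' Apply the forward Brown-Conrady distortion model to ideal pixels
#'
#' Maps ideal (pinhole) pixel positions to the positions at which the lens
#' actually images them.  With normalized coordinates
#' \code{x = (u - u0)/fx}, \code{y = (v - v0)/fy} and \code{r2 = x^2 + y^2}:
#' \deqn{x_d = x (1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2 p_1 x y + p_2 (r^2 + 2 x^2)}
#' and symmetrically for \code{y_d}.
#'
#' @inheritParams backproject_pixels
#' @return n x 2 matrix of distorted pixel positions.
#' @export
distort_points <- function(pixels, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  px <- as_pixel_matrix(pixels)
  d <- cam$dist
  x <- (px[, 1L] - cam$u0) / cam$fx
  y <- (px[, 2L] - cam$v0) / cam$fy
  r2 <- x * x + y * y
  radial <- 1 + d[1L] * r2 + d[2L] * r2^2 + d[5L] * r2^3
  xd <- x * radial + 2 * d[3L] * x * y + d[4L] * (r2 + 2 * x * x)
  yd <- y * radial + d[3L] * (r2 + 2 * y * y) + 2 * d[4L] * x * y
  cbind(u = xd * cam$fx + cam$u0, v = yd * cam$fy + cam$v0)
}

#' Invert the distortion model (distorted -> ideal pixels)
#'
#' Fixed-point iteration on the normalized coordinates, the standard
#' inversion of the Brown-Conrady forward model. Converges in a few
#' iterations for the moderate distortion of endoscopic optics.
#'
#' @inheritParams backproject_pixels
#' @param tol Convergence tolerance on normalized coordinates.
#' @param max_iter Iteration cap.
#' @return n x 2 matrix of ideal pixel positions.
#' @export
undistort_points <- function(pixels, cam, tol = 1e-12, max_iter = 50L) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  px <- as_pixel_matrix(pixels)
  d <- cam$dist
  xd <- (px[, 1L] - cam$u0) / cam$fx
  yd <- (px[, 2L] - cam$v0) / cam$fy
  x <- xd
  y <- yd
  for (i in seq_len(max_iter)) {
    r2 <- x * x + y * y
    radial <- 1 + d[1L] * r2 + d[2L] * r2^2 + d[5L] * r2^3
    dx <- 2 * d[3L] * x * y + d[4L] * (r2 + 2 * x * x)
    dy <- d[3L] * (r2 + 2 * y * y) + 2 * d[4L] * x * y
    xn <- (xd - dx) / radial
    yn <- (yd - dy) / radial
    if (max(abs(xn - x), abs(yn - y)) < tol) {
      x <- xn; y <- yn
      break
    }
    x <- xn; y <- yn
  }
  cbind(u = x * cam$fx + cam$u0, v = y * cam$fy + cam$v0)
}

#' Undistort an image
#'
#' Resamples the image so that the ideal pinhole model holds: each output
#' pixel takes its value from the input image at the position the forward
#' distortion model maps it to (inverse mapping with bilinear sampling).
#' With all-zero coefficients the input is returned unchanged, bit for bit.
#'
#' @param image Numeric matrix (grayscale) or h x w x c array, values in
#'   \code{[0, 1]}, with dimensions matching \code{cam}.
#' @param cam A \code{\link{camera_intrinsics}} object.
#' @return Undistorted image, same dimensions as the input.
#' @export
undistort_image <- function(image, cam) {
  stopifnot(inherits(cam, "camera_intrinsics"))
  dm <- image_dims(image)
  if (dm[1L] != cam$height || dm[2L] != cam$width)
    pv_error("bad_input",
             "image is %d x %d but the camera expects %d x %d",
             dm[1L], dm[2L], cam$height, cam$width)
  if (all(cam$dist == 0)) return(image)
  u <- rep(seq_len(cam$width) - 1, each = cam$height)
  v <- rep(seq_len(cam$height) - 1, times = cam$width)
  src <- distort_points(cbind(u, v), cam)
  vals <- sample_bilinear(image, src[, 1L], src[, 2L])
  if (is.matrix(vals)) {
    out <- array(0, dim = c(cam$height, cam$width, ncol(vals)))
    for (k in seq_len(ncol(vals)))
      out[, , k] <- matrix(vals[, k], cam$height, cam$width)
    out
  } else {
    matrix(vals, cam$height, cam$width)
  }
}
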