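# Rigid geometry: pivot-centered rotations and sparse depth-point sets.

#' Euler rotation matrix Rz * Ry * Rx
#'
#' Right-handed rotations about the camera axes, composed in the order
#' \code{Rz(theta_z) Ry(theta_y) Rx(theta_x)}.
#'
#' @param theta Length-3 vector \code{(theta_x, theta_y, theta_z)}, degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_xyz <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 3L || any(!is.finite(theta)))
    stopf("'theta' must be a finite 3-vector (degrees)")
  th <- deg2rad(theta)
  cx <- cos(th[1L]); sx <- sin(th[1L])
  cy <- cos(th[2L]); sy <- sin(th[2L])
  cz <- cos(th[3L]); sz <- sin(th[3L])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Pivot pose
#'
#' The rigid pose relating the camera frame to the rotation center about
#' which the virtual viewpoint turns.  Most users construct it from a pivot
#' point \code{center} in the camera frame (mm); a full 4 x 4 homogeneous
#' transform may be supplied instead.  Whatever the rotation block of the
#' transform, the fixed point of the induced viewpoint rotation is the
#' transform's translation column.
#'
#' @param center Pivot point \code{(cx, cy, cz)} in the camera frame, mm.
#'   Default \code{(0, 0, 120)}: the rotation center sits 120 mm down the
#'   optical axis, at the center of the scene of interest.
#' @param transform Optional 4 x 4 rigid homogeneous transform (rotation
#'   block orthonormal with determinant +1).
#' @return An object of class \code{"pivot_pose"}.
#' @export
pivot_pose <- function(center = c(0, 0, 120), transform = NULL) {
  if (is.null(transform)) {
    if (!is.numeric(center) || length(center) != 3L || any(!is.finite(center)))
      stopf("'center' must be a finite 3-vector (mm)")
    transform <- diag(4)
    transform[1:3, 4L] <- center
  } else {
    if (!is.matrix(transform) || any(dim(transform) != c(4L, 4L)) ||
        any(!is.finite(transform)))
      stopf("'transform' must be a finite 4 x 4 matrix")
    R <- transform[1:3, 1:3]
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
      stopf("rotation block must be orthonormal with determinant +1")
    if (max(abs(transform[4L, ] - c(0, 0, 0, 1))) > 1e-12)
      stopf("last row of 'transform' must be (0, 0, 0, 1)")
  }
  structure(list(transform = transform, center = transform[1:3, 4L]),
            class = "pivot_pose")
}

# 4x4 map rotating the scene by theta about the pivot:
#   X' = G %*% R %*% G^-1 %*% X,  fixed point at the pivot center.
pivot_transform <- function(theta, pivot, inverse = FALSE) {
  stopifnot(inherits(pivot, "pivot_pose"))
  R <- rotation_xyz(theta)
  Rh <- diag(4)
  Rh[1:3, 1:3] <- R
  G <- pivot$transform
  M <- G %*% Rh %*% solve(G)
  if (inverse) solve(M) else M
}

#' Sparse depth-point set
#'
#' Ordered correspondences between image pixels and 3D scene points in the
#' camera frame.  This is the sparse stand-in for full 3D shape acquisition:
#' only these pixels carry depth, and the warp engine meshes them to
#' interpolate everything in between.
#'
#' @param pixels n x 2 matrix of source pixels \code{(u, v)}, within the
#'   image bounds; no two rows may coincide.
#' @param points n x 3 matrix of camera-frame points \code{(x, y, z)}, mm,
#'   with all \code{z > 0}.
#' @param width,height Source image size, pixels.
#' @return An object of class \code{"depth_point_set"}.
#' @export
depth_point_set <- function(pixels, points, width, height) {
  px <- as_pixel_matrix(pixels)
  pt <- as_point_matrix(points, 3L)
  if (nrow(px) != nrow(pt))
    stopf("'pixels' and 'points' must have the same number of rows")
  if (nrow(px) < 1L) stopf("depth point set must be nonempty")
  if (any(!is.finite(px)) || any(!is.finite(pt)))
    stopf("depth points must be finite")
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  if (any(px[, 1L] < 0 | px[, 1L] > width - 1 |
          px[, 2L] < 0 | px[, 2L] > height - 1))
    stopf("all pixels must lie within the %g x %g image", width, height)
  if (any(pt[, 3L] <= 0))
    pv_error("behind_camera", "all depth points must have z > 0")
  if (anyDuplicated(paste(round(px[, 1L], 9), round(px[, 2L], 9))))
    stopf("no two correspondences may share the same pixel")
  colnames(px) <- c("u", "v")
  colnames(pt) <- c("x", "y", "z")
  structure(list(pixels = px, points = pt,
                 width = as.integer(width), height = as.integer(height)),
            class = "depth_point_set")
}

#' @export
print.depth_point_set <- function(x, ...) {
  cat(sprintf("depth_point_set: %d pixel<->3D correspondences (%d x %d image)\n",
              nrow(x$pixels), x$width, x$height))
  cat(sprintf("  z range: %.2f .. %.2f mm\n",
              min(x$points[, 3L]), max(x$points[, 3L])))
  invisible(x)
}

#' @export
length.depth_point_set <- function(x) nrow(x$pixels)

#' Read / write depth points
#'
#' CSV files must have a header with columns \code{u}, \code{v}, \code{x},
#' \code{y}, \code{z} (pixels and mm).  ASCII PLY files with per-vertex
#' \code{x y z u v} float properties are also accepted.
#'
#' @param path File path (.csv or ASCII .ply).
#' @param width,height Source image size the pixels refer to.
#' @return A \code{\link{depth_point_set}}.
#' @export
read_depth_points <- function(path, width, height) {
  if (!file.exists(path))
    pv_error("missing_input", "depth-point file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "ply") read_ply_points(path) else {
    d <- tryCatch(read.csv(path, check.names = FALSE),
                  error = function(e)
                    pv_error("bad_format", "cannot parse %s: %s",
                             path, conditionMessage(e)))
    need <- c("u", "v", "x", "y", "z")
    miss <- setdiff(need, names(d))
    if (length(miss))
      pv_error("bad_format", "%s lacks required columns: %s",
               path, paste(miss, collapse = ", "))
    m <- suppressWarnings(
      matrix(as.numeric(as.matrix(d[need])), nrow = nrow(d),
             dimnames = list(NULL, need)))
    bad <- which(apply(!is.finite(m), 1L, any))
    if (length(bad))
      pv_error("bad_format",
               "%s: non-numeric or missing value at data line %d",
               path, bad[1L] + 1L)  # +1 for the header line
    as.data.frame(m)
  }
  depth_point_set(as.matrix(df[c("u", "v")]), as.matrix(df[c("x", "y", "z")]),
                  width, height)
}

#' @param pts A \code{\link{depth_point_set}}.
#' @rdname read_depth_points
#' @export
write_depth_points <- function(pts, path) {
  stopifnot(inherits(pts, "depth_point_set"))
  df <- data.frame(u = pts$pixels[, 1L], v = pts$pixels[, 2L],
                   x = pts$points[, 1L], y = pts$points[, 2L],
                   z = pts$points[, 3L])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Minimal ASCII PLY reader for vertex elements carrying x y z u v.
read_ply_points <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || lines[1L] != "ply")
    pv_error("bad_format", "%s is not a PLY file", path)
  if (!grepl("^format ascii", lines[2L]))
    pv_error("bad_format",
             "%s: only ASCII PLY is supported (binary PLY is not)", path)
  endh <- match("end_header", lines)
  if (is.na(endh)) pv_error("bad_format", "%s: no end_header", path)
  header <- lines[seq_len(endh)]
  nv <- sub("^element vertex +", "", grep("^element vertex ", header, value = TRUE))
  if (!length(nv)) pv_error("bad_format", "%s: no vertex element", path)
  nv <- as.integer(nv[1L])
  props <- sub("^property +\\S+ +", "", grep("^property ", header, value = TRUE))
  need <- c("x", "y", "z", "u", "v")
  if (!all(need %in% props))
    pv_error("bad_format", "%s: vertex properties must include x y z u v", path)
  body <- lines[(endh + 1L):(endh + nv)]
  vals <- do.call(rbind, lapply(body, function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1L]])))
  colnames(vals) <- props[seq_len(ncol(vals))]
  as.data.frame(vals[, need, drop = FALSE])
}

#' Rigidly rotate depth points about the pivot
#'
#' Applies the pivot-centered rotation
#' \code{X' = G Rz(tz) Ry(ty) Rx(tx) G^-1 X} to every 3D point, keeping each
#' point's association with its source pixel.  Points whose transformed
#' depth drops to \code{z <= min_z} (behind or on the virtual camera) are
#' dropped; if none survive an error is raised.
#'
#' @param pts A \code{\link{depth_point_set}}.
#' @param theta Length-3 rotation \code{(theta_x, theta_y, theta_z)},
#'   degrees.
#' @param pivot A \code{\link{pivot_pose}}.
#' @param inverse If \code{TRUE}, apply the exact inverse of the map.
#' @param min_z Depth cutoff, mm (default 1e-6).
#' @return A \code{\link{depth_point_set}} of the surviving, transformed
#'   points.
#' @export
transform_points <- function(pts, theta, pivot, inverse = FALSE,
                             min_z = 1e-6) {
  stopifnot(inherits(pts, "depth_point_set"))
  M <- pivot_transform(theta, pivot, inverse = inverse)
  P <- t(M %*% rbind(t(pts$points), 1))[, 1:3, drop = FALSE]
  keep <- P[, 3L] > min_z
  if (!any(keep))
    pv_error("empty_geometry",
             "all %d points fell at or behind the virtual camera",
             nrow(P))
  depth_point_set(pts$pixels[keep, , drop = FALSE], P[keep, , drop = FALSE],
                  pts$width, pts$height)
}
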