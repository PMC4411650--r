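# The warp pipeline: rotate depth points about the pivot, reproject them,
# mesh the reprojected pixels by Delaunay triangulation, and synthesize the
# virtual view by barycentric interpolation of source positions.
#
# The renderer interpolates *positions* of the associated source pixels, not
# colors: for every output pixel inside a mesh triangle, the barycentric
# combination of the triangle's three source pixels gives a continuous
# source position, and the output color is sampled from the source image
# there (bilinearly by default).

#' Reproject transformed depth points onto the image plane
#'
#' Projects each 3D point through the pinhole model, keeping the association
#' with its source pixel.  Projected positions are continuous (not rounded).
#'
#' @param pts A \code{\link{depth_point_set}} (e.g. the output of
#'   \code{\link{transform_points}}); all \code{z > 0} by construction.
#' @param cam A \code{\link{camera_intrinsics}}.
#' @return Data frame with columns \code{u}, \code{v} (source pixel),
#'   \code{up}, \code{vp} (projected pixel) and \code{z} (depth after the
#'   transform, used for occlusion ordering).
#' @export
reproject <- function(pts, cam) {
  stopifnot(inherits(pts, "depth_point_set"))
  pr <- project_points(pts$points, cam)
  data.frame(u = pts$pixels[, 1L], v = pts$pixels[, 2L],
             up = pr[, 1L], vp = pr[, 2L], z = pts$points[, 3L])
}

#' Delaunay-triangulate projected pixel positions
#'
#' Builds the Delaunay triangulation of the reprojected points; its
#' near-equilateral triangles make it well suited to barycentric
#' interpolation, and it is defined for irregular point distributions.
#'
#' @param projected n x 2 matrix of projected pixel positions (n >= 3, not
#'   all collinear).
#' @return An object of class \code{"delaunay_mesh"}: a list with
#'   \code{triangles} (m x 3 matrix of indices into \code{projected}) and
#'   \code{points} (the input positions).
#' @export
build_mesh <- function(projected) {
  p <- as_pixel_matrix(projected, "projected")
  if (nrow(p) < 3L)
    pv_error("degenerate_geometry",
             "triangulation needs at least 3 points, got %d", nrow(p))
  ctr <- sweep(p, 2L, colMeans(p))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2L] <= 1e-9 * max(sv[1L], 1))
    pv_error("degenerate_geometry",
             "projected points are (nearly) collinear; cannot triangulate")
  tr <- tryCatch(
    interp::tri.mesh(p[, 1L], p[, 2L], duplicate = "error"),
    error = function(e)
      pv_error("degenerate_geometry", "triangulation failed: %s",
               conditionMessage(e)))
  tri <- interp::triangles(tr)[, c("node1", "node2", "node3"), drop = FALSE]
  structure(list(triangles = unname(tri), points = p),
            class = "delaunay_mesh")
}

#' Render the virtual view from a meshed reprojection
#'
#' Rasterizes each mesh triangle in the output image.  For every output
#' pixel inside a triangle, the source position is the barycentric
#' combination of the triangle's three vertices' source pixels and the color
#' is sampled from the source image at that position.  Pixels outside the
#' convex hull of the projected points are marked invalid and filled with
#' \code{fill}.  When two triangles cover the same output pixel the one with
#' the smaller mean vertex depth wins if \code{zbuffer} is on; otherwise the
#' triangle with the lowest index wins (pixels exactly on shared edges are
#' always assigned to the lowest-index triangle).
#'
#' @param source_image Source raster (matrix or h x w x c array, values in
#'   \code{[0, 1]}).
#' @param proj Data frame from \code{\link{reproject}} whose rows the mesh
#'   indexes.
#' @param mesh A \code{\link{build_mesh}} triangulation over
#'   \code{cbind(proj$up, proj$vp)}.
#' @param out_size Output size \code{c(height, width)}; defaults to the
#'   source size.
#' @param fill Fill value for invalid pixels (scalar, or one value per
#'   channel). Default black.
#' @param zbuffer Resolve overlapping triangles by mean vertex depth
#'   (default \code{TRUE}). Turn off for bit-reproducible planar scenes.
#' @param sampling \code{"bilinear"} (default) or \code{"nearest"} color
#'   sampling at the interpolated source position.
#' @return An object of class \code{"warp_result"}: list with \code{image},
#'   \code{source_map} (h x w x 2 array of interpolated source positions,
#'   \code{NA} where invalid), \code{validity} (h x w logical),
#'   \code{mesh} and \code{proj}.
#' @export
render_warp <- function(source_image, proj, mesh, out_size = NULL,
                        fill = 0, zbuffer = TRUE,
                        sampling = c("bilinear", "nearest")) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(mesh, "delaunay_mesh"))
  dm <- image_dims(source_image)
  if (is.null(out_size)) out_size <- dm[1:2]
  h <- as.integer(out_size[1L]); w <- as.integer(out_size[2L])
  tri <- mesh$triangles
  px <- mesh$points[, 1L]; py <- mesh$points[, 2L]
  su <- rep(NA_real_, h * w)
  sv <- rep(NA_real_, h * w)
  dep <- rep(Inf, h * w)
  written <- rep(FALSE, h * w)
  tol <- 1e-9
  for (i in seq_len(nrow(tri))) {
    a <- tri[i, 1L]; b <- tri[i, 2L]; cc <- tri[i, 3L]
    x1 <- px[a]; x2 <- px[b]; x3 <- px[cc]
    y1 <- py[a]; y2 <- py[b]; y3 <- py[cc]
    d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(d) < 1e-12) next
    umin <- max(0, ceiling(min(x1, x2, x3) - tol))
    umax <- min(w - 1, floor(max(x1, x2, x3) + tol))
    vmin <- max(0, ceiling(min(y1, y2, y3) - tol))
    vmax <- min(h - 1, floor(max(y1, y2, y3) + tol))
    if (umin > umax || vmin > vmax) next
    us <- umin:umax; vs <- vmin:vmax
    pu <- rep(us, each = length(vs))
    pv <- rep(vs, times = length(us))
    l1 <- ((y2 - y3) * (pu - x3) + (x3 - x2) * (pv - y3)) / d
    l2 <- ((y3 - y1) * (pu - x3) + (x1 - x3) * (pv - y3)) / d
    l3 <- 1 - l1 - l2
    ins <- l1 >= -tol & l2 >= -tol & l3 >= -tol
    if (!any(ins)) next
    idx <- pu * h + pv + 1L
    zi <- (proj$z[a] + proj$z[b] + proj$z[cc]) / 3
    sel <- ins & (!written[idx] | (zbuffer & zi < dep[idx] - 1e-9))
    if (!any(sel)) next
    ii <- idx[sel]
    su[ii] <- l1[sel] * proj$u[a] + l2[sel] * proj$u[b] + l3[sel] * proj$u[cc]
    sv[ii] <- l1[sel] * proj$v[a] + l2[sel] * proj$v[b] + l3[sel] * proj$v[cc]
    dep[ii] <- zi
    written[ii] <- TRUE
  }
  nc <- dm[3L]
  fill <- rep_len(fill, nc)
  vi <- which(written)
  if (nc == 1L) {
    out <- matrix(fill, h, w)
    if (length(vi))
      out[vi] <- sample_bilinear(source_image, su[vi], sv[vi],
                                 method = sampling)
  } else {
    out <- array(rep(fill, each = h * w), dim = c(h, w, nc))
    if (length(vi)) {
      vals <- sample_bilinear(source_image, su[vi], sv[vi], method = sampling)
      for (k in seq_len(nc)) {
        plane <- out[, , k]
        plane[vi] <- vals[, k]
        out[, , k] <- plane
      }
    }
  }
  structure(
    list(image = out,
         source_map = array(c(su, sv), dim = c(h, w, 2L)),
         validity = matrix(written, h, w),
         mesh = mesh, proj = proj,
         zbuffer = zbuffer, sampling = sampling),
    class = "warp_result"
  )
}

#' @export
print.warp_result <- function(x, ...) {
  d <- dim(x$validity)
  cat(sprintf("warp_result: %d x %d image, %d mesh triangles, %.1f%% valid\n",
              d[2L], d[1L], nrow(x$mesh$triangles),
              100 * mean(x$validity)))
  if (!is.null(attr(x, "theta")))
    cat("  theta (deg):", format(attr(x, "theta")), "\n")
  invisible(x)
}

#' Warp a frame to a rotated virtual viewpoint
#'
#' The full pipeline: rotate the depth points rigidly about the pivot,
#' reproject them through the camera, Delaunay-mesh the reprojected pixels
#' and render the virtual view by barycentric interpolation.  Deterministic
#' for fixed inputs: points are sorted lexicographically by projected
#' position (ties by depth) before triangulation, and exact duplicate
#' projections keep only the nearest point.
#'
#' @param image Source raster matching the camera size (assumed already
#'   undistorted; see \code{\link{undistort_image}}).
#' @param pts A \code{\link{depth_point_set}} for this frame.
#' @param theta Viewpoint rotation \code{(theta_x, theta_y, theta_z)},
#'   degrees.
#' @param pivot A \code{\link{pivot_pose}}.
#' @param cam A \code{\link{camera_intrinsics}}.
#' @param ... Passed to \code{\link{render_warp}} (\code{fill},
#'   \code{zbuffer}, \code{sampling}, \code{out_size}).
#' @return A \code{"warp_result"} (see \code{\link{render_warp}}) with the
#'   rotation attached as attribute \code{"theta"}.
#' @export
warp_frame <- function(image, pts, theta, pivot, cam, ...) {
  stopifnot(inherits(pts, "depth_point_set"),
            inherits(cam, "camera_intrinsics"))
  dm <- image_dims(image)
  if (dm[1L] != cam$height || dm[2L] != cam$width)
    pv_error("bad_input", "image is %d x %d but the camera expects %d x %d",
             dm[1L], dm[2L], cam$height, cam$width)
  if (nrow(pts$pixels) < 3L)
    pv_error("degenerate_geometry",
             "warping needs at least 3 depth points, got %d",
             nrow(pts$pixels))
  tp <- transform_points(pts, theta, pivot)
  proj <- reproject(tp, cam)
  o <- order(proj$up, proj$vp, proj$z)
  proj <- proj[o, , drop = FALSE]
  dup <- duplicated(paste(round(proj$up, 9), round(proj$vp, 9)))
  proj <- proj[!dup, , drop = FALSE]
  rownames(proj) <- NULL
  if (nrow(proj) < 3L)
    pv_error("degenerate_geometry",
             "fewer than 3 distinct projected points remain")
  mesh <- build_mesh(cbind(proj$up, proj$vp))
  res <- render_warp(image, proj, mesh, ...)
  attr(res, "theta") <- theta
  res
}

#' Evaluate the piecewise-affine warp map at source pixels
#'
#' The mesh induces a map from source pixels to virtual-view pixels: a query
#' point inside a source-domain triangle is carried by the barycentric
#' combination of that triangle's projected vertices.  This evaluates the
#' warp's geometric map directly, without rasterization, and is the natural
#' probe for interpolation-error studies.
#'
#' @param warp A \code{"warp_result"} from \code{\link{warp_frame}}.
#' @param pixels n x 2 matrix of source pixel positions to map.
#' @return n x 2 matrix of mapped positions; \code{NA} rows for query points
#'   outside every source-domain triangle.
#' @export
map_source_pixels <- function(warp, pixels) {
  stopifnot(inherits(warp, "warp_result"))
  q <- as_pixel_matrix(pixels)
  tri <- warp$mesh$triangles
  proj <- warp$proj
  x1 <- proj$u[tri[, 1L]]; x2 <- proj$u[tri[, 2L]]; x3 <- proj$u[tri[, 3L]]
  y1 <- proj$v[tri[, 1L]]; y2 <- proj$v[tri[, 2L]]; y3 <- proj$v[tri[, 3L]]
  d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  ok <- abs(d) >= 1e-12
  out <- matrix(NA_real_, nrow(q), 2L, dimnames = list(NULL, c("u", "v")))
  tol <- 1e-9
  for (i in seq_len(nrow(q))) {
    l1 <- ((y2 - y3) * (q[i, 1L] - x3) + (x3 - x2) * (q[i, 2L] - y3)) / d
    l2 <- ((y3 - y1) * (q[i, 1L] - x3) + (x1 - x3) * (q[i, 2L] - y3)) / d
    l3 <- 1 - l1 - l2
    hit <- which(ok & l1 >= -tol & l2 >= -tol & l3 >= -tol)
    if (!length(hit)) next
    j <- hit[1L]
    out[i, ] <- c(
      l1[j] * proj$up[tri[j, 1L]] + l2[j] * proj$up[tri[j, 2L]] +
        l3[j] * proj$up[tri[j, 3L]],
      l1[j] * proj$vp[tri[j, 1L]] + l2[j] * proj$vp[tri[j, 2L]] +
        l3[j] * proj$vp[tri[j, 3L]])
  }
  out
}
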