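# Rendering-fidelity evaluation.  Because the synthetic scene is planar, the
# exact pixel-to-pixel map induced by a pivot rotation is a closed-form
# planar homography; the warp engine's mesh interpolation is measured
# against it, in pixels and in millimetres on the phantom surface.

#' Phantom plane in the camera frame
#'
#' @param setup A \code{\link{make_default_setup}} scene.
#' @return An object of class \code{"scene_plane"}: unit normal \code{n},
#'   plane offset \code{d} (so \code{n . X = d}), in-plane axes \code{e1},
#'   \code{e2} and \code{origin} (sheet center), all camera-frame mm.
#' @export
phantom_plane <- function(setup) {
  stopifnot(inherits(setup, "scene_setup"))
  structure(scene_frame(setup$pose), class = "scene_plane")
}

#' Rigidly rotate a plane about the pivot
#'
#' @param plane A \code{"scene_plane"}.
#' @param theta Rotation, degrees.
#' @param pivot A \code{\link{pivot_pose}}.
#' @return The transformed \code{"scene_plane"}.
#' @export
transform_plane <- function(plane, theta, pivot) {
  stopifnot(inherits(plane, "scene_plane"))
  M <- pivot_transform(theta, pivot)
  R <- M[1:3, 1:3]
  out <- list(e1 = as.numeric(R %*% plane$e1),
              e2 = as.numeric(R %*% plane$e2),
              n = as.numeric(R %*% plane$n),
              origin = as.numeric(M %*% c(plane$origin, 1))[1:3])
  out$d <- sum(out$n * out$origin)
  structure(out, class = "scene_plane")
}

# Ray-plane intersection: back-project pixels onto the plane n . X = d.
# Returns n x 3 points; NA rows where the ray misses (parallel or behind).
backproject_to_plane <- function(pixels, cam, plane) {
  px <- as_pixel_matrix(pixels)
  dx <- (px[, 1L] - cam$u0) / cam$fx
  dy <- (px[, 2L] - cam$v0) / cam$fy
  den <- plane$n[1L] * dx + plane$n[2L] * dy + plane$n[3L]
  t <- plane$d / den
  bad <- !is.finite(t) | t <= 0 | abs(den) < 1e-12
  out <- cbind(t * dx, t * dy, t)
  out[bad, ] <- NA_real_
  out
}

#' Closed-form pixel map for a planar scene under a pivot rotation
#'
#' Composes back-projection onto the plane, the rigid pivot rotation and
#' reprojection into one analytic map from source pixels to virtual-view
#' pixels.  For a planar scene this is exact — an 8-degree-of-freedom
#' homography — and serves as the ground truth the mesh warp is compared
#' against.
#'
#' @param plane A \code{"scene_plane"} (see \code{\link{phantom_plane}}); it
#'   must not pass through the camera center.
#' @param cam A \code{\link{camera_intrinsics}}.
#' @param theta Rotation, degrees.
#' @param pivot A \code{\link{pivot_pose}}.
#' @return A function mapping an n x 2 matrix of source pixels to an n x 2
#'   matrix of virtual-view pixels (\code{NA} rows where a ray misses the
#'   plane or the mapped point falls behind the camera).
#' @export
homography_oracle <- function(plane, cam, theta, pivot) {
  stopifnot(inherits(plane, "scene_plane"),
            inherits(cam, "camera_intrinsics"))
  if (abs(plane$d) < 1e-9)
    pv_error("degenerate_geometry",
             "plane passes through the camera center; the view map is undefined")
  M <- pivot_transform(theta, pivot)
  force(cam)
  function(pixels) {
    X <- backproject_to_plane(pixels, cam, plane)
    ok <- is.finite(X[, 3L])
    out <- matrix(NA_real_, nrow(X), 2L, dimnames = list(NULL, c("u", "v")))
    if (any(ok)) {
      Xp <- t(M %*% rbind(t(X[ok, , drop = FALSE]), 1))[, 1:3, drop = FALSE]
      good <- Xp[, 3L] > 0
      res <- matrix(NA_real_, sum(ok), 2L)
      if (any(good))
        res[good, ] <- cbind(cam$fx * Xp[good, 1L] / Xp[good, 3L] + cam$u0,
                             cam$fy * Xp[good, 2L] / Xp[good, 3L] + cam$v0)
      out[ok, ] <- res
    }
    out
  }
}

#' Locate dark landmarks by intensity-weighted centroid
#'
#' For each approximate position, thresholds a window around it, labels the
#' connected components of the dark mask, picks the component nearest the
#' window center and returns its intensity-weighted centroid (weights
#' \code{1 - intensity}).
#'
#' @param image Grayscale matrix or color array, values in \code{[0, 1]}.
#' @param centers n x 2 matrix of approximate positions (pixels).
#' @param radius Half-size of the search window, pixels.
#' @param threshold Intensity below which a pixel counts as mark.
#' @return n x 2 matrix of refined positions; \code{NA} rows where no mark
#'   was found in the window.
#' @export
locate_landmarks <- function(image, centers, radius = 12,
                             threshold = 0.45) {
  img <- as_gray(image)
  ctr <- as_pixel_matrix(centers, "centers")
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, nrow(ctr), 2L,
                dimnames = list(NULL, c("u", "v")))
  for (i in seq_len(nrow(ctr))) {
    if (any(!is.finite(ctr[i, ]))) next
    u0 <- max(0L, floor(ctr[i, 1L] - radius))
    u1 <- min(w - 1L, ceiling(ctr[i, 1L] + radius))
    v0 <- max(0L, floor(ctr[i, 2L] - radius))
    v1 <- min(h - 1L, ceiling(ctr[i, 2L] + radius))
    if (u0 > u1 || v0 > v1) next
    sub <- img[(v0 + 1):(v1 + 1), (u0 + 1):(u1 + 1), drop = FALSE]
    mask <- sub < threshold
    if (!any(mask)) next
    labels <- EBImage::bwlabel(mask * 1)
    uu <- matrix(rep(u0:u1, each = nrow(sub)), nrow(sub))
    vv <- matrix(rep(v0:v1, times = ncol(sub)), nrow(sub))
    dd <- (uu - ctr[i, 1L])^2 + (vv - ctr[i, 2L])^2
    dd[!mask] <- Inf
    lab <- labels[which.min(dd)]
    sel <- labels == lab
    wgt <- (1 - sub)[sel]
    out[i, ] <- c(sum(wgt * uu[sel]), sum(wgt * vv[sel])) / sum(wgt)
  }
  out
}

#' Rendering error of a warp against the analytic ground truth
#'
#' For each landmark, compares its position in the warped image with the
#' position the closed-form homography predicts.  The pixel error is the
#' Euclidean distance in the image; the surface error back-projects both
#' positions through the virtual camera onto the (rotated) phantom plane and
#' measures their 3D separation in mm — the displacement a viewer would
#' perceive on the task surface.
#'
#' @param warp A \code{"warp_result"} from \code{\link{warp_frame}}.
#' @param oracle_map The map returned by \code{\link{homography_oracle}} for
#'   the same rotation.
#' @param landmarks n x 2 matrix of landmark positions in the source view.
#' @param setup The \code{\link{make_default_setup}} scene.
#' @param theta The rotation at which \code{warp} was produced, degrees.
#' @param warped_positions Optional n x 2 matrix of already-measured
#'   landmark positions in the warped image; when \code{NULL} (default)
#'   each landmark is localized with \code{\link{locate_landmarks}} around
#'   its predicted position.
#' @param search_radius Window half-size for localization, pixels; default
#'   2.5 dot radii at the standoff distance.
#' @return An object of class \code{"error_report"}: list with
#'   \code{per_landmark} (data frame: source, oracle and measured positions,
#'   \code{error_px}, \code{error_mm}, \code{valid}), \code{theta} and
#'   summary fields \code{max_mm}, \code{mean_mm}, \code{median_mm},
#'   \code{max_px}, \code{mean_px}, \code{n_valid}, \code{n_excluded}.
#'   Landmarks outside the warp's valid region are excluded from the
#'   summaries and flagged \code{valid = FALSE}, never silently dropped.
#' @export
rendering_error <- function(warp, oracle_map, landmarks, setup, theta,
                            warped_positions = NULL, search_radius = NULL) {
  stopifnot(inherits(warp, "warp_result"), is.function(oracle_map),
            inherits(setup, "scene_setup"))
  if (length(theta) == 1L) theta <- c(theta, 0, 0)
  lm <- as_pixel_matrix(landmarks, "landmarks")
  O <- oracle_map(lm)
  h <- nrow(warp$validity); w <- ncol(warp$validity)
  inside <- is.finite(O[, 1L]) & is.finite(O[, 2L]) &
    O[, 1L] >= 0 & O[, 1L] <= w - 1 & O[, 2L] >= 0 & O[, 2L] <= h - 1
  valid <- inside
  valid[inside] <- warp$validity[cbind(round(O[inside, 2L]) + 1,
                                       round(O[inside, 1L]) + 1)]
  if (is.null(warped_positions)) {
    if (is.null(search_radius)) {
      ph <- setup$phantom
      search_radius <- max(6, 2.5 * setup$cam$fx * ph$dot_radius /
                             setup$pose$standoff)
    }
    W <- matrix(NA_real_, nrow(lm), 2L)
    if (any(valid))
      W[valid, ] <- locate_landmarks(warp$image, O[valid, , drop = FALSE],
                                     radius = search_radius)
  } else {
    W <- as_pixel_matrix(warped_positions, "warped_positions")
    if (nrow(W) != nrow(lm))
      stopf("'warped_positions' must match 'landmarks' row for row")
  }
  valid <- valid & is.finite(W[, 1L]) & is.finite(W[, 2L])
  err_px <- rep(NA_real_, nrow(lm))
  err_mm <- rep(NA_real_, nrow(lm))
  if (any(valid)) {
    dpx <- W[valid, , drop = FALSE] - O[valid, , drop = FALSE]
    err_px[valid] <- sqrt(rowSums(dpx^2))
    plane1 <- transform_plane(phantom_plane(setup), theta, setup$pivot)
    Xw <- backproject_to_plane(W[valid, , drop = FALSE], setup$cam, plane1)
    Xo <- backproject_to_plane(O[valid, , drop = FALSE], setup$cam, plane1)
    err_mm[valid] <- sqrt(rowSums((Xw - Xo)^2))
  }
  per <- data.frame(u_src = lm[, 1L], v_src = lm[, 2L],
                    u_oracle = O[, 1L], v_oracle = O[, 2L],
                    u_warp = W[, 1L], v_warp = W[, 2L],
                    error_px = err_px, error_mm = err_mm, valid = valid)
  ok <- which(valid & is.finite(err_mm))
  summ <- function(f, x) if (length(ok)) f(x[ok]) else NA_real_
  structure(
    list(per_landmark = per, theta = theta,
         max_mm = summ(max, err_mm), mean_mm = summ(mean, err_mm),
         median_mm = summ(median, err_mm),
         max_px = summ(max, err_px), mean_px = summ(mean, err_px),
         n_valid = length(ok), n_excluded = nrow(per) - length(ok)),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "error_report @ theta = (%g, %g, %g) deg: %d landmarks (%d excluded)\n",
    x$theta[1L], x$theta[2L], x$theta[3L], x$n_valid, x$n_excluded))
  cat(sprintf("  surface error: max %.4f mm, mean %.4f mm, median %.4f mm\n",
              x$max_mm, x$mean_mm, x$median_mm))
  cat(sprintf("  image error:   max %.4f px, mean %.4f px\n",
              x$max_px, x$mean_px))
  invisible(x)
}

#' Sweep the rendering error over viewpoint angles
#'
#' Renders the base view once, samples the depth grid once, then for every
#' rotation warps the frame, builds the matching homography oracle and
#' measures the landmark rendering error.
#'
#' @param setup A \code{\link{make_default_setup}} scene.
#' @param theta_list Rotations to evaluate: a numeric vector of
#'   \code{theta_x} values (degrees) or a list of length-3 vectors.
#' @param pitch Depth-grid pitch, mm (default 5).
#' @param method \code{"localize"} (default): landmarks are found in the
#'   rendered warped image by centroid localization — the full-system error.
#'   \code{"map"}: landmarks are pushed through the piecewise-affine warp
#'   map directly (\code{\link{map_source_pixels}}) — the pure interpolation
#'   error, free of rasterization noise.
#' @param supersample Supersampling of the base render.
#' @param ... Passed to \code{\link{warp_frame}}.
#' @return List of \code{"error_report"} objects, one per rotation (empty
#'   list for an empty \code{theta_list}).
#' @export
sweep_angles <- function(setup, theta_list, pitch = 5,
                         method = c("localize", "map"), supersample = 4L,
                         ...) {
  stopifnot(inherits(setup, "scene_setup"))
  method <- match.arg(method)
  if (length(theta_list) == 0L) return(list())
  if (is.numeric(theta_list)) theta_list <- as.list(theta_list)
  base <- render_phantom_view(setup, c(0, 0, 0), supersample = supersample)
  grid <- sample_depth_grid(setup, pitch)
  # Track the dots as *measured* in the base view (centroid localization)
  # rather than their analytically projected centers: warped and reference
  # positions then describe the same physical feature and the small
  # perspective bias of an ellipse centroid cancels.
  lm0 <- dot_landmarks(setup)
  lm <- locate_landmarks(base, lm0)
  miss <- !is.finite(lm[, 1L])
  lm[miss, ] <- lm0[miss, , drop = FALSE]
  plane <- phantom_plane(setup)
  lapply(theta_list, function(th) {
    if (length(th) == 1L) th <- c(th, 0, 0)
    wr <- warp_frame(base, grid, th, setup$pivot, setup$cam, ...)
    om <- homography_oracle(plane, setup$cam, th, setup$pivot)
    wp <- if (method == "map") map_source_pixels(wr, lm) else NULL
    rendering_error(wr, om, lm, setup, th, warped_positions = wp)
  })
}
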