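# Synthetic test scene: a planar dot phantom imaged obliquely, with an
# analytic ground-truth renderer.  All fixtures are generated in code; the
# scene mimics a suturing phantom (a rubber sheet with a printed cut line
# flanked by target dots) viewed by a camera elevated 20 degrees at 117 mm,
# with the viewpoint pivot 120 mm down the optical axis.

#' Planar phantom specification
#'
#' A flat sheet carrying a central line (the simulated tissue cut) flanked
#' by target dots.  Sheet coordinates \code{(a, b)} are mm on the surface,
#' origin at the sheet center: \code{a} runs along the line, \code{b}
#' across it.
#'
#' @param width,height Sheet size, mm. Default 100 x 50.
#' @param dot_centers n x 2 matrix of dot centers \code{(a, b)}, mm.
#'   Default: six pairs flanking the line at \code{b = +-5} mm,
#'   \code{a = -25, -15, ..., 25} (10 mm apart along the line).
#' @param dot_radius Dot radius, mm. Default 1.5.
#' @param line Segment endpoints \code{(a0, b0, a1, b1)}, mm.
#' @param line_halfwidth Half the stroke width of the line, mm.
#' @param bg,fg,backdrop Intensities in \code{[0, 1]} of the sheet
#'   background, the printed marks, and the region outside the sheet.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(width = 100, height = 50,
                         dot_centers = NULL, dot_radius = 1.5,
                         line = c(-30, 0, 30, 0), line_halfwidth = 0.5,
                         bg = 0.85, fg = 0.1, backdrop = 0.6) {
  check_scalar(width, "width", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  check_scalar(dot_radius, "dot_radius", positive = TRUE)
  if (is.null(dot_centers)) {
    a <- seq(-25, 25, by = 10)
    dot_centers <- cbind(a = rep(a, times = 2L),
                         b = rep(c(-5, 5), each = length(a)))
  }
  dot_centers <- as_pixel_matrix(dot_centers, "dot_centers")
  if (any(abs(dot_centers[, 1L]) > width / 2 |
          abs(dot_centers[, 2L]) > height / 2))
    stopf("all dots must lie on the sheet")
  if (length(line) != 4L || any(!is.finite(line)))
    stopf("'line' must be (a0, b0, a1, b1)")
  structure(
    list(width = width, height = height, dot_centers = dot_centers,
         dot_radius = dot_radius, line = as.numeric(line),
         line_halfwidth = line_halfwidth, bg = bg, fg = fg,
         backdrop = backdrop),
    class = "phantom_spec"
  )
}

#' Scene pose of the camera relative to the phantom
#'
#' @param elevation Angle between the optical axis and the sheet surface,
#'   degrees, in (0, 90). Default 20: the near-horizontal view that makes
#'   depth perception hard and motivates viewpoint alternation.
#' @param standoff Distance from the camera center to the sheet center along
#'   the optical axis, mm. Default 117.
#' @param pivot_center Rotation center of the virtual viewpoint in the
#'   camera frame, mm. Default \code{(0, 0, 120)}.
#' @return An object of class \code{"scene_pose"}.
#' @export
scene_pose <- function(elevation = 20, standoff = 117,
                       pivot_center = c(0, 0, 120)) {
  check_scalar(elevation, "elevation")
  if (elevation <= 0 || elevation >= 90)
    stopf("'elevation' must be in (0, 90) degrees")
  check_scalar(standoff, "standoff", positive = TRUE)
  structure(list(elevation = elevation, standoff = standoff,
                 pivot_center = as.numeric(pivot_center)),
            class = "scene_pose")
}

# Orthonormal frame of the sheet in camera coordinates: e1 along the line
# direction (camera x), e2 across the sheet receding from the camera, n the
# unit plane normal; S is the sheet center.  With v (image rows) pointing
# down, the surface recedes upward in the image: e2 = (0, -sin e, cos e).
scene_frame <- function(pose) {
  e <- deg2rad(pose$elevation)
  e1 <- c(1, 0, 0)
  e2 <- c(0, -sin(e), cos(e))
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  n <- n / sqrt(sum(n^2))
  S <- c(0, 0, pose$standoff)
  list(e1 = e1, e2 = e2, n = n, origin = S, d = sum(n * S))
}

#' Default synthetic setup
#'
#' The reference configuration of the synthetic experiment: camera elevated
#' 20 degrees above the sheet at 117 mm standoff, viewpoint pivot at
#' \code{(0, 0, 120)} mm, a 100 x 50 mm phantom sheet, and invented default
#' intrinsics (fx = fy = 800 px, 640 x 480, no distortion) standing in for
#' an unpublished camera calibration.
#'
#' @param cam Optional \code{\link{camera_intrinsics}} override.
#' @param pose Optional \code{\link{scene_pose}} override.
#' @param phantom Optional \code{\link{phantom_spec}} override.
#' @return An object of class \code{"scene_setup"}: list with \code{cam},
#'   \code{pose}, \code{phantom} and \code{pivot} (a
#'   \code{\link{pivot_pose}} at \code{pose$pivot_center}).
#' @export
make_default_setup <- function(cam = NULL, pose = NULL, phantom = NULL) {
  if (is.null(cam))
    cam <- camera_intrinsics(800, 800, 320, 240, width = 640, height = 480)
  if (is.null(pose)) pose <- scene_pose()
  if (is.null(phantom)) phantom <- phantom_spec()
  structure(list(cam = cam, pose = pose, phantom = phantom,
                 pivot = pivot_pose(pose$pivot_center)),
            class = "scene_setup")
}

# Intensity of the phantom surface at sheet coordinates (a, b), vectorized.
phantom_pattern <- function(phantom, a, b) {
  out <- rep(phantom$bg, length(a))
  # line segment distance
  l <- phantom$line
  dx <- l[3L] - l[1L]; dy <- l[4L] - l[2L]
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmin(pmax(((a - l[1L]) * dx + (b - l[2L]) * dy) / len2,
                               0), 1) else 0
  dl <- sqrt((a - (l[1L] + t * dx))^2 + (b - (l[2L] + t * dy))^2)
  out[dl <= phantom$line_halfwidth] <- phantom$fg
  for (i in seq_len(nrow(phantom$dot_centers))) {
    dc <- phantom$dot_centers[i, ]
    hit <- (a - dc[1L])^2 + (b - dc[2L])^2 <= phantom$dot_radius^2
    out[hit] <- phantom$fg
  }
  out[abs(a) > phantom$width / 2 | abs(b) > phantom$height / 2] <-
    phantom$backdrop
  out
}

#' Analytic ground-truth render of the phantom
#'
#' Renders the planar phantom exactly as seen from the camera after rotating
#' the scene by \code{theta} about the pivot: every view ray is intersected
#' with the (rotated) phantom plane in closed form and the surface pattern
#' is evaluated there.  No meshing, no interpolation — this is the oracle
#' the warp engine is measured against.  Edges are anti-aliased by
#' \code{supersample^2} samples per pixel so printed marks can be localized
#' to a small fraction of a pixel.
#'
#' @param setup A \code{\link{make_default_setup}} scene.
#' @param theta Viewpoint rotation, degrees (default zero: the base view).
#' @param supersample Samples per pixel edge (default 4).
#' @return Grayscale matrix \code{cam$height x cam$width}, values in
#'   \code{[0, 1]}. Deterministic: identical inputs give identical pixels.
#' @export
render_phantom_view <- function(setup, theta = c(0, 0, 0), supersample = 4L) {
  stopifnot(inherits(setup, "scene_setup"))
  cam <- setup$cam
  fr <- scene_frame(setup$pose)
  M <- pivot_transform(theta, setup$pivot)
  R <- M[1:3, 1:3]
  S1 <- as.numeric(M %*% c(fr$origin, 1))[1:3]
  n1 <- as.numeric(R %*% fr$n)
  e1p <- as.numeric(R %*% fr$e1)
  e2p <- as.numeric(R %*% fr$e2)
  d1 <- sum(n1 * S1)
  if (S1[3L] <= 1e-6)
    pv_error("degenerate_geometry",
             "phantom center is at or behind the camera after rotation")
  if (abs(d1) < 1e-9)
    pv_error("degenerate_geometry", "phantom plane passes through the camera")
  # edge-on guard: the plane must keep one side facing every view ray
  cu <- c(0, cam$width - 1, 0, cam$width - 1, (cam$width - 1) / 2)
  cv <- c(0, 0, cam$height - 1, cam$height - 1, (cam$height - 1) / 2)
  den <- n1[1L] * (cu - cam$u0) / cam$fx + n1[2L] * (cv - cam$v0) / cam$fy +
    n1[3L]
  if (min(abs(den)) < 1e-6 || length(unique(sign(den))) > 1L)
    pv_error("degenerate_geometry",
             "phantom plane is edge-on within the field of view")
  s <- as.integer(supersample)
  stopifnot(s >= 1L)
  h <- cam$height; w <- cam$width
  ugrid <- rep(seq_len(w) - 1, each = h)
  vgrid <- rep(seq_len(h) - 1, times = w)
  acc <- numeric(h * w)
  offs <- (seq_len(s) - 0.5) / s - 0.5
  for (ou in offs) for (ov in offs) {
    dx <- (ugrid + ou - cam$u0) / cam$fx
    dy <- (vgrid + ov - cam$v0) / cam$fy
    den <- n1[1L] * dx + n1[2L] * dy + n1[3L]
    t <- d1 / den
    X1 <- t * dx - S1[1L]
    X2 <- t * dy - S1[2L]
    X3 <- t - S1[3L]
    a <- X1 * e1p[1L] + X2 * e1p[2L] + X3 * e1p[3L]
    b <- X1 * e2p[1L] + X2 * e2p[2L] + X3 * e2p[3L]
    val <- phantom_pattern(setup$phantom, a, b)
    val[!is.finite(t) | t <= 0] <- setup$phantom$backdrop
    acc <- acc + val
  }
  matrix(acc / (s * s), h, w)
}

#' Sample a uniform depth grid on the phantom
#'
#' Generates the sparse depth-point set the system consumes in place of 3D
#' shape acquisition: 3D points uniformly spaced at \code{pitch} mm on the
#' phantom plane (at the base viewpoint), each paired with its exact
#' projected pixel; points projecting outside the image are dropped.
#' The default 5 mm pitch corresponds to 0.2 sample points per mm.
#'
#' @param setup A \code{\link{make_default_setup}} scene.
#' @param pitch Grid spacing on the surface, mm.
#' @return A \code{\link{depth_point_set}}.
#' @export
sample_depth_grid <- function(setup, pitch = 5) {
  stopifnot(inherits(setup, "scene_setup"))
  check_scalar(pitch, "pitch", positive = TRUE)
  ph <- setup$phantom
  fr <- scene_frame(setup$pose)
  a <- seq(-ph$width / 2, ph$width / 2, by = pitch)
  b <- seq(-ph$height / 2, ph$height / 2, by = pitch)
  ab <- cbind(rep(a, times = length(b)), rep(b, each = length(a)))
  P <- cbind(fr$origin[1L] + ab[, 1L] * fr$e1[1L] + ab[, 2L] * fr$e2[1L],
             fr$origin[2L] + ab[, 1L] * fr$e1[2L] + ab[, 2L] * fr$e2[2L],
             fr$origin[3L] + ab[, 1L] * fr$e1[3L] + ab[, 2L] * fr$e2[3L])
  keep <- P[, 3L] > 0
  pr <- matrix(NA_real_, nrow(P), 2L)
  pr[keep, ] <- project_points(P[keep, , drop = FALSE], setup$cam)
  keep <- keep & is.finite(pr[, 1L]) &
    pr[, 1L] >= 0 & pr[, 1L] <= setup$cam$width - 1 &
    pr[, 2L] >= 0 & pr[, 2L] <= setup$cam$height - 1
  if (!any(keep))
    pv_error("empty_geometry", "no grid point falls inside the field of view")
  depth_point_set(pr[keep, , drop = FALSE], P[keep, , drop = FALSE],
                  setup$cam$width, setup$cam$height)
}

#' Source-pixel positions of the phantom dots
#'
#' Projects the dot centers of the phantom into the base (theta = 0) view;
#' these are the landmarks tracked by the evaluation module.
#'
#' @param setup A \code{\link{make_default_setup}} scene.
#' @return n x 2 matrix of pixel positions \code{(u, v)}, with the dots'
#'   sheet coordinates attached as attribute \code{"sheet"}.
#' @export
dot_landmarks <- function(setup) {
  stopifnot(inherits(setup, "scene_setup"))
  fr <- scene_frame(setup$pose)
  dc <- setup$phantom$dot_centers
  P <- cbind(fr$origin[1L] + dc[, 1L] * fr$e1[1L] + dc[, 2L] * fr$e2[1L],
             fr$origin[2L] + dc[, 1L] * fr$e1[2L] + dc[, 2L] * fr$e2[2L],
             fr$origin[3L] + dc[, 1L] * fr$e1[3L] + dc[, 2L] * fr$e2[3L])
  px <- project_points(P, setup$cam)
  attr(px, "sheet") <- dc
  px
}

#' Generate a synthetic two-axis input trace
#'
#' Deterministic joystick traces for exercising the control law, emulating
#' the characteristic usage patterns seen in practice: holding one alternate
#' viewpoint, pulsing to a viewpoint and back, or wandering continuously.
#' The first \code{n_neutral_frames} samples are always exactly neutral so
#' the automatic neutral calibration sees a resting stick.
#'
#' @param profile One of \code{"neutral"} (stick at rest throughout),
#'   \code{"hold"} (deflect, then release and keep the reached viewpoint),
#'   \code{"pulse"} (deflect one way, then the other, then rest) or
#'   \code{"continuous"} (seeded smooth wandering).
#' @param duration Trace length, seconds.
#' @param update_rate Samples per second.
#' @param seed Integer seed (only \code{"continuous"} draws random numbers;
#'   the global RNG state is restored on exit).
#' @param n_neutral_frames Length of the leading neutral segment.
#' @return Data frame with columns \code{t}, \code{q1}, \code{q2}; all
#'   values in \code{[-1, 1]}.
#' @export
make_input_trace <- function(profile = c("neutral", "hold", "pulse",
                                         "continuous"),
                             duration = 10, update_rate = 16, seed = 1L,
                             n_neutral_frames = 10L) {
  profile <- match.arg(profile)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(update_rate, "update_rate", positive = TRUE)
  n <- max(as.integer(round(duration * update_rate)), 1L)
  tt <- (seq_len(n) - 1) / update_rate
  q1 <- numeric(n)
  q2 <- numeric(n)
  ncal <- min(as.integer(n_neutral_frames), n)
  active <- seq_len(n) > ncal
  if (profile == "hold") {
    push <- active & seq_len(n) <= ncal + round(0.35 * n)
    q1[push] <- 0.7
  } else if (profile == "pulse") {
    seg <- floor(5 * (seq_len(n) - 1) / n)  # five equal segments
    q1[active & seg == 1L] <- 0.8
    q1[active & seg == 3L] <- -0.8
  } else if (profile == "continuous") {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    f <- runif(2L, 0.1, 0.4)
    phase <- runif(2L, 0, 2 * pi)
    q1[active] <- 0.8 * sin(2 * pi * f[1L] * tt[active] + phase[1L])
    q2[active] <- 0.4 * sin(2 * pi * f[2L] * tt[active] + phase[2L])
  }
  data.frame(t = tt, q1 = pmin(pmax(q1, -1), 1), q2 = pmin(pmax(q2, -1), 1))
}
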