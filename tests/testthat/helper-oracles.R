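# Shared fixtures and independent oracles for the test suite.

# Expensive fixtures (renders, warps) computed once per test run.
.fixtures <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE))
    assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures, inherits = FALSE)
}

default_setup <- function() fixture("setup", make_default_setup())
base_view <- function() fixture("base", render_phantom_view(default_setup()))
depth_grid <- function(pitch) {
  fixture(paste0("grid_", pitch), sample_depth_grid(default_setup(), pitch))
}
warped_at <- function(theta_x, pitch) {
  fixture(sprintf("warp_%g_%g", theta_x, pitch),
          warp_frame(base_view(), depth_grid(pitch), c(theta_x, 0, 0),
                     default_setup()$pivot, default_setup()$cam))
}

# Independent rigid-rotation oracle: componentwise rotations about x, then
# y, then z of the pivot-relative coordinates, written out as scalar
# trigonometry (no shared code with the package's matrix path).
rotate_about_pivot_oracle <- function(p, theta_deg, center) {
  t <- theta_deg * pi / 180
  v <- p - center
  # Rx
  v <- c(v[1], cos(t[1]) * v[2] - sin(t[1]) * v[3],
         sin(t[1]) * v[2] + cos(t[1]) * v[3])
  # Ry
  v <- c(cos(t[2]) * v[1] + sin(t[2]) * v[3], v[2],
         -sin(t[2]) * v[1] + cos(t[2]) * v[3])
  # Rz
  v <- c(cos(t[3]) * v[1] - sin(t[3]) * v[2],
         sin(t[3]) * v[1] + cos(t[3]) * v[2], v[3])
  v + center
}

# Brute-force empty-circumcircle check of a triangulation: TRUE when no
# input point lies strictly inside any triangle's circumcircle.
circumcircles_empty <- function(points, triangles, rel_tol = 1e-7) {
  for (i in seq_len(nrow(triangles))) {
    tv <- points[triangles[i, ], , drop = FALSE]
    ax <- tv[1, 1]; ay <- tv[1, 2]
    bx <- tv[2, 1]; by <- tv[2, 2]
    cx <- tv[3, 1]; cy <- tv[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    d2 <- (points[, 1] - ux)^2 + (points[, 2] - uy)^2
    inside <- which(d2 < r2 * (1 - rel_tol))
    if (length(setdiff(inside, triangles[i, ]))) return(FALSE)
  }
  TRUE
}

# Fit a 3x3 homography from exactly 4 point pairs (direct linear solve of
# the 8 unknowns with h33 = 1) and apply it.
fit_homography4 <- function(src, dst) {
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; xp <- dst[i, 1]; yp <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * xp, -y * xp)
    A[2 * i, ] <- c(0, 0, 0, x, y, 1, -x * yp, -y * yp)
    b[2 * i - 1] <- xp
    b[2 * i] <- yp
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}
apply_homography <- function(H, px) {
  p <- cbind(px, 1) %*% t(H)
  p[, 1:2] / p[, 3]
}

# Invert the Brown-Conrady forward model by fixed-point iteration (test-side
# twin used to synthesize distorted images; the package's forward model is
# the oracle it iterates on).
invert_distortion <- function(px, cam, iters = 60) {
  d <- cam$dist
  xd <- (px[, 1] - cam$u0) / cam$fx
  yd <- (px[, 2] - cam$v0) / cam$fy
  x <- xd; y <- yd
  for (k in seq_len(iters)) {
    r2 <- x^2 + y^2
    radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
    x <- (xd - (2 * d[3] * x * y + d[4] * (r2 + 2 * x^2))) / radial
    y <- (yd - (d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y)) / radial
  }
  cbind(x * cam$fx + cam$u0, y * cam$fy + cam$v0)
}
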