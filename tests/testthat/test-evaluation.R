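test_that("the planar oracle is the identity at zero rotation", {
  setup <- default_setup()
  om <- homography_oracle(phantom_plane(setup), setup$cam, c(0, 0, 0),
                          setup$pivot)
  set.seed(31)
  px <- cbind(runif(50, 100, 540), runif(50, 100, 380))
  expect_lt(max(abs(om(px) - px)), 1e-9)
})

test_that("the oracle map is an 8-degree-of-freedom homography", {
  setup <- default_setup()
  th <- c(25, 0, 0)
  om <- homography_oracle(phantom_plane(setup), setup$cam, th, setup$pivot)
  anchors <- cbind(c(150, 500, 150, 500), c(150, 150, 380, 380))
  H <- fit_homography4(anchors, om(anchors))
  set.seed(33)
  px <- cbind(runif(100, 120, 520), runif(100, 130, 400))
  expect_lt(max(abs(apply_homography(H, px) - om(px))), 1e-6)
})

test_that("a plane through the camera center is rejected", {
  setup <- default_setup()
  plane <- phantom_plane(setup)
  plane$d <- 0
  expect_error(homography_oracle(plane, setup$cam, c(5, 0, 0), setup$pivot),
               class = "pv_degenerate_geometry")
})

test_that("measuring a warp against positions from the oracle itself gives zero", {
  setup <- default_setup()
  th <- c(15, 0, 0)
  wr <- warped_at(15, 5)
  om <- homography_oracle(phantom_plane(setup), setup$cam, th, setup$pivot)
  lm <- dot_landmarks(setup)
  rep0 <- rendering_error(wr, om, lm, setup, th, warped_positions = om(lm))
  expect_equal(rep0$n_valid, nrow(lm))
  expect_lt(rep0$max_mm, 1e-6)
  expect_lt(rep0$max_px, 1e-6)
})

test_that("a one-pixel shift measures the local pixel-to-surface scale", {
  setup <- default_setup()
  th <- c(25, 0, 0)
  wr <- warped_at(25, 5)
  om <- homography_oracle(phantom_plane(setup), setup$cam, th, setup$pivot)
  lm <- dot_landmarks(setup)
  O <- om(lm)
  shifted <- O + cbind(rep(1, nrow(O)), 0)
  repS <- rendering_error(wr, om, lm, setup, th, warped_positions = shifted)
  expect_equal(repS$per_landmark$error_px, rep(1, nrow(lm)))
  # finite-difference oracle for the mm displacement of a 1 px u-shift
  plane1 <- transform_plane(phantom_plane(setup), th, setup$pivot)
  bp <- function(px) {
    dx <- (px[, 1] - setup$cam$u0) / setup$cam$fx
    dy <- (px[, 2] - setup$cam$v0) / setup$cam$fy
    t <- plane1$d / (plane1$n[1] * dx + plane1$n[2] * dy + plane1$n[3])
    cbind(t * dx, t * dy, t)
  }
  eps <- 1e-4
  fd <- sqrt(rowSums((bp(O + cbind(rep(eps, nrow(O)), 0)) - bp(O))^2)) / eps
  expect_equal(repS$per_landmark$error_mm, fd, tolerance = 0.02)
})

test_that("pixel and surface errors agree through the local scale factor", {
  setup <- default_setup()
  th <- c(25, 0, 0)
  wr <- warped_at(25, 5)
  om <- homography_oracle(phantom_plane(setup), setup$cam, th, setup$pivot)
  lm <- dot_landmarks(setup)
  rep1 <- rendering_error(wr, om, lm, setup, th)
  per <- rep1$per_landmark
  plane1 <- transform_plane(phantom_plane(setup), th, setup$pivot)
  bp <- function(px) {
    dx <- (px[, 1] - setup$cam$u0) / setup$cam$fx
    dy <- (px[, 2] - setup$cam$v0) / setup$cam$fy
    t <- plane1$d / (plane1$n[1] * dx + plane1$n[2] * dy + plane1$n[3])
    cbind(t * dx, t * dy, t)
  }
  for (i in which(per$valid & per$error_px > 1e-4)) {
    o <- cbind(per$u_oracle[i], per$v_oracle[i])
    dir <- c(per$u_warp[i] - per$u_oracle[i],
             per$v_warp[i] - per$v_oracle[i]) / per$error_px[i]
    eps <- 1e-4
    scale <- sqrt(sum((bp(o + eps * rbind(dir)) - bp(o))^2)) / eps
    expect_equal(per$error_mm[i], per$error_px[i] * scale,
                 tolerance = 0.05)
  }
})

test_that("landmarks outside the valid warp region are flagged, not dropped", {
  setup <- default_setup()
  th <- c(25, 0, 0)
  wr <- warped_at(25, 5)
  om <- homography_oracle(phantom_plane(setup), setup$cam, th, setup$pivot)
  lm <- rbind(dot_landmarks(setup), c(2, 2))  # far corner: outside the hull
  rep1 <- rendering_error(wr, om, lm, setup, th)
  expect_equal(nrow(rep1$per_landmark), nrow(lm))
  expect_false(rep1$per_landmark$valid[nrow(lm)])
  expect_equal(rep1$n_excluded, 1L)
  expect_true(rep1$max_mm >= rep1$mean_mm, rep1$mean_mm >= 0)
})

test_that("an angle sweep at zero rotation reports near-zero error", {
  setup <- default_setup()
  reports <- sweep_angles(setup, 0, pitch = 5)
  expect_length(reports, 1L)
  expect_lt(reports[[1]]$max_mm, 0.02)
  expect_identical(sweep_angles(setup, numeric(0)), list())
})
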