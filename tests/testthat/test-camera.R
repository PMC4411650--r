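test_that("pinhole projection follows the calibration model", {
  cam <- camera_intrinsics(1000, 1000, 320, 240, width = 640, height = 480)
  expect_equal(project_points(c(10, -5, 100), cam),
               cbind(u = 420, v = 190))
  # any point on the optical axis hits the principal point
  for (z in c(1, 50, 1000))
    expect_equal(unname(project_points(c(0, 0, z), cam)),
                 matrix(c(320, 240), 1))
  # projection is scale-invariant along the viewing ray
  set.seed(7)
  p <- cbind(runif(20, -30, 30), runif(20, -30, 30), runif(20, 50, 300))
  for (s in c(0.5, 2, 7.3))
    expect_equal(project_points(s * p, cam), project_points(p, cam),
                 tolerance = 1e-12)
  expect_error(project_points(c(1, 1, 0), cam), class = "pv_behind_camera")
  expect_error(project_points(c(1, 1, -5), cam), class = "pv_behind_camera")
})

test_that("back-projection inverts projection to machine precision", {
  cam <- camera_intrinsics(800, 780, 315.5, 242.1, width = 640, height = 480)
  expect_equal(unname(backproject_pixels(c(315.5, 242.1), 77, cam)),
               matrix(c(0, 0, 77), 1))
  set.seed(11)
  px <- cbind(runif(100, 0, 639), runif(100, 0, 479))
  z <- runif(100, 1, 1000)
  rt <- project_points(backproject_pixels(px, z, cam), cam)
  expect_lt(max(abs(rt - px)), 1e-9)
  expect_error(backproject_pixels(c(10, 10), 0, cam))
  expect_error(backproject_pixels(c(10, 10), -3, cam))
})

test_that("undistortion with zero coefficients is a bit-exact identity", {
  cam <- camera_intrinsics(500, 500, 32, 24, width = 64, height = 48)
  set.seed(3)
  img <- matrix(runif(48 * 64), 48, 64)
  expect_identical(undistort_image(img, cam), img)
  rgb <- array(runif(48 * 64 * 3), dim = c(48, 64, 3))
  expect_identical(undistort_image(rgb, cam), rgb)
})

test_that("undistortion removes a known radial distortion", {
  cam <- camera_intrinsics(800, 800, 320, 240, dist = c(0.1, 0, 0, 0, 0),
                           width = 640, height = 480)
  # Synthesize the distorted observation of two coordinate-ramp scenes:
  # a distorted image O satisfies O(q) = I(distort^{-1}(q)).
  w <- cam$width; h <- cam$height
  q <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
  ideal_pos <- invert_distortion(q, cam)
  ramp_u <- matrix(ideal_pos[, 1] / (w - 1), h, w)
  ramp_v <- matrix(ideal_pos[, 2] / (h - 1), h, w)
  rec_u <- undistort_image(ramp_u, cam) * (w - 1)
  rec_v <- undistort_image(ramp_v, cam) * (h - 1)
  # per-pixel displacement between recovered and true pixel coordinates,
  # over the central 80% of the frame
  uu <- matrix(rep(0:(w - 1), each = h), h, w)
  vv <- matrix(rep(0:(h - 1), times = w), h, w)
  central <- uu >= 0.1 * w & uu <= 0.9 * w & vv >= 0.1 * h & vv <= 0.9 * h
  disp <- sqrt((rec_u - uu)^2 + (rec_v - vv)^2)
  expect_lt(max(disp[central]), 0.5)
  expect_lt(mean(disp[central]), 0.05)
})

test_that("undistortion rejects images of the wrong size", {
  cam <- camera_intrinsics(500, 500, 32, 24, width = 64, height = 48)
  expect_error(undistort_image(matrix(0, 48, 63), cam),
               class = "pv_bad_input")
  expect_error(undistort_image(matrix(0, 10, 64), cam),
               class = "pv_bad_input")
})

test_that("calibration files round-trip through JSON", {
  cam <- camera_intrinsics(812.3, 790.1, 321.7, 239.2,
                           dist = c(0.05, -0.01, 1e-4, -2e-4, 0.001),
                           width = 640, height = 480)
  f <- tempfile(fileext = ".json")
  write_calibration(cam, f)
  cam2 <- read_calibration(f)
  expect_equal(cam2, cam)
  expect_error(read_calibration(tempfile()), class = "pv_missing_input")
})

test_that("intrinsics constructor enforces its invariants", {
  expect_error(camera_intrinsics(-1, 800, 320, 240, width = 640, height = 480))
  expect_error(camera_intrinsics(800, 800, 700, 240, width = 640, height = 480))
  expect_error(camera_intrinsics(800, 800, 320, 240, dist = 1:3,
                                 width = 640, height = 480))
})
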