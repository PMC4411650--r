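test_that("pivot-centered transforms are rigid with the pivot fixed", {
  piv <- pivot_pose(c(0, 0, 120))
  pts <- depth_point_set(cbind(c(10, 20, 30), c(10, 20, 30)),
                         cbind(c(0, 5, -5), c(0, 2, -2), c(110, 117, 125)),
                         64, 64)
  # identity rotation returns the input exactly
  t0 <- transform_points(pts, c(0, 0, 0), piv)
  expect_identical(t0$points, pts$points)
  expect_identical(t0$pixels, pts$pixels)
  # hand-computed quarter-turn about the pivot
  one <- depth_point_set(cbind(5, 5), cbind(0, 0, 110), 64, 64)
  r <- transform_points(one, c(90, 0, 0), piv)
  expect_equal(unname(r$points), matrix(c(0, 10, 120), 1), tolerance = 1e-12)
  # the pivot point itself never moves
  pivpt <- depth_point_set(cbind(1, 1), cbind(0, 0, 120), 64, 64)
  for (th in list(c(33, 0, 0), c(10, -40, 5), c(0, 0, 90))) {
    expect_equal(unname(transform_points(pivpt, th, piv)$points),
                 matrix(c(0, 0, 120), 1), tolerance = 1e-9)
  }
  # rigidity: pairwise distances preserved
  set.seed(21)
  P <- cbind(runif(40, -20, 20), runif(40, -20, 20), runif(40, 90, 150))
  big <- depth_point_set(cbind(seq_len(40), seq_len(40)), P, 64, 64)
  tb <- transform_points(big, c(12, -7, 31), piv)
  expect_lt(max(abs(dist(tb$points) - dist(P))), 1e-9)
  # inverse transform restores the original points
  back <- transform_points(tb, c(12, -7, 31), piv, inverse = TRUE)
  expect_lt(max(abs(back$points - P)), 1e-9)
})

test_that("a rotation that puts all points behind the camera errors", {
  pts <- depth_point_set(cbind(c(1, 2, 3), c(1, 2, 3)),
                         cbind(0, 0, c(100, 110, 120)), 64, 64)
  expect_error(transform_points(pts, c(180, 0, 0), pivot_pose(c(0, 0, 0))),
               class = "pv_empty_geometry")
})

test_that("reprojection restores the constructed pixels at zero rotation", {
  setup <- default_setup()
  grid <- depth_grid(5)
  proj <- reproject(transform_points(grid, c(0, 0, 0), setup$pivot),
                    setup$cam)
  expect_lt(max(abs(proj$up - proj$u)), 1e-6)
  expect_lt(max(abs(proj$vp - proj$v)), 1e-6)
  # a point on the optical axis projects to the principal point
  ax <- depth_point_set(cbind(5, 5), cbind(0, 0, 100), 64, 64)
  pr <- reproject(ax, setup$cam)
  expect_equal(c(pr$up, pr$vp), c(setup$cam$u0, setup$cam$v0))
})

test_that("Delaunay meshing handles canonical and degenerate inputs", {
  tri1 <- build_mesh(cbind(c(0, 10, 5), c(0, 0, 8)))
  expect_equal(nrow(tri1$triangles), 1L)
  expect_setequal(as.vector(tri1$triangles), 1:3)
  # unit square: two triangles sharing one diagonal
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
  tri2 <- build_mesh(sq)
  expect_equal(nrow(tri2$triangles), 2L)
  shared <- intersect(tri2$triangles[1, ], tri2$triangles[2, ])
  expect_length(shared, 2L)
  expect_true(circumcircles_empty(sq, tri2$triangles))
  expect_error(build_mesh(cbind(c(0, 1), c(0, 1))),
               class = "pv_degenerate_geometry")
  expect_error(build_mesh(cbind(1:5, 2 * (1:5) + 3)),
               class = "pv_degenerate_geometry")
})

test_that("random triangulations satisfy the empty-circumcircle property", {
  set.seed(123)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    p <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    m <- build_mesh(p)
    expect_true(circumcircles_empty(p, m$triangles))
  }
})

test_that("rendering reproduces an affine intensity field exactly", {
  cam <- camera_intrinsics(400, 400, 40, 30, width = 80, height = 60)
  a <- 0.003; b <- 0.006; cc <- 0.05
  img <- outer(0:(cam$height - 1), 0:(cam$width - 1),
               function(v, u) a * u + b * v + cc)
  set.seed(17)
  px <- cbind(runif(40, 0, 79), runif(40, 0, 59))
  px <- rbind(px, c(0, 0), c(79, 0), c(0, 59), c(79, 59))
  pts <- depth_point_set(px, backproject_pixels(px, 100, cam),
                         cam$width, cam$height)
  wr <- warp_frame(img, pts, c(0, 0, 0), pivot_pose(c(0, 0, 100)), cam)
  uu <- matrix(rep(0:(cam$width - 1), each = cam$height),
               cam$height, cam$width)
  vv <- matrix(rep(0:(cam$height - 1), times = cam$width),
               cam$height, cam$width)
  want <- a * uu + b * vv + cc
  expect_lt(max(abs(wr$image - want)[wr$validity]), 1e-9)
  # the full frame is inside the hull here, so everything is valid
  expect_true(all(wr$validity))
})

test_that("pixels outside the convex hull get the fill value and are invalid", {
  cam <- camera_intrinsics(400, 400, 40, 30, width = 80, height = 60)
  img <- matrix(0.5, 60, 80)
  px <- cbind(c(30, 50, 40), c(20, 20, 40))
  pts <- depth_point_set(px, backproject_pixels(px, 100, cam), 80, 60)
  wr <- warp_frame(img, pts, c(0, 0, 0), pivot_pose(c(0, 0, 100)), cam,
                   fill = 0.25)
  expect_false(wr$validity[1, 1])
  expect_equal(wr$image[1, 1], 0.25)
  expect_true(all(is.na(wr$source_map[, , 1][!wr$validity])))
  expect_true(all(is.finite(wr$source_map[, , 1][wr$validity])))
  # valid interpolated source positions stay within the source bounds
  expect_true(all(wr$source_map[, , 1][wr$validity] >= 0 &
                    wr$source_map[, , 1][wr$validity] <= 79))
})

test_that("warping at zero rotation reproduces the input on the mesh hull", {
  setup <- default_setup()
  wr <- warped_at(0, 5)
  d <- abs(wr$image - base_view())[wr$validity]
  expect_lt(max(d), 1e-9)
  expect_gt(mean(wr$validity), 0.2)
})

test_that("warp_frame guards degenerate inputs and stays deterministic", {
  setup <- default_setup()
  two <- depth_point_set(cbind(c(1, 2), c(1, 2)),
                         cbind(c(0, 1), c(0, 1), c(100, 100)),
                         setup$cam$width, setup$cam$height)
  expect_error(warp_frame(base_view(), two, c(0, 0, 0), setup$pivot,
                          setup$cam),
               class = "pv_degenerate_geometry")
  expect_error(warp_frame(matrix(0, 10, 10), depth_grid(5), c(0, 0, 0),
                          setup$pivot, setup$cam),
               class = "pv_bad_input")
  w1 <- warp_frame(base_view(), depth_grid(10), c(15, 0, 0), setup$pivot,
                   setup$cam)
  w2 <- warp_frame(base_view(), depth_grid(10), c(15, 0, 0), setup$pivot,
                   setup$cam)
  expect_identical(w1$image, w2$image)
  expect_identical(w1$mesh$triangles, w2$mesh$triangles)
})

test_that("coincident projections keep the nearer point", {
  cam <- camera_intrinsics(400, 400, 40, 30, width = 80, height = 60)
  # two depth points whose 3D positions both sit on the optical axis:
  # they project to the same output pixel; the nearer one must survive
  px <- cbind(c(10, 60, 20, 50), c(10, 10, 50, 50))
  P <- rbind(c(0, 0, 100), c(0, 0, 200),
             c(-5, 5, 100), c(5, 5, 100))
  pts <- depth_point_set(px, P, 80, 60)
  wr <- warp_frame(matrix(0.5, 60, 80), pts, c(0, 0, 0),
                   pivot_pose(c(0, 0, 100)), cam)
  at_pp <- which(abs(wr$proj$up - 40) < 1e-9 & abs(wr$proj$vp - 30) < 1e-9)
  expect_length(at_pp, 1L)
  expect_equal(wr$proj$z[at_pp], 100)
  expect_equal(c(wr$proj$u[at_pp], wr$proj$v[at_pp]), c(10, 10))
})
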