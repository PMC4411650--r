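---
title: "Pseudo-viewpoint alternation: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-viewpoint alternation: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoview)
```

## The problem

A rigid laparoscope constrained by a trocar has effectively three useful
degrees of freedom, so for a given region of interest there is essentially
one physical viewpoint available. When that viewpoint is nearly parallel to
the task surface — the common near-horizontal view in deep abdominal work —
depth perception collapses and precise tasks such as evenly spaced suturing
become markedly harder.

`pseudoview` implements a non-mechanical way out: keep the endoscope where
it is and *synthesize* the image a virtual camera would record after
rotating the viewpoint about a pivot placed at the region of interest. The
surgeon drives the virtual viewpoint with a small two-axis input device; the
image is re-rendered each frame.

## The model

**Camera.** A pinhole camera with Brown–Conrady lens distortion. After
undistortion (`undistort_image()`), a camera-frame point $(x, y, z)$ (mm,
$z > 0$ along the optical axis) projects to

$$u = \frac{f_x}{z}x + u_0, \qquad v = \frac{f_y}{z}y + v_0 .$$

Pixels are 0-based, $u$ = column (rightward), $v$ = row (downward), with
pixel centers at integer coordinates. The distortion vector is the usual
$(k_1, k_2, p_1, p_2, k_3)$; undistortion is exact inverse mapping through
the forward model with bilinear resampling, and is a bit-exact identity at
zero coefficients.

**Sparse depth.** Full 3D shape acquisition is outside this package's
scope. Instead a `depth_point_set` supplies pixel↔3D correspondences for a
*fraction* of pixels; the default synthetic scene samples the task surface
on a uniform grid of 5 mm pitch (0.2 points per mm). The pipeline is
explicitly designed to work from such sparse, even irregular, samplings.

**Viewpoint rotation.** For a commanded rotation
$\theta = (\theta_x, \theta_y, \theta_z)$ (degrees), every 3D point is
mapped rigidly by

$$X' = T(c)\, R_z(\theta_z) R_y(\theta_y) R_x(\theta_x)\, T(-c)\, X,$$

so the pivot $c$ — by default $(0, 0, 120)$ mm, the center of the scene of
interest — is the fixed point and the region of interest stays in view.
Right-handed rotations, composed in the fixed order $R_z R_y R_x$. Points
whose transformed depth falls below $10^{-6}$ mm are dropped before
reprojection (the configuration never rotates that far in practice, but the
guard keeps the projection well defined).

**Meshing and rendering.** The transformed points are reprojected with the
same intrinsics, Delaunay-triangulated in the output image plane
(`interp::tri.mesh`), and the output is rasterized triangle by triangle:
each covered output pixel receives the barycentric combination of the
triangle's three *source* pixel positions, and the color is sampled from
the source image at that continuous position (bilinear by default,
nearest-neighbor as an option). Positions, not colors, are interpolated —
colors are fetched once, at the interpolated position. Pixels outside the
convex hull of the projected points are flagged invalid and filled with a
configurable color (default black).

**Control law.** A raw two-axis input $q \in [-1,1]^2$ maps to an
increment $\Delta\theta = \Omega\,(q - q_0)$, where $q_0$ is the neutral
position averaged over the first 10 frames and

$$\Omega = \begin{pmatrix} \cos\gamma & \sin\gamma \\ \sin\gamma & \cos\gamma \\ 0 & 0 \end{pmatrix}.$$

The accumulated angle advances per axis by the sign-preserving power law
$\theta_i \leftarrow \theta_i + \alpha_i\,\mathrm{sign}(\Delta\theta_i)\,|\Delta\theta_i|^{r}$,
clamped to $\pm\theta_\text{limit}$. With $r = 1$ the response is linear;
the default $r = 2$ gives fine motion near neutral and fast sweeps at full
deflection. The default gain `rate_to_gain(28.2, 16)` makes a sustained
full deflection sweep 28.2°/s at a 16 Hz update rate; only the x axis is
driven by default ($\alpha_y = \alpha_z = 0$), matching a one-axis
elevate/lower controller. A reset action (`reset_viewpoint()`) returns to
the true camera view.

## Design choices where the design was open

* **Sign of the neutral offset.** The control law is implemented as
  $\Omega (q - q_0)$: $q_0$ is *defined* as the resting stick position and a
  resting stick must leave the viewpoint stationary. (Writing the offset
  with a $+$ and storing the negated mean is the same map; we store the mean.)
* **$\Omega$ as printed.** The default matrix is symmetric — both
  off-diagonal entries are $+\sin\gamma$ — rather than a rotation matrix.
  It is kept that way and is user-overridable by any 3×2 matrix.
* **Power law at negative input.** $\Delta\theta^r$ is undefined for
  negative increments at even $r$; the sign-preserving form
  $\mathrm{sign}(\cdot)\,|\cdot|^r$ keeps the law an odd function, which is
  what a direction-preserving sensitivity shaping requires. This also gives
  the exact $\pm$ symmetry property the tests check.
* **Pivot semantics.** The pivot-centered map is written so that the
  configured pivot point is the fixed point of the rotation (with a general
  4×4 pivot pose $G$, the map is $G R G^{-1}$, whose fixed point is $G$'s
  translation column). That is the only reading consistent with "the
  rotation center is at the center of the scene".
* **Angle limits.** $\pm 90°$ per axis by default; limits clearly exist in
  an interactive system but no specific value is canonical, so the bound is
  a parameter.
* **Occlusion.** The intended scenes are planar, so self-occlusion cannot
  occur; for non-planar point sets the renderer z-buffers per triangle on
  mean vertex depth (`zbuffer = TRUE` by default, switchable off for
  bit-reproducible planar runs). Two points projecting to the *same* pixel
  keep the nearer one.
* **Determinism and ties.** Projected points are sorted lexicographically
  (then by depth) before triangulation; output pixels exactly on shared
  triangle edges go to the lowest-index triangle; with z-buffering, equal
  depths also resolve to the lowest index. Warping the same inputs twice
  gives identical bits.

## The synthetic scene

All test data are generated in code (`make_default_setup()`):

* a 100 × 50 mm planar sheet carrying a dark central line (a simulated
  tissue cut) flanked by six pairs of dots at $b = \pm 5$ mm, 10 mm apart
  along the line, dot radius 1.5 mm — a planar suturing phantom;
* a camera whose optical axis meets the sheet at 20° elevation, 117 mm
  from the sheet center — the near-horizontal view that motivates the
  system; the pivot sits 120 mm down the optical axis;
* invented intrinsics $f_x = f_y = 800$ px, 640 × 480, no distortion. The
  real device's calibration is not public; every quantitative check is
  stated relative to whatever intrinsics are configured, so this choice
  only sets the scale of the rendered fixtures.

`render_phantom_view()` is the *ground-truth* renderer: each view ray is
intersected with the (rotated) sheet plane in closed form and the surface
pattern is evaluated there, with 4×4 supersampling per pixel so printed
marks can be localized to a small fraction of a pixel. It shares no code
with the mesh warp. `sample_depth_grid()` returns the uniform surface grid
with *exact* projections, and `make_input_trace()` produces deterministic
joystick traces (neutral / hold / pulse / continuous) for the control law.

What the synthetic scene deliberately does **not** emulate: tissue texture,
specular highlights, sensor noise, rolling shutter, non-planar anatomy, and
instruments above the surface. Passing tests therefore demonstrate the
geometric correctness of the pipeline on its stated assumptions — a planar
scene with known sparse depth — not robustness to real endoscopic imagery;
on real scenes the dominant error source would be the quality of the depth
input, which is exactly the term excluded here.

## Measuring rendering error

Because the scene is a plane, the exact pixel map of any pivot rotation is
a closed-form homography: back-project the source pixel onto the plane,
rotate rigidly, reproject (`homography_oracle()`; the tests additionally
verify it *is* an 8-DoF projective map by fitting on 4 points and checking
100 others). `rendering_error()` compares, per dot landmark,

* the dot's position in the warped image, localized as the
  intensity-weighted centroid of the connected dark component nearest the
  predicted position (`EBImage::bwlabel` for labelling), against
* the oracle-mapped position of the same landmark,

and reports the discrepancy both in pixels and in mm *on the task surface*
(both positions are back-projected through the virtual camera onto the
rotated plane and their 3D separation is taken). The surface metric is the
clinically meaningful one: it is the displacement a viewer would ascribe to
a feature on the tissue. `sweep_angles()` tracks the landmarks as measured
in the base view, so the small perspective bias between a dot's projected
center and its ellipse centroid cancels between the two views.

Numerical tolerances used throughout: triangle-interior tests at
$10^{-9}$, degenerate-triangle cutoff at $10^{-12}$ on twice the signed
area, depth cutoff $10^{-6}$ mm, z-buffer depth ties at $10^{-9}$ mm.
Degenerate inputs (fewer than 3 points, collinear points, a plane through
the camera center, a sheet edge-on in the field of view, all points behind
the camera) raise classed errors rather than producing images.

## Problem sizes used in the shipped checks

The packaged tests and the `scripts/acceptance.R` harness run, on the
default scene: the four-angle sweep $\theta_x \in \{5, 15, 25, 34\}°$ at
5 mm pitch (48 landmark measurements; the maximum surface error is the
headline number, bounded by 1.00 mm); an identity-warp check at
$\theta = 0$; a dense-mesh (1 mm pitch) comparison against the homography
at $\theta_x = 25°$ with a 0.5 px bound; a mesh-density convergence ladder
at pitches 10, 5, 2, 1 mm probed off the grid nodes through the
piecewise-affine warp map (`map_source_pixels()`), which must be monotone
non-increasing; 1,000-point brute-force rotation audits; 100 random
triangulations against a brute-force circumcircle check; and a
10,000-step random drive of the control law against its clamping and
symmetry invariants. These sizes keep the full suite under a couple of
minutes while leaving each measurement comfortably above numerical noise.

## A worked example

```{r example, eval = FALSE}
setup <- make_default_setup()
base  <- render_phantom_view(setup)           # the 20-degree base view
grid  <- sample_depth_grid(setup, pitch = 5)  # 203 sparse depth points

wr <- warp_frame(base, grid, theta = c(25, 0, 0), setup$pivot, setup$cam)
wr
#> warp_result: 640 x 480 image, 363 mesh triangles, 49.7% valid
#>   theta (deg): 25  0  0

om  <- homography_oracle(phantom_plane(setup), setup$cam, c(25, 0, 0),
                         setup$pivot)
rendering_error(wr, om, dot_landmarks(setup), setup, c(25, 0, 0))
#> error_report @ theta = (25, 0, 0) deg: 12 landmarks (0 excluded)
#>   surface error: max 0.0163 mm, mean 0.0061 mm, median 0.0044 mm
#>   image error:   max 0.0752 px, mean 0.0335 px
```

## Known limitations

* Everything off the depth-carrying surface (a needle, an instrument) is
  warped *as if* it lay on that surface; its rendering error grows with its
  height above the plane. Fixing this requires real depth input, which is
  out of scope.
* The renderer fills nothing outside the convex hull of the projected
  points; there is no inpainting.
* Binary PLY depth files are not read (ASCII PLY and CSV are).
* The rasterizer is vectorized base R; it renders a 640 × 480 frame from a
  few hundred depth points in well under a second, but it is not a
  real-time video path.
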