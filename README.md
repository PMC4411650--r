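# pseudoview

Pseudo-viewpoint alternation for endoscopic images: given one calibrated
camera frame and a sparse set of pixel↔3D correspondences, `pseudoview`
synthesizes the image a **virtual camera** would see after rotating the
viewpoint about a pivot placed in the scene — no extra degrees of freedom
at the endoscope tip, just image processing.

A trocar-constrained laparoscope offers essentially one physical viewpoint
per region of interest. When that view is nearly parallel to the task
surface, depth perception collapses. This package re-renders the scene
from an elevated virtual viewpoint instead, driven interactively through a
two-axis control law, so the operator gets an overlooking view while the
camera never moves. It is aimed at researchers in computer-assisted
intervention who want a reference implementation of the warp, its control
law, and a fully synthetic, ground-truth-known evaluation bench.

## The method

1. **Camera model** — pinhole with Brown–Conrady distortion. After
   undistortion, `u = fx·x/z + u0`, `v = fy·y/z + v0` (mm in, pixels out).
2. **Viewpoint rotation** — each depth point is mapped rigidly by
   `X' = T(c) Rz(θz) Ry(θy) Rx(θx) T(−c) X`, so the pivot `c` (default
   `(0, 0, 120)` mm, the scene center) is the fixed point.
3. **Reprojection + meshing** — the rotated points are reprojected and
   Delaunay-triangulated in the output plane.
4. **Barycentric rendering** — every output pixel inside a triangle gets
   the barycentric combination of the vertices' *source* pixel positions;
   the color is sampled there (bilinearly). Pixels outside the hull are
   flagged invalid.
5. **Control law** — raw input `q ∈ [−1,1]²` maps through
   `Δθ = Ω (q − q0)` and the sign-preserving power update
   `θ ← θ + α sign(Δθ)|Δθ|^r` (defaults: `r = 2`, 28.2°/s at full
   deflection, 16 Hz, x-axis only, auto-calibrated neutral from 10 frames).

Because the reference scene is a planar phantom, the exact warp is a
closed-form homography; the package measures its own rendering error
against it, in mm **on the task surface**.

## A worked example

```r
library(pseudoview)

setup <- make_default_setup()                 # 20 deg elevation, 117 mm standoff
base  <- render_phantom_view(setup)           # ground-truth base view
grid  <- sample_depth_grid(setup, pitch = 5)  # sparse depth: 0.2 points/mm

wr <- warp_frame(base, grid, theta = c(25, 0, 0), setup$pivot, setup$cam)
wr
#> warp_result: 640 x 480 image, 363 mesh triangles, 49.7% valid
#>   theta (deg): 25  0  0

om <- homography_oracle(phantom_plane(setup), setup$cam, c(25, 0, 0),
                        setup$pivot)
rendering_error(wr, om, dot_landmarks(setup), setup, c(25, 0, 0))
#> error_report @ theta = (25, 0, 0) deg: 12 landmarks (0 excluded)
#>   surface error: max 0.0163 mm, mean 0.0061 mm, median 0.0044 mm
#>   image error:   max 0.0752 px, mean 0.0335 px
```

The warped frame shows the phantom as seen from a viewpoint elevated a
further 25°; the report says every dot landmark in the synthesized image
sits within 0.017 mm (on the sheet) of where the exact planar homography
puts it — the interpolation cost of warping from a 5 mm depth grid.

## Command line

A thin wrapper over the same functions lives at `inst/cli/pseudoview.R`:

```sh
Rscript inst/cli/pseudoview.R simulate --out-dir fixture --pitch 5 --seed 1
Rscript inst/cli/pseudoview.R warp --image fixture/view.png \
    --calibration fixture/calib.json --depth-points fixture/depth_points.csv \
    --theta "25,0,0" --out-dir run1
Rscript inst/cli/pseudoview.R evaluate --out-dir eval1
Rscript inst/cli/pseudoview.R replay --trace trace.csv --out-dir replay1
```

Each run writes a `manifest.json` with parameters and input/output
checksums; errors exit nonzero with a JSON `{"category", "message"}` on
stderr.

## Scope

The package consumes calibration and depth points; it does not estimate
either (no chessboard detection, no stereo/structured-light 3D shape
acquisition). See the vignette
(`vignettes/pseudo-viewpoint-alternation.Rmd`) for the model details,
design decisions and known limitations.
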