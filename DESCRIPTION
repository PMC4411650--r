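Package: pseudoview
Title: Pseudo-Viewpoint Alternation for Endoscopic Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Synthesizes the view of a virtual camera rotated about a pivot in
    the scene from a single endoscopic frame and a sparse set of pixel-to-3D
    correspondences. Implements the pinhole camera model with lens
    undistortion, a joystick-style control law mapping two-axis input to
    incremental viewpoint rotations with a sign-preserving power gain, rigid
    rotation of sparse depth points about a scene pivot, Delaunay meshing of
    the reprojected points with barycentric image warping, a synthetic
    planar-phantom scene generator with an analytic ground-truth renderer,
    and a rendering-error metric measured in millimetres on the task surface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    interp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
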