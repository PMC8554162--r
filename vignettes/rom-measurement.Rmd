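---
title: "Measuring lower-limb joint range of motion from RGB-D marker tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lower-limb joint range of motion from RGB-D marker tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Rehabilitation robots must keep each joint of a patient's limb inside its
safe range of motion (ROM). The traditional instrument — a hand-held
goniometer — needs two clinicians, is subjective, and is especially awkward
for hip abduction/adduction in the coronal plane. `romvision` implements a
single-camera alternative: colored strip markers are fixed along the thigh
and calf (and one on the seat as the angular zero reference), an RGB-D
camera films the physician dragging the limb through its range, and the
per-frame marker geometry yields the hip and knee angles in the sagittal
plane and the hip angle in the coronal plane. The ROM is the max/min of each
angle trace.

## From pixels to camera coordinates

A color pixel $(u, v)$ with metric depth $z$ lifts to camera coordinates
through the intrinsic matrix $K = \begin{pmatrix} f_x & 0 & u_0 \\ 0 & f_y &
v_0 \\ 0 & 0 & 1\end{pmatrix}$:

$$X = z\,\frac{u - u_0}{f_x}, \qquad Y = z\,\frac{v - v_0}{f_y}, \qquad Z = z.$$

Lens distortion is the standard five-coefficient polynomial on the
normalized plane ($k_1, k_2, k_3$ radial, $p_1, p_2$ tangential). The
forward model is `apply_distortion()`; the measurement chain needs its
inverse, which `undistort()` computes by fixed-point iteration initialized
at the distorted point (50 iterations maximum, tolerance $10^{-9}$ on the
forward residual — the iteration contracts for the mild distortion of
consumer RGB-D optics, and a non-converged point raises an error rather
than passing through).

Depth and color come from different sensors, so each valid depth pixel is
back-projected through the depth intrinsics $K_d$, moved by the rigid
extrinsic $(R, t)$ into the color frame, and re-projected through $K_c$
(`register_depth_to_color()`). Two modeling choices matter here:

* **Occlusion.** When two depth points land on one color pixel the nearer Z
  wins. The source text of the method does not discuss collisions;
  nearest-wins is the physically correct rule.
* **Footprint, not point.** A depth pixel covers a block of color pixels
  whenever the color grid is finer (here $f_{x,c}/f_{x,d} \approx 1.23$), so
  its Z is written to every color pixel whose center falls inside the
  projected footprint, as production depth-to-color aligners do. Treating
  depth pixels as points leaves the registered map a sparse lattice; the
  lattice interacts with the one-pixel-per-bin sampling rule below and
  produced coherent line-direction biases up to ~0.6 degrees in testing.
  With equal intrinsics the footprint is exactly one pixel, so identity
  registration reproduces the input map.

## Marker extraction

Markers are segmented by Euclidean RGB distance to a reference color:
foreground iff $L = \lVert (R,G,B) - (R_1,G_1,B_1) \rVert \le T$ (the
boundary is inclusive; the default $T = 60$ on 0–255 channels tolerates a
color-noise standard deviation of 5 with indoor lighting). Foreground pixels
are grouped into 8-connected components (small ones discarded, default
minimum 40 pixels at 1280x720).

Three concurrent strips must be told apart. With per-role reference colors
(the generator's default: distinct seat/thigh/calf colors) each role is
segmented independently and its largest component taken. With a single
marker color, components are matched to the roles' previous-frame centroids
greedily by ascending distance, each component used once; a role whose best
match exceeds a gate (default 80 px) is reported missing for that frame.

**Median-depth sampling.** One representative pixel is selected per bin
along the component's dominant image-plane axis (default 32 bins; one bin
reproduces the one-pixel-per-marker reading). The representative's depth is
the bin's median depth — the method's only robustness device, which rejects
depth impulses. Two refinements proved necessary:

* *Median tolerance.* With continuous-valued depth the exact-median pixel is
  unique and sits at a random lateral position across the strip's width,
  which tilts the fitted line. All pixels within `median_tol` (default 2 mm
  — between the sensor's quantization and its noise) of the median are
  treated as sharing it, and the candidate nearest the bin's pixel centroid
  is selected, keeping the sample laterally centered.
* *Dense bin geometry.* Bin axes, edges and centroids are computed from the
  full component pixel set; only the depth statistics are restricted to
  pixels with valid registered depth. The valid set is shaped by the
  depth-sensor grid and must not steer the geometry.
* *Depth-consistency window.* Pixels whose depth deviates more than 0.20 m
  from the component's median depth are rejected before binning. Near strip
  edges, depth/color parallax lets background depth land on marker-colored
  pixels; the window rejects those samples on the physical ground that a
  marker lies on a limb of limited thickness.

## Geometry fitting and the angles

All fits are constrained total least squares solved in closed form from the
centered scatter matrix — deterministic and directly testable against SVD
oracles:

* **Plane** $ax + by + cz + d = 0$, $a^2+b^2+c^2 = 1$: the normal is the
  smallest-eigenvalue eigenvector.
* **3-D line** through the centroid: the largest-eigenvalue eigenvector.
* **2-D line** minimizing $\sum (a x_i - b y_i + c)^2$ with $a^2 + b^2 = 1$:
  the direction vector is $e = (b, a)$. (The minus sign follows the
  minimized polynomial; only that form makes $e$ a direction of the line.)

The stated sign constraints ($a > 0$, $l > 0$, $b \ge 0$) leave
measure-zero cases open; the package breaks ties lexicographically — the
first nonzero component of the constrained vector is made positive.

The sagittal working frame is built once per session from calibration
frames (a knee sweep with the hip fixed): the plane is fitted to the calf
samples pooled over all calibration frames without weighting, the x-axis is
the seat-line direction projected into the plane, the y-axis is the
in-plane perpendicular with non-negative camera-frame v component, and the
z-axis follows the right-hand rule. A seat line tilted more than 30 degrees
out of the plane is rejected as a configuration error. Per frame, marker
samples are lifted to 3-D, projected into this frame, and fitted as 2-D
lines; the hip angle is the signed angle from the seat direction $e_l$ to
the thigh direction $e_k$, the knee angle from $e_k$ to the calf direction
$e_x$. The sign is the sign of the 2-D cross product, with zero counted
positive, so results lie in $(-180, 180]$ degrees. With the direction
convention $b \ge 0$, individual marker lines must stay within $\pm 90$
degrees of the seat line; the anatomical bounds of a seated subject satisfy
this with margin.

For the coronal hip angle, a plane is fitted to the pooled thigh + calf
samples of each frame (the knee is bent so the two strips span a plane; the
fit is rejected as degenerate when the second in-plane singular value falls
below a tenth of the first, i.e. the strips are collinear). The first
frame's normal is the zero reference and the angle of frame $j$ is
$\theta_{kg,j} = \arccos |e_j \cdot e_1|$ — absolute, so the result lies in
$[0, 90]$ and the normal's arbitrary sign cancels.

## Series processing

Frames with a lost marker or insufficient depth are flagged and carry a
missing value — they are never silently dropped, and ROM is reported with
the valid-frame count. The coronal trace is smoothed by a median-average
filter (window 5 by default): per centered window, drop the single maximum
and minimum and average the rest; edges use the truncated window, and a
plain mean is used when fewer than three values remain. The filter
suppresses impulse spikes that would otherwise masquerade as ROM extremes,
and never amplifies a series' extremes. Sagittal channels are unfiltered by
default.

Peak detection uses turning-point logic: an extremum is committed once the
trace reverses away from it by at least the prominence (default 5 degrees),
giving strictly alternating maxima and minima; plateaus of exactly equal
values report their center sample; series endpoints are not peaks.
`compare_with_reference()` matches same-type peaks between the vision trace
and a reference trace greedily by nearest timestamp within a gate (default
1 s) and reports $\delta$ = vision − reference per pair and the maximum
$|\delta|$.

## The synthetic scene generator

The test instrument is a generator (`generate_session()`) that renders a
two-link articulated leg with seat/thigh/calf strips through the full
camera model. What it emulates:

* the kinematics: hip rotation in the sagittal plane, knee rotation from
  the thigh extension line, coronal tilt of the leg plane about the hip's
  anterior-posterior axis, with the straight-knee-collinear-markers
  convention;
* the imaging chain: separate depth-camera geometry (default 1024x768,
  $f = 730$) and color geometry (1280x720, $f = 900$, the study camera's
  resolution), a nonzero depth-to-color extrinsic (15 mm baseline, 0.5
  degree rotation) so registration cannot be stubbed out, optional lens
  distortion on either sensor, and area-integrating pixels (2x2 subpixel
  supersampling — hard-edged rasterization produces staircase edge
  artifacts that a physical sensor does not);
* the sensor errors: per-pixel Gaussian depth noise (default
  $\sigma = 5$ mm, the depth accuracy of the study camera at ~1 m), 1 mm
  depth quantization, optional dropout, and Gaussian 8-bit color noise
  (default $\sigma = 5$).

Geometry defaults, chosen once as a realistic seated adult filmed from the
side: thigh 0.40 m, calf 0.38 m, strips 0.25/0.20 m long and 0.02 m wide
offset 0.06 m toward the camera, camera 1.2 m from the sagittal plane
(within the protocol's 0.8–1.5 m), 10 fps. What it does **not** emulate:
soft-tissue motion of markers taped to skin, non-uniform lighting, motion
blur, cloth occlusion, and specular materials. Passing tests therefore
demonstrate the correctness of the geometry and estimation chain under
realistic sensor noise, not robustness to every clinical artifact.

All randomness flows through one seeded generator; a fixed seed reproduces
sessions bit for bit.

## Validation experiments and problem sizes

Two simulated replications of the precision experiment are built in:

* `replicate_sagittal_validation()`: thigh still, calf through 6 triangular
  0–90 degree knee cycles (12 frames per cycle at 10 fps — the apex falls
  exactly on a sample), full noise model; measured knee-angle peaks are
  compared to ground-truth peaks.
* `replicate_coronal_validation()`: knee bent 45 degrees, abduction through
  6 trapezoidal 0–40 degree cycles, median-average filtering on. The
  trapezoid's short dwell at each limit mirrors how a physician holds a limb
  at its end of range; it also means the filter sees a locally constant
  plateau and does not clip the peak, which a pure triangle sampled at 10
  fps would suffer by construction.

The test suite closes the loop noiselessly on 20 randomized sessions per
measurement mode (random trajectories inside the visibility-safe anatomical
ranges, random camera poses up to 6 degrees of rotation) with every
per-frame angle within 0.5 degrees of truth, and runs both noisy
replications on five seeds each. Session sizes (8-frame calibration sweeps,
9-frame random sessions, 73/133-frame validation sessions) are the
package's chosen balance between statistical coverage and a test suite that
runs in minutes.

## Known limitations

* The 2-D direction convention restricts marker lines to $\pm 90$ degrees
  from the seat line; supine protocols with hyperextension would need a
  different reference.
* Marker strips are assumed rigid and parallel to the limb plane; skin
  motion violates this and is not modeled.
* The coronal angle is unsigned (abduction and adduction fold together), as
  the absolute-value angle definition dictates.
* The ankle is not measured.
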