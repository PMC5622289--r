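---
title: "Methods: stitching microscope fields of view into virtual slides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stitching microscope fields of view into virtual slides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A consumer camera held against a microscope eyepiece can digitize a whole
slide: the operator sweeps the stage in a serpentine path while frames
(fields of view, FoVs) are captured with ~30% overlap, and software stitches
them into one navigable virtual slide. Two things make this harder than
ordinary panorama stitching. First, the capture loop must run live on weak
hardware, so tracking happens on downsampled frames and only rough pairwise
translations are available in real time; full-resolution stitching happens
afterwards. Second, the eyepiece-plus-phone-lens optics introduce an
unknown, setup-specific nonlinear distortion: until it is corrected, no
pure-translation placement of the FoVs is consistent, and stacking
uncorrected frames compounds the error with every FoV added.

`slidestitch` implements this two-stage pipeline — client-side tracking
with operator guidance, server-side selective keypoint matching, polynomial
self-calibration of the distortion, translation-graph layout, feathered
rendering and tiled export — plus a ground-truthed synthetic scan generator
used as the test substrate, and the slide-level diagnostic agreement
statistics used to evaluate such systems clinically.

## Keypoint detection

Detection is a SURF-family blob detector: box-filter approximations of the
Hessian at filter sizes $L \in \{9, 15, 21, 27, 39, 51\}$ px (one pyramid
layer per size, scale $s = 1.2L/9$), responses
$\det H = D_{xx}D_{yy} - (0.9\,D_{xy})^2$ computed from an integral image,
and 3×3×3 scale-space non-maximum suppression with quadratic sub-pixel
refinement clamped to half a sample.

Instead of one global response threshold, each layer gets its own: the
smallest threshold at or above an absolute floor ($10^{-4}$ for intensities
in $[0,1]$) such that at most $n_{hi}$ candidates survive; if fewer than
$n_{lo}$ candidates clear the floor, scarcity is accepted. The published
description of this adaptive scheme names the goal (bounded per-layer
keypoint counts without starving weak layers) but not the exact update
rule, so the count-band quantile rule here is a documented stand-in chosen
for determinism. Defaults $[n_{lo}, n_{hi}] = [50, 400]$ bound descriptor
matching cost per pair at roughly $400^2$ distance evaluations per layer.

Descriptors are upright 64-dimensional SURF-style vectors: a $20s \times
20s$ grid of Haar responses (wavelet size $2s$), Gaussian-weighted
($\sigma = 3.3s$), accumulated as $(\sum dx, \sum dy, \sum|dx|, \sum|dy|)$
over 4×4 subregions and unit-normalized. Upright is the default because a
microscope stage translates but does not rotate; a dominant-orientation
mode is available by flag. Keypoints whose support window leaves the image
are dropped rather than padded — this matters for sizing test worlds (see
below).

## Pairwise matching

The client matches brute-force: all cross-pair descriptor distances,
Lowe ratio test (0.8), then a robust single-translation consensus —
each tentative pair proposes $t = x_A - x_B$, hypotheses are scored by
inliers within a radius (3 px client, 5 px on uncorrected full-resolution
frames), the best consensus is refined as the inlier mean, and ties break
by lower rms then lexicographic order, so the estimate is deterministic.
At least 8 inliers are required; otherwise the pair is *lost*.

The server exploits the client's rough translation as a prior: for a
keypoint at $x$ in A, descriptor distances are evaluated only against
B-keypoints within a constant radius (default 64 full-resolution px) of
the predicted location $x - t_{prior}$; all other pairs are treated as
infinitely distant, which is implemented by never materializing them. The
number of distances actually computed is recorded, making the cost saving
a countable, hardware-independent quantity; on the synthetic suite the
mean saving exceeds 50%. If more than 90% of A's keypoints have no
candidate at all, the prior itself is declared bad (`lost_with_prior`).

Sign convention, used everywhere: $t_{AB}$ is the global position of B
minus that of A, and a slide point at local position $u$ in A appears at
$u - t_{AB}$ in B.

## The tracker and its guidance codes

Each incoming downsampled frame is matched against the last accepted one
and classified, in this order: too few keypoints (< 20) →
*touching boundary*; no reliable translation → *lost*; translation beyond
the overlap floor → *moving too fast*; otherwise accepted. Precedence is
boundary > lost > too-fast because matching is meaningless without
keypoints and a translation must exist before its size can be judged.
Rejected frames never advance the reference, so the operator can recover
by moving back. The session starts on the first frame with enough
keypoints; an all-blank stream therefore yields an empty-session error
rather than a silent one-frame session.

The overlap floor is applied per axis — $|t_x| > 0.7\,W$ or $|t_y| >
0.7\,H$ — rather than against $\min(W, H)$: with 4:3 frames, a legitimate
along-row step at 30% overlap has $|t| = 0.7W > 0.7\min(W,H)$, and the
magnitude rule would reject every clean horizontal step. The per-axis form
preserves exactly the semantics the floor encodes (at least 30% overlap on
the axis of motion).

A mini-map is rasterized from the accepted FoV rectangles (default cell:
4 downsampled px); its marked area equals the rectangle union up to a
one-cell rim, and the cumulative position always equals the sum of link
translations exactly.

## Distortion self-calibration

In normalized FoV coordinates $z$ (origin at the image center, unit = half
the image diagonal, so the image fits the unit disk — a bounded domain
keeps the polynomial basis well-conditioned), the inverse-distortion map
is

$$P(z) = z + \sum_{2 \le p+q \le D} a_{pq}\, z_x^p z_y^q \quad
  \text{(separate coefficients per output axis)},$$

with zero constant term and identity linear part. This gauge fixing is
necessary: any affine component of $P$ can be absorbed into the per-pair
translations, so only the nonlinear part is identifiable, and fixing the
smallest possible constraint set gives a unique minimizer.

Fitting uses the phase-difference constraint — all matched pixel pairs of
one overlapping FoV pair share a single translation in corrected space:

$$\min_{a,\,t} \sum_{\text{pairs } j} \sum_{\text{matches } i}
  \bigl\lVert P(u_i) - P(v_i) - t_j \bigr\rVert^2 .$$

Because each $t_j$ enters linearly, it is eliminated in closed form by
(weighted) centering of each pair's residuals, leaving one linear
least-squares problem per axis in the coefficients. Robustness against
mismatches comes from iterating this solve with Huber reweighting
(tuning constant 1.345 on a MAD-based scale with a 0.25 px floor) until
the coefficient change falls below $10^{-8}$ or 25 iterations. A ridge
term $\lambda = 10^{-6}$ — scaled by the mean diagonal of the normal
matrix so it is unit-free — stabilizes the solve; the condition number is
reported, with a warning above $10^{10}$. One model is fitted per scan
session, never per FoV.

Default order is $D = 3$ (configurable 2–5). A Taylor argument says high
enough order approximates any smooth distortion, but it does not fix $D$;
three facts govern the choice:

* the standard radial lens model $P(z) = z\,(1 + k_1 r^2 + k_2 r^4)$ is
  degree 5; its $k_1$ part is exactly inside the $D=3$ family;
* the $D=3$ truncation residual of the $k_2$ part is a fixed fraction
  (~0.4% at $|k_2| = 0.02$) of the half-diagonal, i.e. below half a pixel
  for FoVs up to roughly 200 px half-diagonal and growing linearly beyond;
  the unrepresentable component leaks partly into the per-pair
  translations as a small (~0.3%) scale-like gauge, which a chain of links
  accumulates as global drift — invisible within the mosaic, visible
  against external ground truth;
* orders 4–5 add basis directions that sequential-chain match geometry
  (matches confined to narrow overlap bands, no loop closure) constrains
  poorly; fits can go wild outside the bands. High order is safe only
  with loop-closing links or broad match coverage, so it is not the
  default.

Images are corrected by inverse mapping: each output pixel position is
pulled back through $P^{-1}$ by Newton iteration on the polynomial
(analytic Jacobian, converged when the update falls below $10^{-12}$ in
normalized units), then the input is sampled bilinearly; out-of-domain or
non-converged pixels are flagged in a validity mask. Models whose Jacobian
determinant drops below $10^{-8}$ anywhere on the pixel grid are rejected
as non-physical, naming the offending location.

## Layout, rendering, export

Global placement minimizes $\sum_{links} \lVert p_b - p_a - t_{ab}
\rVert^2$ with the anchor (lowest-index) FoV at the origin — a per-axis
linear least squares on the translation graph solved by QR on the reduced
incidence matrix. Connectivity is checked first and the error lists the
components. On consistent inputs recovery is exact to $10^{-9}$; the
dedicated test cross-checks against dense normal equations.

Rendering places FoVs at positions rounded only at this final step
(layout itself stays sub-pixel) and blends overlaps by feathering: each
FoV's weight at a pixel is the chamfer distance to its nearest invalid
pixel or border, so seams fade linearly instead of cutting; cut seams
were rejected because residual photometric mismatch would imprint visible
lines. Pixels covered by no valid FoV are transparent in the mask. The
canvas is quantized to the 8-bit grid at render time so the tile export
round-trips bit-exactly.

Export is a DeepZoom-style tree: an XML descriptor plus one directory of
256-px PNG tiles (gray + alpha coverage) per level. Level 0 is full
resolution and level $L$ its $2^L$ box-downsample with ceil-half
dimensions (note this numbering is the reverse of the DeepZoom
convention, which counts up from a 1-px level; the descriptor records the
level count). Downsampling averages only valid children, and mean
intensity is conserved within half an intensity level per level.

## The synthetic world

The generator produces a histology-like slide — smooth illumination,
dark soft-edged elliptical "nuclei" (radius 5–10 px, ~100 per FoV),
a band-limited "stromal" texture (Gaussian noise bumps of ~6 px grain,
amplitude 0.05) and fine per-pixel speckle (0.02) — scanned along a
serpentine path with seeded stage jitter (σ = 1 px), through a radial
lens distortion, at two tiers (full resolution and block-averaged client
copies, ratio 2). The captured pixel at raw position $u$ shows the slide
at $pos + c + R\,P(u_n)$, so the configured $(k_1, k_2)$ are exactly the
inverse-distortion polynomial a perfect calibration recovers, and every
byte is reproducible from the seed.

Sizing was chosen once, on physical grounds: the 20s descriptor support
excludes a ~21 px margin at the finest client scale, so the 30%-overlap
band between client frames must be substantially wider than ~42 px — toy
client frames of 100–150 px cannot be tracked by any SURF-style front
end with full-size descriptors. Defaults are therefore FoV 480×360
(client 240×180), mirroring the ~3:1 ratio between real capture
resolution and the ~640 px client working copies of deployed systems.
The stromal texture exists for the same reason real tissue is trackable:
matchable structure everywhere, not only at nuclei.

Injected faults deterministically trigger each guidance code: `blank`
(constant frame → boundary warning), `blur` (defocus mush: coarse random
blobs uncorrelated with the slide → keypoints exist but nothing matches
→ lost) and `jump` (captured 75% of a FoV width away → beyond the 70%
floor → moving too fast). Fault frames are inserted into the stream
without advancing the path, so the following clean frame matches the last
accepted one.

What a green synthetic test does **not** establish: robustness to
photometric drift (vignetting, exposure), real tissue morphology, focus
gradients, rolling shutter, or chromatic effects — the generator has
none of these. It establishes the geometric core: detection,
prior-guided matching, distortion recovery within the stated polynomial
family, global layout and rendering fidelity against a known ground
truth.

## Diagnostic agreement statistics

Slide-level evaluation uses a three-way call per diagnosis: if any
critical region of interest was missed the slide is *low sensitivity*
(LSen); otherwise, if every region's pattern was read correctly it is
*accurate*, else *low specificity* (LSpe). Tables aggregate one rater ×
one modality with a sample-count-weighted average row that always equals
the column sums.

Two conventions are inferred from the published tables this package's
fixtures encode, and are therefore documented rather than derived:

* Display ratios round half up to two decimals, and cross-rater rates
  average the *displayed* ratios and round again — the only convention
  that reproduces all twelve published averaged rates (e.g. lung accuracy
  (0.43 + 0.57)/2 = 0.50, where exact-count averaging gives 0.48).
* The published per-category counts sum to 99 per rater (one smartphone
  lung scan and one scanner thyroid scan were missing), although the
  printed denominators say /31 and /28; the printed *ratios* match the
  real counts (9/30 = 0.30, not 9/31). The fixtures encode the real
  counts, and `tabulate_agreement()` divides by the records present; the
  printed average-row strings, which mix /99 and /100 arithmetic, are
  preserved verbatim in `inst/extdata/printed_averages.json`.

Scan effort normalizes as `minutes × 225 / area_mm²`, the time to cover
the reference 15 × 15 mm sample area.

## Known limitations

* Client tracking under distortion is biased by design (the overlap band
  lies where distortion is largest); its translations are priors only,
  and the sub-pixel link-accuracy guarantee applies to undistorted scans.
* $D \ge 4$ fits need loop-closing links; with sequential chains they
  can diverge outside the match bands (see above).
* Blending is purely geometric; no photometric gain compensation.
* Rendering is in-memory and desk-scale; the tiling logic is
  size-agnostic but no out-of-core path exists.
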