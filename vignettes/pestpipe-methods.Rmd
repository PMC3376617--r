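---
title: "Methods: segmentation, features, classifier and link protocol in pestpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, features, classifier and link protocol in pestpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestpipe)
```

pestpipe is a desk-scale re-implementation of a portable field pest
classifier: a device photographs a single trapped insect, separates it from
the background, reduces it to 13 shape and color numbers, classifies it
with a small neural network, and ships the image over an unreliable
wireless link in fixed-format frames. This vignette records the models,
the numerical conventions, and the design choices that were genuinely open,
so that a maintainer can see why the code is the way it is.

## Segmentation

An insect photograph is converted from RGB to HSV and thresholded on the
hue (H) channel: insect bodies occupy a hue band well separated from the
trap background, so a static band `[t_low, t_high)` on H, followed by
binarization, isolates candidate foreground. Denoising then keeps only the
largest connected region ("searching the maximum linked area"): small
hue-matched specks (debris, wings of other insects) are discarded because
they are smaller than the body.

Conventions and choices:

* Hue lives in `[0, 1)` and wraps; a band with `t_low > t_high` selects
  `h >= t_low | h < t_high`, which red-toned insects straddling hue 0 need.
* Connected components are found by an **iterative queue-based flood
  fill** (in C++), not recursion — identical output, no stack-depth hazard
  on large regions. Connectivity defaults to 8 (robust for thin legs and
  antennae), configurable to 4.
* Equal-sized largest regions are tied-broken toward the region whose
  first pixel comes earliest in row-major order. Any rule would do; this
  one is deterministic and testable.
* No published threshold exists for the field camera, so the band is a
  required configuration value. An optional `auto` mode bins H into 32
  bins, takes the two highest-count bins at circular distance at least 2
  as the foreground and background modes, cuts at the minimum-frequency
  valley between them, and keeps the side with less pixel mass (the insect
  is assumed smaller than the background). This heuristic is our
  construction — reproducible, but not a substitute for a calibrated band.
* Holes inside the body are **not** filled; denoising is exactly
  largest-region retention, nothing more.

## The 13 features

From the image and its mask the pipeline computes, in fixed order: nine
color moments, the eccentricity ratio, the sphericity, and two Hu
invariant moments.

**Color moments** (per channel, over the masked pixels only): mean
$E_i = \frac{1}{N}\sum_j p_{ij}$, population standard deviation
$\sigma_i = (\frac{1}{N}\sum_j (p_{ij}-E_i)^2)^{1/2}$, and skewness
$s_i = (\frac{1}{N}\sum_j (p_{ij}-E_i)^3)^{1/3}$. The cube root of a
negative third moment uses the **real signed root**
$\mathrm{sign}(x)|x|^{1/3}$ — skewness must be allowed to be negative, and
the principal complex root would be wrong. The channels are H, S, V of the
masked region: the segmentation pipeline already works in HSV, and the
features describe the target area, not the background. (RGB/whole-image
variants are available for experimentation.) Because H is treated as a
linear value, hues straddling the 0/1 wrap would average incorrectly; the
synthetic generator keeps body hues away from the wrap, and real
deployments with red-hued insects should rotate the hue origin first.

**Shape moments** are binary: computed over the coordinates of the mask's
1-pixels (pixel centers at 0-based integers, x = column, y = row), not
over intensities, because the region is binarized before geometric
features are extracted. Normalized central moments are
$\eta_{pq} = \mu_{pq} / \mu_{00}^{(p+q)/2+1}$, and the two Hu invariants
are $\varphi_1 = \eta_{20}+\eta_{02}$ and
$\varphi_2 = (\eta_{20}-\eta_{02})^2 + 4\eta_{11}^2$ — invariant to
translation, scale and rotation (exactly for lattice-preserving
rotations, within raster error otherwise).

**Eccentricity** is the semi-axis ratio $EC = p/q$, $p \ge q$, of the
momental ellipse — the ellipse with the region's second central moments;
$p,q = 2\sqrt{\lambda_{1,2}}$ with $\lambda$ the eigenvalues of the
coordinate covariance. The $p \ge q$ convention makes $EC \ge 1$ (the
ratio's orientation is otherwise arbitrary). A collinear region has
$\lambda_2 = 0$; it returns `Inf` by default, cappable via `max_cap`.
Single-pixel regions define $EC = SP = 1$ by convention.

**Sphericity** is $SP = r_i/r_c$, inscribed over circumscribed radius, 1
for a disc. $r_i$ is the maximum of the exact Euclidean distance
transform over region pixels (computed with the lower-envelope-of-parabolas
algorithm in C++; off-image counts as background so border-touching
regions stay finite). $r_c$ is the radius of the minimum enclosing circle
(Welzl's algorithm on the convex hull) of the region treated as a union of
**unit pixel squares**, i.e. fitted over the corner points of the hull
pixels. The corner convention matters: fitting centers instead biases
$r_c$ low by half a pixel diagonal, which for a 40x20 rectangle moves SP
3% off its analytic value $10/\sqrt{500}$; with corners the square and
rectangle values are exact. Discretization can still leave $r_i$ a few
tenths of a pixel above $r_c$ for near-circular regions, so SP is clamped
to `(0, 1]`, its documented range.

No worked feature vector is published for the original field data, so
absolute feature values are validated against analytic shapes (discs,
squares, rectangles, ellipses) and brute-force oracles (per-pixel moment
loops, exhaustive flood fill, exhaustive circle search), not against field
numbers.

## The classifier

A three-layer feedforward network trained by back-propagation (the general
delta rule). Features are first min-max normalized per column,
$x' = (x - \min_j)/(\max_j - \min_j)$; the bounds are fitted on the
**training set only** and reused at test time with clipping to `[0, 1]` —
fitting them on test data would leak. Constant columns map to 0.

The hidden width follows the rule of thumb $n_1 = \sqrt{n+m} + a$ with $a$
an experiential integer in 1..10; $\sqrt{19} \approx 4.36$ is not an
integer, so it is rounded to nearest before adding $a$, which reproduces
the reference 13-10-6 architecture at $a = 6$. Both layers use the
logistic sigmoid (the transfer function is otherwise unspecified);
targets are hard 0/1 one-hot by default with an optional 0.1/0.9 soft
encoding. Weights initialize uniformly in `[-0.5, 0.5]`; updates are
online (per-sample) in a freshly shuffled order per epoch; learning rate
0.1, at most 5,000 epochs, stopping early when the epoch MSE falls below
1e-3. All defaults are exposed in `train_config()`. Everything random is
driven by one seed, so identical seed + data give bit-identical weights —
the property that lets trained weights be frozen and ported to a device.
Training and inference stay in double precision throughout.

The key correctness oracle is not accuracy but gradients: analytic
backprop gradients are checked against central finite differences to
1e-6 on small random networks. Tie-breaks in prediction go to the lowest
class index.

## The link protocol

Image payloads travel in fixed 517-byte frames: head `0x1B 0x7E`, a
16-bit sequence number (big-endian — byte order was unspecified), 512
data bytes, end `0xFF`. The published format fixes 512 valid bytes per
frame and says nothing about a short tail, so the sender zero-pads the
last chunk and prepends a **length frame** (4-byte big-endian total
length, then zeros) — every frame stays format-identical and the receiver
can strip padding exactly. The length frame is an explicit extension, not
part of the original format. No checksum is added: the printed format has
none, and corruption surfaces through the erroneous-reply path instead.

Sending is stop-and-wait with one frame in flight: send, await reply; on
timeout resend the same frame; on an erroneous reply reset the connection
and resend the same frame; advance only on a correct reply. The simulator
represents the modem's replies as single bytes (`0x06` acknowledge,
`0x15` erroneous, silence = timeout) — a test convention, since the real
reply format is modem-specific. The channel double draws per-transmission
outcomes from its own seeded xorshift stream (drop probability, then
corrupt probability), deliberately independent of R's global RNG. Timeout
duration and retry limits were never published; the simulator exposes
`max_retries_before_reset` (default 5) and a per-frame attempt budget
(default 50) after which delivery fails cleanly.

## The synthetic study conditions

The original six-species field image collection (pest traps photographed
over a year) was never deposited, so the package carries a generator whose
images make every stage testable: one rotated filled ellipse (the body)
with per-pixel HSV noise on a uniform-hue background, plus up to a few
small noise blobs sharing the body's hue but disjoint from it. Bodies are
ellipses rather than photorealistic insects **on purpose**: every
geometric feature then has an analytic oracle, and the ground-truth mask
is the exact rasterization of the body.

Two regimes model two study conditions:

* **easy** — six classes with non-overlapping hue centers (0.06 to 0.63)
  and distinct axis ranges; per-pixel hue noise sd 0.01. Every class pair
  differs by at least 3 pooled standard deviations in some feature, and
  the end-to-end benchmark (segment, extract, train, predict) reaches at
  least 95% held-out accuracy at 70 training / 20 test images per class.
* **field_like** — the same six classes compressed onto hue centers 0.10
  to 0.40 at 0.06 spacing, with three sources of realistic variation:
  **per-individual color** (each insect draws its own hue center, sd
  0.03, and its own brightness, sd 0.08 — per-pixel noise alone cannot
  make classes overlap, because a mean over a thousand body pixels
  averages it away), **pose jitter** (free rotation), and **lighting
  jitter** (a global value-channel shift up to ±0.15, the published
  system's "field lighting conditions" reduced to one knob). Axis ranges
  overlap between neighbouring classes. Benchmarks use the reference
  sample sizes (70/69/72/70/75/76 training, 23/15/18/21/25/30 test per
  class) and land in the 0.70–0.92 accuracy band around the 82% field
  operating point. The overlap parameters were fixed once to sit
  mid-band; they are the package's model of field difficulty, not a fit
  to any dataset.

What passing these benchmarks does **not** show: robustness to textured
backgrounds, occlusion, multiple insects, specular highlights, or species
whose hue distributions are genuinely inseparable — the generator has
none of these. Canvas defaults are 96x128 pixels with semi-axes of 8–41
pixels, sized so the full benchmark (about 1,100 images end to end) runs
in well under a minute per regime on one CPU.

## Numerical notes and degenerate inputs

* All-background images raise a classed segmentation failure; empty masks
  raise invalid-input errors before any moment is computed.
* The distance transform is exact (squared Euclidean; no chamfer
  approximation), so inscribed radii carry no metric error.
* Welzl's minimum-enclosing-circle runs on the convex hull with a fixed
  deterministic pre-shuffle; its coverage tolerance is 1e-7 pixels.
* Model JSON stores doubles at 17 significant digits, the minimum that
  round-trips IEEE doubles bit-exactly.
* The frame layer treats payloads as opaque bytes; compressing the image
  (e.g. JPEG 2000) before packetizing is a caller-side concern.

## Limitations

Hue-linear color moments near the red wrap, single-target assumption,
no hole filling, and a classifier deliberately frozen at the reference
design (no momentum, regularization, or alternative architectures) — the
package reproduces a specific, small, portable design rather than the
state of the art.
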