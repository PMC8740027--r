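---
title: "Divergence-based mapping of focal activation sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence-based mapping of focal activation sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divmap)
```

## The problem

During atrial fibrillation (AF), localized *focal drivers* — sites that
activate the surrounding tissue centrifugally — are candidate ablation
targets. Multipolar mapping catheters (five-spline, PentaRay-like devices)
record a handful of bipolar electrograms simultaneously, from which one
local activation time (LAT) per site and beat can be annotated. `divmap`
turns those scattered space–time samples into a continuous picture of wave
propagation and a quantitative marker of focal activity, in three steps.

**1. Interpolation.** For each beat, the LATs $t_i$ at site positions
$X_i \in \mathbb{R}^2$ are interpolated by a polyharmonic radial basis
function expansion with Duchon's cubic kernel and a first-order polynomial
tail,

$$ f(X) \;=\; \sum_{i=1}^{N} \alpha_i\,\lVert X - X_i\rVert^3
   \;+\; \beta_1 + \beta_2 x + \beta_3 y, $$

subject to the interpolation conditions $f(X_i) = t_i$ and the side
constraints $\sum_i \alpha_i = \sum_i \alpha_i x_i = \sum_i \alpha_i y_i
= 0$. The combined saddle-point system is solved by a dense direct
factorization — at clinical $N \le$ a few tens of sites there is nothing to
be gained from iterative or fast-multipole machinery. The kernel needs no
shape parameter, and the polynomial tail gives *linear precision*: an
affine LAT field (a plane wave) is reproduced exactly, so its conduction
velocity has no method error. For conditioning, coordinates are centered
and scaled by the mean pairwise site distance before assembly and the
weights de-scaled afterwards; this is exact algebraically and matters only
because the cubic kernel spans a large dynamic range on millimetre
coordinates. Duplicate sites (closer than $10^{-6}$ mm) are rejected
rather than averaged, and a missing LAT simply drops that site from that
beat's fit.

**2. Velocity.** The interpolant is analytically differentiable, and the
wavefront propagates along $\nabla f$ with speed $1/\lVert\nabla f\rVert$:

$$ v \;=\; \frac{\nabla f}{\lVert\nabla f\rVert^2}, $$

evaluated in closed form at every node of an evaluation grid (1 mm/ms =
100 cm/s). Nodes where $\lVert\nabla f\rVert < 10^{-6}$ ms/mm are flagged
invalid rather than propagated as near-infinite speeds; such degeneracies
occur at extrema of $f$ — including the reconstructed focal origin itself.
By default maps are masked to the convex hull of the contributing sites,
because the cubic kernel extrapolates aggressively outside it.

**3. Divergence.** Focal sources are sources of the *normalized* velocity
field $\hat v = \nabla f / \lVert\nabla f\rVert$: normalization removes
speed so only the angular structure remains. The scalar field
$D = \nabla\cdot\hat v$ (units mm$^{-1}$) is positive at centrifugal
sources, negative along wavefront collision lines, and $\approx 0$ for
planar propagation. The focal-driver estimate is the global argmax of $D$
over valid nodes, optionally after node-wise averaging of per-beat maps.

## The two divergence estimators

`divergence_field()` offers two estimators, and the choice is a genuine
design decision rather than a numerical detail.

* `method = "grid"` (default) samples $\hat v$ on the grid and applies
  central differences. Because unit-vector components are bounded by 1,
  this estimator is bounded by $2/h$ ($h$ = grid spacing) and it *saturates*
  exactly where the direction field reverses in both axes within one cell —
  which is what happens at a focal source. On 0.2 mm cells a clean focal
  map peaks near $10\ \mathrm{mm}^{-1}$ with a surrounding median around
  $0.1\ \mathrm{mm}^{-1}$, and a collision line dips to roughly
  $-1/h$. The bound is what makes the argmax robust: annotation jitter
  creates spurious local extrema of $f$ near recording sites, where the
  *analytic* divergence grows like $1/\lVert\nabla f\rVert$ without limit
  and would dominate the map. Saturation caps those spikes at the same
  level as genuine sources, and beat-to-beat averaging then separates the
  persistent source from the wandering artifacts.

* `method = "analytic"` evaluates
  $D = \mathrm{tr}(H)/\lVert g\rVert - g^\top H g / \lVert g\rVert^{3}$
  from the exact gradient $g$ and Hessian $H$ of the interpolant. It is
  the right tool for verifying the derivative algebra (the test suite
  checks it against independent finite-difference oracles) and for smooth
  fields, e.g. confirming that an ideal focal reconstruction follows the
  $D = 1/r$ law of a unit radial field to within 2% beyond two grid
  spacings from the source.

We initially made the analytic estimator the default and found localization
under jitter *degraded* when averaging divergence maps across beats — the
opposite of the intended behaviour — precisely because of the unbounded
near-site spikes. With the grid estimator, 10-beat averaging behaves as it
should.

## The synthetic substrate

Validation needs dense ground truth, which clinical data cannot provide,
so `simulate_activation_field()` generates first-arrival-time fields on a
4 cm × 4 cm patch, down-sampled on a 200 × 200 cell-centred grid (0.2 mm
cells), for four canonical patterns:

| pattern | construction | default speed |
|---|---|---|
| `plane` | $t = \hat d \cdot X / c$ | 60.4 cm/s |
| `focal_homogeneous` | $t = \lVert X - s\rVert / c$ | 54.6 cm/s |
| `collision` | pointwise min of two opposing plane waves | 55.8 cm/s |
| `focal_heterogeneous` | eikonal first arrival over 8 angular sectors | 60 ± 13 cm/s sectors |

The default speeds are the realized conduction velocities of the
benchmark scenarios this generator emulates. The heterogeneous pattern
draws one speed per sector from a truncated Normal(60, 13) cm/s (floor
20 cm/s); with 8 sectors the expected realized field is about
60 ± 12.5 cm/s. Its arrival times solve the isotropic eikonal equation
$\lVert\nabla T\rVert = 1/F$ by *factored* fast marching (compiled, second
order in the multiplier): writing $T = u \cdot T_0$ with $T_0$ the exact
radial time of a reference homogeneous medium removes the point-source
singularity that makes plain upwind marching locally inaccurate; the
solver is verified against the closed-form radial solution to within 1%
beyond five grid spacings.

Activation times are quantized to a configurable time quantum. The default
is 0.1 ms, the temporal resolution of the excitable-substrate models whose
output the generator stands in for; setting 1 ms emulates annotation on
1 kHz electrograms, and 0 yields ideal continuous-time fields for analytic
tests. The plane-wave benchmark is the sensitive one here: at 0.1 ms the
reconstructed median speed is 60.40 cm/s with ~0.13% pointwise error,
whereas 1 ms quantization alone inflates the plane-wave error tenfold.

Two corruption models mirror what corrupts clinical recordings:
`remove_sites()` drops a random subset of sites (all beats alike), and
`add_jitter()` adds independent uniform annotation jitter expressed as a
fraction $\varepsilon$ of the 150 ms cycle length. The *amplitude
convention* is the full width of the uniform distribution — jitter is drawn
from $[-\varepsilon \cdot \mathrm{CL}/2,\, +\varepsilon \cdot
\mathrm{CL}/2]$. Both conventions are implemented; the full-width default
was fixed by calibrating against the package's stability benchmarks (the
half-width reading roughly doubles every noise-induced error and is far
outside their interquartile ranges), and it was not revisited afterwards.

What the generator deliberately does **not** emulate: membrane kinetics and
electrogram morphology, lattice-anisotropic wavefront roughness of cellular
automata, anatomical curvature, and rotors (the interpolant cannot
represent the phase discontinuity at a rotor core, a known limitation of
the method). Consequently the *noiseless* pointwise error floors of curved
patterns come out smaller here than on rougher substrates — reconstruction
of a clean analytic cone is easier than of a jagged one — while all
noise- and removal-driven results are comparable.

## The stability experiments

`run_removal_experiment()` and `run_noise_experiment()` reconstruct each
pattern through the 15-bipole layout (`pentaray_patch_layout()`) under
progressive corruption and compare with ground truth node-by-node on the
truth grid inside the convex hull of the available sites, reporting median
(IQR) over 100 repetitions of: estimated median CV, median absolute
pointwise speed error (%), and median absolute angle error (rad). The
catheter is patch-centred (source-centred for focal patterns) — the
deterministic zero-corruption rows imply a fixed placement. With
`n_beats > 1`, per-beat *speed magnitudes* are averaged node-wise for the
speed metrics and the node-wise *vector mean* provides directions for the
angle metric. The distinction matters: averaging full vectors under
direction noise systematically shrinks the mean vector, biasing speeds low
(by nearly a factor of two in error at 10% noise), whereas magnitudes
average without that shrinkage.

`run_localization_sweep()` mirrors the localization robustness experiment:
per repetition the catheter is placed uniformly at random (source inside
the swept disk, whole layout inside the patch, random rotation), the
recording corrupted, per-beat divergence maps computed and averaged, and
the argmax distance to the true source recorded. Accuracy is judged
against the chance-level threshold $r = R\sqrt{0.05}$, the radius whose
disk covers 5% of the swept area — 2.7 mm (13.5 cells) for the default
layout, which is why the default swept radius is $2.7/\sqrt{0.05} \approx
12.07$ mm with bipoles at radii proportional to 4, 8, 12 mm.

All stochastic drivers derive one sub-seed per repetition from a single
top-level seed (`derive_seeds()`), so tables are reproducible as a whole
and per repetition.

Problem sizes are chosen so the full benchmark set (100 repetitions per
condition on the 200 × 200 grid) runs in well under half an hour on one
core; the bundled test suite uses 10–25 repetitions where a direction, not
a benchmark value, is being checked.

## Activation annotation

`detect_activation_times()` implements barycenter annotation of bipolar
electrograms: band-pass 40–250 Hz, rectification, 20 Hz envelope, adaptive
threshold at a fraction (default 0.5) of an upper percentile of envelope
peak heights with a baseline-relative noise floor, refractory merging of
windows closer than 50 ms, and the envelope-weighted barycenter of each
window as its LAT. The barycenter is insensitive to amplitude scaling and
robust to fragmented morphologies, and it maps naturally to the bipole
midpoint position. These filter settings are conventional for atrial
electrograms, not dictated by the reconstruction method, and every one is
exposed as an argument. Ventricular far-field handling is out of scope;
the companion generator `synthesize_bipolar_egm()` therefore plants purely
atrial biphasic wavelets (optionally fragmented, with the energy
barycenter pinned to the true LAT) plus white noise at a configurable SNR.
On those fixtures, annotation is essentially perfect at 20 dB, matches
≥95% of activations within ±5 ms at 10 dB, and degrades gracefully below.
`beats_from_detections()` pools per-site detections and clusters them into
beats with a cycle-length hint (window ±40% of the hint), flagging
ambiguous alignments and dropping beats seen at fewer than 3 sites.

## Numerical choices and edge cases

* Fit failure (singular saddle-point system, condition number above
  $10^{14}$) raises a typed `divmap_fit_error`; experiment drivers count
  failures per condition instead of aborting.
* Collinear or near-duplicate site sets are input errors — the
  interpolation problem is underdetermined, and silently averaging
  duplicates would alter the data.
* Ties in the divergence argmax break to the first node in storage order
  (x varying fastest); no sub-grid refinement is attempted, consistent
  with judging localization in grid cells.
* The degeneracy threshold $10^{-6}$ ms/mm corresponds to a speed of
  $10^{8}$ cm/s; it exists to avoid dividing by zero, not to filter
  physiology. A node invalid in more than half of the beats stays invalid
  in beat-averaged maps.
* `locate_focal_source()` reports `d_max` but no significance cutoff: the
  benchmarks never calibrate one, so the decision "is there a source at
  all" is left to the caller (a planar map yields `d_max` near machine
  zero).

## Known limitations

Rotors and conduction block are out of scope: the interpolant is a sum of
continuous functions and cannot represent phase discontinuities, and
missing activations are dropped rather than modelled as block. Multi-source
detection would require replacing the global argmax with local-maxima
analysis plus a calibrated `d_max` threshold. The simulated patch is flat;
no geodesic correction is applied, so results transfer to curved anatomy
only locally.
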