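# divmap

Divergence-based localization of focal activation sources from
multielectrode cardiac mapping data.

## What it does, and for whom

During atrial fibrillation, *focal drivers* — sites that activate the
surrounding atrium centrifugally — are candidate ablation targets.
Multipolar catheters (five-spline, PentaRay-like) deliver a handful of
simultaneous bipolar electrograms, each yielding one local activation time
(LAT) per beat. `divmap` is aimed at cardiac electrophysiology researchers
and mapping-methods developers who want to turn those scattered LATs into
continuous activation maps, conduction-velocity (CV) vector fields and a
quantitative focal-source marker, and to study how robust that chain is to
the data corruptions seen clinically.

The method, per beat:

1. **Interpolation.** LATs `t_i` at site positions `X_i` are interpolated
   with a polyharmonic radial basis function expansion (Duchon's cubic
   kernel) plus a first-order polynomial:

   `f(X) = Σ α_i ||X − X_i||³ + β₁ + β₂x + β₃y`,

   with `f(X_i) = t_i` and the orthogonality constraints
   `Σα_i = Σα_i x_i = Σα_i y_i = 0`. The kernel needs no tuning parameter
   and the polynomial tail reproduces plane waves exactly.

2. **Velocity.** The wavefront moves along the LAT gradient with speed
   `1/||∇f||`: `v = ∇f / ||∇f||²`, evaluated analytically on a grid
   (reported in cm/s).

3. **Divergence.** The divergence `D = ∇·v̂` of the *normalized* field
   `v̂ = ∇f/||∇f||` is positive at centrifugal sources, negative along
   wavefront collision lines and ≈0 for planar propagation. The focal
   driver estimate is the global maximum of `D`, optionally after
   averaging maps over beats; a localization is called accurate when it
   falls within the chance-level radius `r = R√0.05` of the truth
   (2.7 mm for the default 12.07 mm swept radius).

The package also ships the validation apparatus: a tissue-patch simulator
for four canonical patterns (plane wave, focal source in homogeneous and
heterogeneous tissue — the latter via a compiled factored fast-marching
eikonal solver — and wavefront collision), corruption models (uniform LAT
jitter, random electrode loss), Monte-Carlo stability experiments, and a
barycenter-based LAT annotator for bipolar electrogram traces with a
synthetic electrogram generator for testing it.

## Worked example

Plant a focal source at the centre of a 4 cm tissue patch, map it with a
15-bipole catheter placed 2.8 mm off-source, corrupt the annotations with
5% jitter, and reconstruct:

```r
library(divmap)

lay   <- pentaray_patch_layout()                       # 15 bipoles, R = 12.07 mm
field <- simulate_activation_field(pattern_config("focal_homogeneous"))
rec   <- sample_multisite(field, lay, center = c(22, 19), n_beats = 3)
rec   <- add_jitter(rec, eps_fraction = 0.05, seed = 7)

model <- fit_interpolant(rec, beat = 1)
grid  <- field_grid(field, hull_of = rec$positions)

cv <- velocity_field(model, grid)
median_speed(cv)
#> [1] 52.80903

dv  <- divergence_field(model, grid)
loc <- locate_focal_source(dv)
assess_localization(loc, field$source,
                    localization_threshold(lay$swept_radius))
#> <localization_result> distance 2.14 mm (threshold 2.70 mm): accurate; d_max 8.39 /mm
```

The estimated median CV (52.8 cm/s) sits close to the configured
54.6 cm/s despite the jitter; the divergence map peaks at 8.4 mm⁻¹ — the
near-saturated signature of a source, against a background of ~0.1 mm⁻¹ —
and the argmax lands 2.1 mm from the planted source, inside the 2.7 mm
chance-level threshold. Against the dense ground truth, the reconstruction
has a median pointwise speed error of 24.5% and direction error of
0.19 rad at this noise level:

```r
pointwise_speed_error(cv, field)   # 24.54205  (%)
pointwise_angle_error(cv, field)   # 0.1879503 (rad)
```

Monte-Carlo robustness tables come from the experiment drivers, e.g.

```r
run_noise_experiment("focal_homogeneous", eps = c(0, 0.05, 0.10),
                     n_beats = c(1L, 10L), n_reps = 100L, seed = 1)
run_localization_sweep("homogeneous", axis = "noise", n_reps = 100L)
```

Command-style wrappers (`cmd_simulate()`, `cmd_map()`, `cmd_stability()`)
write CSV/JSON bundles with a reproducibility manifest; a thin CLI script
is installed at `inst/cli/divmap.R`.

## Scope

Rotor/phase-singularity tracking, conduction-block delineation,
ventricular far-field removal and 3-D/geodesic surfaces are out of scope;
see the methods vignette (`vignettes/divergence-mapping.Rmd`) for the
model, parameter and design rationale, and the known limitations.
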