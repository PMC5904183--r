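---
title: "Methods: quantifying the matrix-stiffness response of lymphatic endothelial cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the matrix-stiffness response of lymphatic endothelial cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffscape)
```

During early lymphatic development, venous lymphatic endothelial cell (LEC)
progenitors leave the cardinal vein and migrate into tissue that is roughly
an order of magnitude softer than the vessel wall. stiffscape implements the
three quantitative workhorses needed to study that transition: a probe-level
fold-change filter for exon-array transcriptomes (with siRNA-dependence
assessment and cross-stimulus comparison), Hertz-model analysis of AFM
force-indentation curves, and the standard image-quantification formulas.
Each comes with a synthetic-data generator carrying recorded ground truth,
so the whole pipeline is testable without any external download.

## Probe-level stiffness-response filter

Exon arrays measure each gene through several exon probe set IDs. Rather
than moderated per-gene statistics, the filter used here is deliberately
simple and fold-change-driven:

1. **Expression floor.** Probes whose mean log2 expression over the samples
   of the contrast is below 5 are considered not expressed and removed. The
   floor is applied per contrast, not over the whole file, because each
   stepwise analysis stands alone. Removal is strict (`< 5`); a probe
   averaging exactly 5 stays.
2. **Per-probe fold change.** Values are RMA-normalized log2 intensities,
   so the fold change is a difference of per-condition replicate means,
   `mean(soft) − mean(stiff)`. Taking condition means first and differencing
   afterwards equals the mean of paired differences for balanced designs; we
   state the order explicitly because "average log2 fold change" alone does
   not fix it.
3. **Gene rule.** A probe is regulated when `|log2FC| > 0.5` (strictly; 0.5
   log2 units is a 1.4-fold change). A gene is called up (down) when at
   least 3 probes are regulated in that direction, and its effect size is
   the average fold change over only those regulated probes. Genes
   qualifying in *both* directions — a signature of differential splice-variant
   expression — are flagged bidirectional and excluded from the final lists;
   their fraction among regulated genes is reported. We require ≥ 3 probes
   *per direction* for the bidirectional call (the other defensible reading,
   "any probes in both directions", is stricter on exclusion and can be
   explored by lowering `min_probes`).
4. **Knockdown dependence.** For every regulated gene, the *same* probe IDs
   that drove its call are re-extracted in the control-soft vs
   GATA2-siRNA-soft contrast and averaged. The gene is GATA2-dependent when
   that average exceeds 0.5 in absolute value, in either direction; a
   `concordant_reversal` flag additionally records whether the knockdown
   shift opposes the stiffness direction, preserving the stricter
   interpretation without enforcing it. Genes whose probes drop out of the
   knockdown contrast are reported as unassessable rather than silently
   lost.

The gene-level path (`apply_flat_filter()`) applies the floor and the 0.5
threshold per row with no minimum-probe rule; it is the right tool for
gene-level matrices such as the published static vs oscillatory-shear (OSS)
comparison, whose up/down sets are then intersected with the stiffness sets
by exact, case-sensitive identifier matching (`cross_stimulus_overlap()`;
supply an `id_map` when the two platforms use different identifiers — the
original cross-platform mapping is not documented, so it is a user input
here).

```{r genes}
sim <- simulate_probe_matrix(array_sim_config(
  n_genes = 300, effect_log2fc = 1, noise_sd = 0.1, seed = 1))
calls <- call_stiffness_genes(sim$matrix, "ctrl-stiff", "ctrl-soft")
table(calls$status)

kd <- probe_log2fc(filter_expressed(sim$matrix, 5, c("ctrl-soft", "kd-soft")),
                   "ctrl-soft", "kd-soft")
dep <- assess_gata2_dependence(calls, kd)
table(dependent = dep$dependent, direction = dep$stiffness_status)
```

### What the array simulator emulates — and what it does not

`simulate_probe_matrix()` draws log2 baselines of expressed probes from
N(7, 1) with a low-mean N(3, 0.7) component (10% of probes by default) so
the floor filter has real work to do, adds per-probe planted effects
N(1.0, 0.2) in the soft (or OSS) arm, and i.i.d. Gaussian replicate noise
(0.1 log2 units by default). The default layout mirrors the study design: 6
biological replicates per control condition and 2 per siRNA condition.
GATA2 dependence is simulated as complete effect abolition by default, with
`dependence_attenuation < 1` available for partial dependence, since real
knockdowns only "abrogate or reduce" regulation; 25% of planted genes are
dependent by default, in line with the reported proportions. Every regulated
gene is guaranteed at least one expressed effect-carrying probe so recorded
truth is always recoverable in principle.

Real arrays violate these assumptions in known ways the simulator does not
model: probe effects within a gene are correlated (shared hybridization
biology), noise is heteroskedastic in intensity, effects are not Gaussian,
and unexpressed probes show intensity-dependent background rather than a
clean second mode. Passing recovery tests therefore demonstrates that the
*filter logic* is correct and well-calibrated against its own model — not
that the thresholds are optimal for any particular array platform. The
magnitude distribution of true biological effects is likewise a convention
(N(1.0, 0.2)), not a measured quantity.

With 6+6 replicates at noise 0.05 the per-probe fold-change noise is about
0.03 log2 units, so planted effects of 1.0 are separated from the 0.5
threshold by many standard errors and sensitivity/specificity ≥ 0.95 is
expected; the dependence contrast has only 2+2 replicates (noise ≈ 0.05 per
fold change) but averages ≥ 3 probes, which keeps dependence accuracy
≥ 0.95. A null simulation (no planted effects, noise 0.2) yields well under
1% regulated genes: at that noise a single probe exceeds 0.5 with
probability ~10⁻⁵, and three simultaneous exceedances are essentially
impossible.

## AFM force curves and the pyramidal Hertz model

Tissue stiffness is measured by indenting vibratome sections with a square
pyramidal AFM tip. For a four-sided pyramid with face-to-axis half-angle
θ indenting an elastic half-space by δ,

$$F(\delta) \;=\; \frac{\tan\theta}{\sqrt 2}\;\frac{E}{1-\nu^2}\;\delta^2,$$

with E the effective Young's modulus and ν the Poisson ratio. In kPa, µm
and nN the prefactor needs no unit conversion (1 kPa µm² = 1 nN). Defaults:
θ = 25°, ν = 0.5 (incompressible soft tissue; the source measurements do
not state ν, so it is exposed as a parameter). "Edge angle" is not a
universal convention — some instruments quote the edge-to-axis angle — so
`angle_convention = "edge"` switches the prefactor to tan θ/2 rather than
guessing. A 10° cantilever-tilt correction (multiplicative 1/cos² tilt) is
available but off by default, since the form of the original correction is
not documented. Moduli are labeled *effective* throughout: the model assumes
a homogeneous, elastic, quasistatic contact, none of which embryonic tissue
satisfies exactly, so values support comparisons, not absolute mechanics.

Processing follows standard force-spectroscopy practice:

- **Sensitivity calibration** (`calibrate_sensitivity()`): on a rigid
  substrate the cantilever deflects by the full piezo travel, so the
  deflection sensitivity (nm/V) is the inverse slope of the linear contact
  segment, selected between 25% and 90% of the signal range and validated
  by R² ≥ 0.95.
- **Preprocessing** (`preprocess_curve()`): a linear baseline (offset +
  slope) is estimated on the non-contact region — initially the far 60% of
  the approach, then refined after a contact estimate obtained by a
  sustained 5σ threshold crossing followed by a walk-back to baseline
  level, iterating until the window stabilizes — and subtracted. Raw volts
  are converted to force via sensitivity × spring constant, and the
  tip-sample separation is corrected for the cantilever deflection.
- **Fitting** (`fit_hertz_pyramid()`): the contact point is a free
  parameter fitted jointly with E, seeded by the threshold estimate. For a
  candidate contact point the model `F = a + b·s + C·δ²` is linear in
  (a, b, C) and solved in closed form; the contact point is profiled over a
  101-point grid and refined by golden-section search. Fitting the residual
  baseline jointly is deliberate: any tilt left by preprocessing (e.g. when
  noise delays contact detection) would otherwise bias E upward by tens of
  percent, while the joint fit absorbs it exactly. A negative fitted
  prefactor is clamped to zero and the fit flagged non-converged, as are
  fits with fewer than 10 post-contact points; non-converged fits are
  counted as rejected in aggregation, never dropped silently.

Noiseless round trips recover E to better than 10⁻⁶ relative error across
0.1–100 kPa, and a brute-force grid search over (E, contact point) finds
the same optimum. `aggregate_region()` then reports per-region means and
standard errors over converged fits and the fold difference between two
regions; applied to the two measured tissue means (3.6 and 0.27 kPa) it
gives the ~13-fold vein-vs-tissue stiffness contrast, and ensembles of 50
noisy simulated ramps per region (5% of the 5 nN setpoint) recover that
fold within sampling error:

```{r afm}
set.seed(1)
mk <- function(E, region) hertz_fit_table(
  lapply(1:50, function(i) fit_simulated_curve(
    curve_sim_config(true_modulus_kPa = E, noise_sd_nN = 0.25,
                     contact_z_um = 2))), region)
aggregate_region(rbind(mk(3.6, "CV"), mk(0.27, "outside")),
                 fold = c("CV", "outside"))
```

The curve simulator writes force-mode curves in which the z axis already
plays the role of the tip-sample separation (the deflection-to-force
conversion is assumed applied upstream); raw-mode curves model the physical
split of piezo travel into indentation and deflection, so that calibration,
conversion and fitting can be exercised end to end.

## Image quantification

Three formulas from routine fluorescence quantification, computed on
intensity images with user-supplied (or simulated) label masks:

- **Corrected total cell fluorescence**:
  `CTCF = integrated density − area × mean background`, per labeled cell,
  with a manually chosen background mask (no automatic background detection
  — backgrounds were hand-selected in the original workflow). CTCF is
  invariant under global intensity offsets and linear under scaling, which
  the tests verify numerically.
- **Circularity**: `4π·area/perimeter²` — the standard shape descriptor; the
  measurement tool's built-in definition in the original workflow is not
  documented, so ours is stated, not inferred. The perimeter is measured on
  the marching-squares contour polygon simplified with a 0.8 px
  Douglas-Peucker tolerance; without simplification the digitization
  staircase inflates the perimeter of a radius-50 disc by ~6% and depresses
  its circularity to 0.89, while the simplified contour yields 0.98 for the
  disc, π/4 ± 1% for a raster square, and ellipse values within 2% of the
  analytic perimeter. Values are clipped to [0, 1.05]; single-pixel objects
  return 1 with a degenerate flag.
- **Nuclear/cytoplasmic split**: mean intensity over the (DAPI-derived)
  nuclear mask intersected with cell coverage, and over the remaining
  covered pixels; nuclear plus cytoplasmic pixel counts always equal the
  coverage count. The original 3D surface masking is reduced to 2D label
  masks on maximum-intensity projections — a documented simplification.
  The cell-coverage threshold is a required parameter, since the original
  value is unstated.
- **Object counting** (`count_objects()`): strict binarization, 8-connected
  component labeling, and a minimum-area filter, mirroring
  primary-object-identification nuclei counts; the label image is returned
  for audit.

The image simulator places non-overlapping elliptical cells with co-centred
nuclei (nucleus forced inside its cell), optional low-order harmonic
boundary roughness (which lowers circularity, emulating the distorted
nuclei of migrating LECs), and Gaussian intensity noise. It does not model
point-spread blur, shading, or touching cells — so segmentation quality is
out of scope by construction; the measures are tested on exact masks.

## The pipeline runner

`run_pipeline()` executes a stage list (simulate → call → dependence →
compare; simulate curves → fit → aggregate; simulate image → measure) from
one R list or YAML file, with a single seed for all randomness, and writes
a deterministic JSON report (byte-identical across runs apart from the
timestamp). A failing stage aborts the run with the stage named and leaves
a `FAILED` marker beside the partial report.
`inst/extdata/study_run.yaml` ships the configuration with the study's
standard parameters (floor 5, threshold 0.5, min_probes 3; ν = 0.5,
θ = 25°, 5 nN setpoint; 6/6 + 2/2 replicates).

## Numerical choices and problem sizes

Tolerances and sizes used by the test-suite and the acceptance script, all
chosen as desk-scale defaults: 200–400 simulated genes with 4–8 probes
each; 10 seeds per recovery and null experiment; 50 curves per region for
fold recovery (600 points per curve, 6 µm scan range inside the 1–14 µm
envelope); 101-point contact grid with 10⁻¹² golden-section tolerance;
contour simplification at 0.8 px. Strict inequalities are used at the floor
and at the fold-change threshold, mirroring the filter's wording; ties at
exactly 5 or exactly ±0.5 are retained and unregulated respectively.

## Known limitations

Reproducing the published array counts requires the deposited series
matrices; this package ships the parser (`read_series_matrix()`) and the
exact filter chain, but no expression data. The fold-change-only filter has
no variance moderation by design — genes with one aberrant replicate can
pass or fail on the mean alone. The Hertz fit assumes a single elastic
half-space per ramp; layered or adhesive responses (retract-segment
analysis, viscoelastic models) are out of scope. Circularity depends on
rasterization below ~10 px object radius, where the digitization slack
dominates.
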