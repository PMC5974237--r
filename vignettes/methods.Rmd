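---
title: "Models, parameters and design choices in microvox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in microvox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microvox)
```

This vignette documents the science inside the package: the models and
their assumptions, the tunable parameters with their units and defaults,
what the synthetic-data generator does and does not emulate, and the
numerical decisions taken where the methods literature leaves the design
open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. Phosphorescence lifetime oximetry

Oxygen quenches the phosphorescence of the intravascular/interstitial
probe, shortening its emission lifetime. We model the calibration in
Stern–Volmer form,

$$\frac{1}{\tau} = \frac{1}{\tau_0} + k_q \, \mathrm{pO_2},$$

with `sv_calibration()` defaults $\tau_0 = 60\ \mu s$ (zero-oxygen
lifetime) and $k_q$ chosen so that $\tau(160\ \mathrm{mmHg}) \approx 20\
\mu s$. **These are placeholders**: calibration constants for this probe
class at 37 °C / pH 7.2 are not published with the values needed here,
so both constants are plain arguments and every downstream function
accepts a custom calibration. What the package guarantees is the
machinery: the forward map and its inverse agree to $10^{-9}$ relative,
and `lifetime_to_po2()` refuses lifetimes above $\tau_0$ as unphysical.

Decay traces are averaged photon counts over a 275 µs laser-off window
following a 25 µs excitation gate, typically over 3000 cycles.
`fit_lifetime()` fits $A e^{-t/\tau} + B$ by nonlinear least squares.
The constant background $B$ is included deliberately: in vivo the
background signal grows with imaging depth, and omitting it biases
$\tau$ low. Starting values come from a log-linear regression on
background-subtracted counts; a derivative-free optimizer is the
fallback if the Gauss–Newton path fails. Fitted lifetimes outside
(1, 1000) µs are rejected rather than returned.

Vessel-center pO2 (`vessel_center_po2()`) fits a quadratic to a short
transverse line grid (10–15 points) and returns the fitted maximum,
clamped to the sampled range. If the fitted curvature is non-negative
(flat or upward-opening profile: no interior maximum), the maximum
sample is returned with a flag instead of an extrapolated vertex.
Per-vessel depth averages (`mean_vessel_po2()`) are unweighted means of
the per-depth centerline values over the first 150 µm, matching
acquisition in 30–40 µm depth steps.

## 2. Saturation, content, extraction

Hemoglobin saturation uses the Hill equation with mouse constants
$n = 2.59$, $P_{50} = 40.2$ mmHg (`oxygen_constants()`). Blood oxygen
content combines dissolved and bound terms,
$[\mathrm{O_2}] = \alpha\,\mathrm{pO_2} + 4\,\mathrm{Hct}\,C_{Hb}\,S\mathrm{O_2}$,
with $\alpha = 1.27\times10^{-3}$ µmol ml⁻¹ mmHg⁻¹ and $C_{Hb} = 5.3$
µmol Hb per ml RBC. The OEF standard deviation propagates the
saturation SDs assuming **independence** of arterial and venous values —
the published form of the error propagation is not available, and
independence is the natural default when the two means come from
disjoint vessel sets. The formula is checked in the tests against
brute-force Monte-Carlo propagation (10⁶ draws, 2% agreement).

## 3. The Krogh cylinder fit

The periarteriolar model assumes an infinite straight arteriole of
radius $R_{art}$ supplying a coaxial tissue cylinder of radius $R_t$
with spatially uniform net consumption OC (µmol ml⁻¹ min⁻¹; converted
to seconds internally since $\alpha$ and $D$ are per-second). The
analytic solution plateaus at $R_t$ with zero slope, and we extend it as
a constant beyond $R_t$.

Design choices:

* **$R_t$ is a free fit parameter**, not a graphical plateau reading.
  At $r = R_t$ the model derivative vanishes, so fitting $R_t$
  operationalizes "the distance at which the profile plateaus"
  reproducibly. Points beyond the candidate $R_t$ still constrain it
  through the constant extension.
* For fixed $R_t$ the model is **linear** in (OC, pO2_art), so
  `fit_krogh()` reduces the 3-parameter problem to a 1-D search over
  $R_t$: a 40-point grid over the bounds (default $[R_{art}+5, 300]$ µm)
  plus local refinement, with an exact linear solve at each candidate.
  This is deterministic, cannot be trapped by poor nonlinear starts, and
  a brute-force lattice never beats it by more than 1% RSS in the tests.
* Fits with $R_t$ within 0.5 µm of a bound are flagged and excluded by
  `oc_statistics()` (excluded counts are reported).
* Least squares is **unweighted**; no weighting scheme is published for
  this kind of profile and the grid noise is approximately homoscedastic.
* Identifiability: only OC/($\alpha D$) is constrained by the shape, so
  OC is only meaningful for stated $\alpha, D$; the scale-consistency
  test pins this down.

Because capillaries inside the cylinder also deliver oxygen, the fitted
OC is a *net* consumption — CMRO2 minus capillary supply per unit
volume — which is what makes `OC / CMRO2` an estimate of the arteriolar
supply share (`arteriolar_supply_fraction()`; CMRO2 per gram is
converted to per ml with brain density 1.05 g/ml).

## 4. Line-scan flowmetry

Space–time images are 100 points over a ~20 µm line at 800 Hz, analyzed
in 250 ms segments (200 lines). Perpendicular scans: the time-averaged
spatial profile is fitted with a Gaussian and the FWHM
($2\sqrt{2\ln 2}\,\sigma$) is the internal diameter. Longitudinal
scans: streak angle by a Radon-style search — shear the image at
candidate angles, maximize the variance of the projected profile
(coarse 2° sweep, fine 0.25° sweep, parabolic refinement). An
isotropy guard compares the best score against the same statistic on a
deterministically pixel-scrambled copy of the image (which preserves the
intensity distribution and bin-occupancy pattern but no structure); if
the streak signal does not beat that null by 3×, the image is rejected
as having no dominant angle rather than returning a random velocity.

Flux counting collapses the image to one dimension (time trace within
the lumen for perpendicular scans; the de-skewed streak coordinate for
longitudinal scans) and counts below-threshold runs separated by ≥ 2
samples. The threshold is mean − 1.5 SD as a default; when shadows are
so dense that this falls below the dark level itself (strongly bimodal
profile), the dark/bright midpoint is used. No counting rule is
published; these constants are arguments.

Hematocrit is `flux × V_RBC / flow` with $V_{RBC} = 55\ \mu m^3$, and
resistance per unit length is $128\,\eta/(\pi d^4)$ with the in-vitro
diameter- and hematocrit-dependent relative viscosity law of the Pries
tradition (normalized so $\eta_{rel}(d, 0) = 1$); the underlying
equations are cited rather than printed in the methods literature we
follow, so the law's constants live in code as one documented function
(`relative_viscosity()`). All coefficients of variation use the sample
(n−1) SD.

## 5. Velocity-volume flowmetry and CBF

En-face axial-velocity slices (~3.8 µm depth steps) are thresholded at
|v| > 0.5 mm/s; connected components of uniform sign with ≥ 4 voxels are
vessels (arterioles positive/downward, venules negative/upward). Axes
come from second moments (equivalent-ellipse convention, axis =
4√eigenvalue, with a voxel-footprint correction). Diameter = minor
axis; flow = projected area × mean projected velocity — an identity
that holds for any vessel tilt because the en-face flux of a tilted
cylinder is tilt-invariant; path velocity = projected velocity ×
(major/minor).

Two numerical points: (a) the threshold filter clips the slow rim of the
parabolic profile, removing a $(v_{thr}/v_{max})^2$ fraction of the
flow; `depth_profiles()` adds the closed-form rim correction
$A\,v_{thr}^2 / (2(v_{max}-v_{thr}))$, which is what brings
arteriovenous closure inside 2% on synthetic volumes. (b) the top
50 µm are excluded (pial vessels have mixed Doppler signs); totals are
averaged over 50–650 µm for regional means and over 50–100 µm for CBF,
where `CBF = flow / (area × 1.5 mm × 1.05 g/ml)`.

Capillary density from angiogram stacks: binarize each slice, apply a
binary median (majority) filter sized ~11 µm to erase sub-10 µm tubes,
and subtract the surviving large-vessel fraction from the total vascular
fraction; the 0–150 µm depth band is summarized. The deep-learning
segmentation used on real angiograms is out of scope; global-threshold
binarization is exact on synthetic stacks, and the density arithmetic is
implemented as described.

## 6. The synthetic cohort: what it emulates, what it does not

The generator's defaults *are* the stated world of the study the
package mirrors: group presets (`make_cohort_config()`) carry the
published group means — arteriolar pO2 94.7/86.9/75.0 mmHg, venular
62.9/58.1/49.9 mmHg, tissue 38.2/35.6/29.2 mmHg, CBF 1.7/2.3/1.9
ml/g/min for young/middle/old — and hypoxic pockets exist only in the
old preset, sized so that roughly 1% of sampled tissue points fall
below 5 mmHg (the published old-group figure). Quantities that are
plotted but not printed in the source material were chosen once as
field-realistic values and are documented in `R/synth-config.R`:
systemic hematocrit 0.45/0.44/0.40, capillary diameter 4.8/4.9/5.3 µm,
RBC speed 800/700/900 µm/s, flux 45/38/50 s⁻¹, speed CV
0.35/0.35/0.45 — preserving the published qualitative ordering (flux
and speed dip at middle age and rise in old age; diameter and speed
heterogeneity rise in old age; hematocrit falls after middle age).

Choices worth knowing when interpreting green tests:

* **RBC arrivals are a hard-core renewal process** (exponential gaps
  plus a dead time), not a bare Poisson process: cells cannot overlap in
  a single-file capillary, and non-overlapping shadows make "count the
  dark streaks" well-defined. The rate equals the requested flux. The
  generator's truth records the number of shadows actually rendered in
  each image — the same quantity a human counter would see — which can
  differ from rate × duration by edge effects, exactly as in a real
  kymograph.
* **Shadows are rectangles** of length 6 µm along flow, softened by a
  1-pixel Gaussian blur; no optics/PSF model, no photobleaching, no
  motion artifacts.
* **Tissue fields are forward-model composites**: the maximum over
  per-arteriole Krogh profiles, minus Gaussian venular sinks, with
  pockets imprinted as `min(baseline, floor + ramp)`, where the ramp is
  zero inside the pocket radius and rises quadratically
  (0.02 mmHg/µm²) outside it — continuous, with every in-radius point
  at the floor. With one arteriole and nothing else the sampled points
  lie exactly on the Krogh curve; this is the oracle the fitting tests
  rely on, and it also means tissue-field tests cannot detect
  model-misfit failure modes (real cortex is not a Krogh composite).
* **Velocity volumes are ideal parabolic cylinders** with axial
  projection handled exactly; no pulsatility, no noise floor structure,
  no shadowing under large vessels. When a flow target is given the
  layout assigns per-vessel flows first and derives radii from drawn
  peak velocities, so vessels never approach the detection threshold.
  Arteriovenous closure is enforced by construction — the closure test
  validates the *measurement chain*, not hemodynamics.
* **The coupled cohort** (`gen_coupled_cohort()`) drives every modality
  from one CMRO2 truth: venular pO2 is solved from the Fick relation at
  the preset CBF and hematocrit, the velocity volume carries exactly the
  preset CBF, and the periarteriolar field consumes exactly the chosen
  arteriolar share. Recovery tests therefore validate unit conversions
  and estimator consistency across modules, which is precisely what a
  desk-scale build can establish. They cannot validate the physiology.
* Raw OCT reconstruction (spectral shaping, dispersion compensation,
  Kasai autocorrelation) is out of scope; the pipeline starts at
  reconstructed velocity volumes.

## 7. Other numerical choices and degenerate inputs

* Hypoxic pockets: single-linkage clustering of sub-threshold points
  (`hclust`/`cutree` at the linkage radius, equal to brute-force
  union-find); default linkage radius 1.5× the max in-plane grid
  spacing; pocket extent = maximum pairwise member distance. No
  connectivity rule or size metric is published; these are documented
  defaults. With coarse plane spacing a physically single pocket can
  report as one component per plane — a sampling property, not a bug.
* Region classification is a disjoint, exhaustive partition with
  arteriole priority (near-arteriole < 100 µm; near-venule < 100 µm from
  a venule but ≥ 100 µm from any arteriole; capillary bed otherwise).
  Venular radial profiles exclude points within 100 µm of an arteriole.
* Distances are to the vessel **centerline**, not the lumen surface:
  radii (≤ 15 µm) are small against the 100 µm cutoffs, and centerline
  distance is unambiguous for crossing vessels.
* Reports use s.e.m. for group summaries and the star convention
  `*` p<0.05 … `*****` p<0.00001 with `#` for p<0.1. ANOVA + Tukey HSD
  are delegated to `stats::aov`/`stats::TukeyHSD`; the suite checks the
  F = t² two-group identity and the null type-I rate.
* Determinism: every generator is a pure function of (parameters, seed);
  derived seeds are produced by a fixed integer hash kept below 2³¹.
  Reports serialize doubles at 17 significant digits, so write → read →
  write round trips are byte-identical.
* Degenerate inputs fail loudly rather than silently: flat decay traces,
  uniform line-scan images, saturated images, upward-opening vessel
  profiles, volumes shallower than 100 µm, pocket centers outside the
  volume, overlapping vessels, capillary densities above 20%, and
  unknown config fields all raise typed errors with stage tags in the
  pipeline.

## 8. Known limitations

Desk-scale cohort sizes (8 vessels, 12 capillaries per group by
default) make group means noisier than the published cohorts (20–30
vessels, ~250 capillaries); `run_cohort_analysis()` exposes the sizes
as arguments. The calibration constants are placeholders (section 1).
The viscosity-law constants follow the in-vitro tradition and are not
validated here. Pocket statistics at 225-point grid resolution are
qualitative. None of the synthetic tests can establish that the models
describe real aging cortex — only that the estimators recover what the
models generate.
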