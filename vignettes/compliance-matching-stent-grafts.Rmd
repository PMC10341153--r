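---
title: "Modeling and optimizing compliance-matching stent-grafts"
author: "cmgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing compliance-matching stent-grafts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmgraft)
```

## The problem

Prosthetic aortic grafts made of woven PET are one to two orders of
magnitude stiffer than a healthy aorta. This *compliance mismatch*
suppresses the Windkessel function of the proximal aorta, raises pulse
wave velocity (PWV) and pulse pressure, and is implicated in long-term
cardiovascular morbidity after aortic replacement.

A compliance-matching (CM) stent-graft addresses this with a two-layer,
artery-like architecture: the stiff woven fabric (the collagen analogue)
is held circumferentially compressed — folded — by an outer, shape-set
superelastic nitinol z-stent (the elastin analogue). At physiological
pressure the folded fabric carries almost no hoop load, so the radial
response is governed by strut bending in the soft stent; the fabric
engages only at high pressure and then provides strength. The design
question is inverse: which stent geometry gives the assembly a target
aortic distensibility, `Da = (dA/dP)/Aref`, of about
`1.6e-3 /mmHg` at the 100 mmHg reference?

`cmgraft` implements the complete desk-scale workflow: constitutive
models and fitting, a reduced-order mechanical evaluator, the
Box-Behnken response-surface optimizer, the bench-data analysis
pipeline, and synthetic generators that stand in for the laboratory.

## Constitutive models

### Ogden fabric

The fabric is an isotropic, incompressible, third-order Ogden material.
**The energy convention matters**: we use

$$W = \sum_{i=1}^{3} \frac{2\mu_i}{\alpha_i^2}
  \left(\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i} +
        \lambda_3^{\alpha_i} - 3\right),$$

under which the ground-state shear modulus is $\sum_i \mu_i$ and the
uniaxial nominal stress is
$P(\lambda) = \sum_i (2\mu_i/\alpha_i)(\lambda^{\alpha_i-1} -
\lambda^{-\alpha_i/2-1})$. Fitted $(\mu_i, \alpha_i)$ values are
meaningless without the convention, so serialized parameter files carry
the tag `"ogden_2mu_over_alpha_sq"` and `read_material_json()` refuses
files tagged otherwise. In the one-dimensional membrane reduction the
fabric is treated as exactly incompressible; no volumetric penalty term
is carried.

`fit_ogden()` is a multi-start Levenberg-Marquardt least-squares fit
(cost tolerance `1e-10`): six fixed exponent patterns bracketing typical
strongly strain-stiffening fabric behavior, each rescaled so the
small-strain slope $3\sum\mu_i$ matches the data, with $\mu_i$ kept
positive on a log scale. Ogden fitting is notoriously multi-modal; what
the package guarantees (and tests) is recovery of the stress *curve*,
not uniqueness of the parameter vector.

The reference fabric parameters, `ogden_params(c(60, 30, 10), c(8, 2, -2))`
MPa (ground-state shear modulus 100 MPa for a 0.36 mm wall), are the
generating truth of the synthetic uniaxial fixture. They are plausible
for a woven PET graft wall but are stand-ins: no public parameter table
exists for the commercial fabric.

### Superelastic nitinol

The stent material is a one-dimensional flag-shaped (Auricchio-style)
superelastic model without plasticity: austenite elasticity `E_A` up to
the forward transformation start, a hardening transformation plateau
from `sigma_s_AS` to `sigma_f_AS` accumulating up to `eps_L` of
transformation strain, martensite elasticity `E_M` beyond, and reverse
transformation through the lower plateau on unloading, so that any
strain history that returns monotonically to zero ends at zero stress.
The elastic modulus mixes linearly with the martensite fraction. All
four plateau stresses shift linearly with temperature
(Clausius-Clapeyron slopes `C_AS`, `C_SA`), and the model is only valid
in the superelastic window between `A_f` and `M_d`.

Defaults (`nitinol_params()`): `E_A` 60 GPa, `E_M` 30 GPa, plateaus
400/500 and 200/100 MPa at 37 degC, `eps_L` 0.04, `C_AS` 6 MPa/degC.
`C_SA` is set to 4 MPa/degC and `A_f` to 12 degC *jointly*, so that the
reverse-finish plateau extrapolates to about zero at `A_f` and is still
positive at the 21 degC laboratory condition; a steeper reverse slope
would push the reverse plateau negative at room temperature, outside the
model's validity. These are engineering values for medical-grade tubing,
not a fit to a specific lot. A consequence of `C_AS != C_SA` is that the
hysteresis loop area grows slightly with temperature; the tests
therefore check the individual plateau shifts, not area invariance.

## The reduced-order evaluator

A full simulation of the assembly would resolve three stent rings with
hexahedral meshes, layer contact and an explicit solver. For a
desk-scale optimization loop the package instead solves an axisymmetric
two-layer membrane balance in which both layers share one internal
radius $R$:

$$P\,R + F_{\mathrm{stent}}(R) = T_{\mathrm{fabric}}(R),$$

with $P$ the intraluminal pressure (stored in mmHg, converted with
1 mmHg = 133.322 Pa), $F_{\mathrm{stent}}$ the outward restoring line
tension of the z-stent (positive below the shape-set radius $d/2$), and
$T_{\mathrm{fabric}}$ the hoop line tension of the fabric. Neglected by
construction: inter-layer friction (layers interact only through the
shared radius), fabric bulging between rings, suture points, and end
effects. These are fidelity limits, not tunables.

### Stent

Radial deformation of a z-stent is bending-dominated. Each z-period
contributes two struts of effective length `l_eff = l - 2r` (the apex
arcs stiffen the ends) acting as fixed-guided beams with second moment
`I = w t^3 / 12`, giving a per-ring radial stiffness proportional to
`n E_A I / l_eff^3`. The ring force is smeared into a line tension by
the axial ring pitch (zig-zag height plus spacing `s`), which is the
only role of `s` in this model. The strut *stress* estimate uses the
circumferential opening kinematics (tip deflection `pi dR / n`),
multiplied by an apex stress-concentration factor
`Kt = 1 + 0.5 sqrt(t/r)` — equal to 1.5 at the `t = r` reference and
overridable by a fixed number. When the nominal strut stress enters the
transformation plateau the restoring force follows the secant of the
monotone superelastic branch, so the stent softens smoothly instead of
switching modulus discontinuously. The force law is valid for
excursions within ±30% of `d/2` and errors beyond that band.

### Fabric

The folded fabric is slack until its engagement circumference
`C_engage = pi D_nominal / prestretch^kappa` is reached; beyond it the
tension is the plane-stress incompressible Ogden membrane value at hoop
stretch `2 pi R / C_engage`, with the current thickness
`h/(lambda_theta lambda_z)`. Longitudinal prestretch `lambda_z` shrinks
the engagement circumference through the exponent `kappa` (default 1,
an isochoric fold-geometry argument); this is a model choice validated
only directionally. The slack-to-taut transition is smoothed with the
C1 ramp `1 - exp(-((lambda-1)/w)^2)` over the engagement width `w`
(default 0.02, i.e. 2% hoop stretch): the pleated folds of a real graft
unfold gradually, and the smooth ramp keeps the root-finding stable. Five
percent beyond engagement the ramp is within 0.2% of one, so the closed-
form membrane solution is recovered.

The Ogden moduli soften linearly with temperature (default 1% per degC
above the 21 degC fit temperature, capped at 50%), a first-order account
of polymer softening. This is the only temperature channel that acts in
the right direction on the assembly: warmer fabric is softer, so the
engaged branch of the pressure-radius curve steepens with temperature,
as observed for both bare PET and CM grafts. Nitinol plateau shifts act
on the strut-stress branch selection but leave the austenitic stiffness
unchanged.

### Equilibrium and calibration

`equilibrium_radius()` solves the balance by bracketed root finding
(`uniroot`, tolerance `1e-9` mm) between 75% of `d/2` and an upper
bracket expanded until the residual changes sign; the residual is
strictly unimodal on this interval, so the root is unique. At zero
pressure with a slack fabric the solution is exactly `d/2`. The solver
is verified against a dense-grid force-balance search to `1e-6` mm on
randomly drawn assemblies.

The default assembly (`default_assembly()`) is a 24 mm stent
(`l` 12, `s` 2, `n` 12, `w` 0.35, `r` 0.5, `t` 0.35 mm) in a 28.8 mm
fabric: compression ratio 1/6, chosen once so that under the expected
implantation conditions (36 degC, 10% longitudinal prestretch) fiber
engagement begins just above the 100 mmHg reference pressure. This
placement reproduces the qualitative signature of the measured devices —
slack-stent-dominated distensibility around the reference, engagement-
limited distensibility at high pressure, and sensitivity of the engaged
branch to temperature and prestretch. It is slightly above the 10-15%
compression of the physical prototypes; the reduced-order model needs
the extra margin because it has no inter-ring bulge compliance.

## Hemodynamic metrics

`compliance_from_curve()` computes volume compliance `Cv = dV/dP`
(mL/mmHg), area compliance `Ca = dA/dP` (mm^2/mmHg, `A = pi R^2`) and
distensibility `Da = Ca/Aref` (1/mmHg) with centered 3-point finite
differences on the (possibly non-uniform) pressure grid and one-sided
differences at the ends; `Aref` comes from monotone (Fritsch-Carlson)
interpolation. Both normalizations of the pressure-resolved
distensibility are implemented and the caller chooses: `"reference"`
divides by the area at the reference pressure (100 mmHg by default),
`"pointwise"` by the local area; the scalar at the reference pressure is
the same either way. `moens_korteweg_pwv()` and
`pwv_distensibility_ratio()` provide the standard wall-property and
Bramwell-Hill conversions (blood density default 1050 kg/m^3).

## The bench pipeline

`distensibility_from_recording()` composes the analysis of a hydraulic-
circuit recording (1 kHz; pressure, pump flow, external diameter,
optional mid-span deflection):

1. **Filtering.** Order-4 Butterworth low-pass at 50 Hz, applied
   forward-backward so that no phase lag is introduced between pressure
   and diameter; ends are mirror-padded to suppress startup transients.
   The cut-off sits *at* the utility frequency, where a Butterworth
   magnitude is -3 dB, so roughly half the mains amplitude survives one
   notional pass; the zero-phase double application and the ensemble
   averaging over ten cycles remove the rest in practice. We keep the
   stated cut-off rather than move it.
2. **Segmentation.** Cycles are cut at upward midline crossings of the
   low-passed pressure after removing a linear drift. A 0.05-5 Hz
   band-pass would serve the same drift-proofing purpose, but its
   ~20 s low-frequency memory distorts the crossings of the final
   cycles — exactly the experimental ones — so the detrended-midline
   variant is used. Ten preconditioning plus ten experimental cycles are
   expected; only the experimental (last) cycles are analyzed, and only
   their loading (inflation) branches, since the protocol is
   stress-controlled inflation.
3. **Volume and the bending correction.** Pump flow is integrated
   (cumulative trapezoid) to volume. Because a pressurized graft with
   low axial rigidity bows between the supports like a beam fixed at
   both ends, the elongation adds spurious volume; with the fixed-fixed
   uniform-load shape `y(x) = w 16 x^2 (L-x)^2 / L^4` the bent length is
   the arc-length integral, evaluated by adaptive quadrature, and
   `A(t) (bent_length - span)` is subtracted.
4. **Distensibility.** The lumen area follows the volume route, anchored
   to the optically measured area at the reference pressure. Per-cycle
   loading branches are averaged onto a 1 mmHg grid (trimming 3% at the
   turning points); the scalar `Ca` at the reference uses a local-linear
   slope over a 15 mmHg window, which suppresses the noise amplification
   of sample-by-sample differentiation, while the pressure-resolved
   arrays use the centered differences above. Results are reported per
   cycle and as mean (SD).

Group comparisons use the paired t-test or Welch's t-test with
Holm-Bonferroni correction across a declared family (significance 0.05);
model-versus-measurement agreement is summarized by RMSE, OLS slope and
intercept, and Pearson's r. Latex-liner and circuit compliance are
assumed negligible (orders of magnitude away from the graft's) and no
correction term is applied.

## The optimizer

`optimize_graft()` reproduces the iterative design-of-experiments
strategy: a 6-factor Box-Behnken design — the canonical cyclic triple
blocks, 48 edge points plus a *single* center point, 49 runs per cycle —
is evaluated with the reduced-order model; a full quadratic response
surface (28 coefficients) is least-squares fitted to the objective
`|Da - Da_target|`; and the design box is translated to the surface
minimizer over the coded cube (projected Newton step safeguarded by
box-constrained quasi-Newton refinement) and shrunk by `gamma = 0.7`,
floored at 1% of each bound width. A single center point (rather than
replicated centers) keeps the cycle at the canonical 49 runs.

Iteration stops when the *mean evaluator response* over the 49 points of
consecutive cycles changes by less than 1% (relative); interpreting the
convergence statistic as the center-point response instead is available
via `mean_mode = "center"`. Multi-start centers (default 5) are a seeded
Latin hypercube over the feasible box; identical seeds give identical
traces. Failed evaluations beyond 20% of a cycle trigger one retry with
halved ranges, then the start is abandoned.

The default six factors are `{l, n, w, r, t, d}` — the screening step
(`main_effects_screen()`, a two-level full factorial up to 7 candidates
or a resolution-III fraction beyond) is available for other material
combinations. The circumferential step `n` is treated as continuous
during optimization (a homogenized z-period density); a manufacturable
design rounds it. The default target, `1.6e-3 /mmHg` at 100 mmHg under
36 degC and 10% prestretch, is the mean distensibility of healthy adult
aortas at the reference pressure; a band-averaged objective over a
pressure window is available through `make_graft_evaluator(band = )`.

## Synthetic data

The generators make every stage testable without hardware, and their
defaults are the study conditions: 50-200 mmHg stress-controlled cycles
at 0.3 Hz (valid range 0.2-0.5 Hz), 1 kHz sampling, ten preconditioning
plus ten experimental cycles, 50 Hz mains interference on the pressure
channel. Sensor noise magnitudes (pressure white noise SD 0.2 mmHg plus
a 0.5 mmHg mains sinusoid; diameter SD 0.01 mm) are engineering choices
— the instruments' true noise floors are unpublished. The pump flow is
derived from the ground-truth volume (including the beam-bending
elongation when enabled), so the pipeline's integration and bending
correction are genuinely exercised and invertible;
`constant_da_curve()` provides analytic truth curves with exactly
constant pointwise distensibility for recovery tests.

What the generator does *not* emulate: circuit fluid dynamics, trapped
air, liner and tubing compliance, optical-micrometer artifacts, and any
fabric viscoelasticity or yarn rearrangement. Passing recovery tests
therefore demonstrates correctness of the *analysis*, not robustness to
every laboratory artifact.

The physiological distensibility envelope shipped in
`inst/extdata/aortic_distensibility_envelope_synthetic.csv` is a smooth
synthetic reconstruction with literature-derived magnitudes (adult
thoracic aortas; distensibility of order 1e-3 to 5e-3 per mmHg,
decreasing with pressure). It is marked synthetic in its filename,
editable, and checked at load time for well-formedness; it is not
measured data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full workflow at
desk scale: 5 multi-starts with up to 30 cycles of 49 evaluations each;
equilibrium solves to `1e-9` mm on brackets expanded geometrically;
the solver cross-check against a three-pass dense-grid search on
randomly drawn assemblies; recovery tests on three synthetic recordings
of 20 cycles (about 67,000 samples) each. Degenerate inputs fail loudly:
non-positive stretches, non-uniform sampling, out-of-window
temperatures, pressures outside 0-250 mmHg, underdetermined fits and
rank-deficient response surfaces are all errors, not warnings.

## Known limitations

* The evaluator is a homogenized membrane balance; it cannot predict
  absolute strut stresses better than the beam-plus-concentration
  estimate, inter-ring bulge, kinking, or migration, and its
  compression-ratio calibration absorbs geometry it does not resolve.
* The fabric temperature channel is a linear softening law; the nitinol
  channel affects only branch selection. Temperature effects are
  therefore directional, not quantitative.
* The flag-shaped nitinol model is tension-oriented; mild compressive
  strains are treated as austenite-elastic.
* Anchor-stent design, endovascular crimping and axial bending of the
  graft are out of scope.
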