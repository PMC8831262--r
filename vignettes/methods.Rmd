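---
title: "Methods: wall shear stress to plaque composition, sector by sector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wall shear stress to plaque composition, sector by sector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearplaque)
```

## The problem

Advanced carotid plaques are compositionally heterogeneous around the vessel
circumference, and the local hemodynamic environment — summarized by the
time-averaged wall shear stress (TAWSS) and the oscillatory shear index
(OSI) — is a candidate driver of that heterogeneity. Testing the association
requires (i) WSS fields on the lumen surface, (ii) histological quantification
of plaque components on cross-sections of the excised plaque, (iii) a common
spatial frame in which the two can be compared at sub-section resolution, and
(iv) statistics that respect the strong between-patient differences in
absolute WSS levels. `shearplaque` implements that whole chain, together with
a synthetic-study generator whose ground truth is analytic, so every stage is
testable without patient data.

## Hemodynamic layer

**Womersley solution.** The inflow boundary condition is the classical
pulsatile solution for laminar flow in a rigid straight tube. We work in
flow-rate form: the waveform $Q(t)$ is decomposed into complex harmonics
$Q_n$, and for each harmonic the axial velocity is

$$u_n(r) = \frac{Q_n}{\pi R^2}\,
\frac{1 - J_0(\beta_n r/R)/J_0(\beta_n)}{1 - F_n},
\qquad
F_n = \frac{2 J_1(\beta_n)}{\beta_n J_0(\beta_n)},
\qquad \beta_n = i^{3/2}\alpha_n,$$

with Womersley number $\alpha_n = R\sqrt{\omega_n \rho/\mu}$. This form
integrates to $Q_n$ *exactly*, so flow conservation is a structural
invariant, not a numerical accident; the test suite still verifies it by
independent Simpson quadrature of the velocity profile (relative error
$\le 10^{-6}$). The signed wall shear is
$\tau_n = -(\mu Q_n/\pi R^3)(\beta_n^2/2)\,F_n/(1-F_n)$ and the steady
harmonic contributes the Poiseuille value $4\mu Q_0/\pi R^3$.

$J_0, J_1$ at the complex argument $i^{3/2}\alpha$ are computed by their
ascending power series. On this ray the result grows like
$e^{\alpha/\sqrt2}$, so cancellation is mild; we cap $\alpha \le 50$, which
keeps the precision loss below roughly seven digits and covers every
physiological carotid case (a 3 mm radius at 68 bpm gives $\alpha_1 \approx
4.4$, and the eighth harmonic $\approx 12.5$).

**Waveform scaling.** The inflow is scaled so the cycle-averaged wall shear
magnitude in the common carotid equals a 0.9 Pa setpoint. Because wall shear
is linear in flow and TAWSS is positively homogeneous, the factor is simply
`target / TAWSS(waveform)`; the implementation verifies the result by
recomputation and falls back to a bracketing root-finder only if the direct
factor misses the 0.001 Pa tolerance (it never should — the fallback guards
future non-linear extensions). We satisfy the stronger reading of the
setpoint: it is the full Womersley TAWSS, not the Poiseuille mean, that hits
0.9 Pa.

**Rheology.** The Carreau–Yasuda model is provided for documenting and
querying the shear-thinning viscosity used by CFD solvers. The analytic
Womersley layer is Newtonian by construction and uses the reference
viscosity `mu_ref` (default 3.5 mPa s); the Carreau–Yasuda parameters are
configuration with literature-typical defaults
($\mu_0 = 22$, $\mu_\infty = 2.2$ mPa s, $\lambda = 0.11$ s, $a = 0.644$,
$n = 0.392$), not measured constants.

**Outflow split.** The ICA/ECA flow split as a function of ICA stenosis
degree is not standardized; `split_outflow()` uses a configurable monotone
table defaulting to a 64/36 split below 50% stenosis, decreasing linearly to
zero at occlusion. Only monotonicity and conservation are contractual.

## WSS metrics

Per vertex, over one cycle sampled at times $t_i$:
$\mathrm{TAWSS} = \frac1T\int_0^T |\boldsymbol\tau_w|\,dt$ and
$\mathrm{OSI} = \frac12\bigl(1 - |\int_0^T \boldsymbol\tau_w\,dt| /
\int_0^T |\boldsymbol\tau_w|\,dt\bigr)$. Both integrals use the trapezoidal
rule with periodic wrap (the last interval closes the cycle), which is
spectrally accurate for band-limited signals on uniform grids. Metrics are
computed from the *vector* series, so directional oscillation registers in
the OSI even when the magnitude never vanishes. Vertices whose shear
magnitude integrates to zero get OSI 0 plus a `zero_shear` flag rather than
`NaN`, keeping downstream binning total.

## Co-localization

Each histology section has a frame: an axial position along the centerline,
a center (the registered centerline point), a normal, and an
`angular_reference` unit vector marking where sector 0 starts. The reference
is explicit because no convention exists for it; synthetic data sets it, and
real data must supply it from the registration. Vertices are selected in a
±0.3 mm axial window (projection: arclength of the nearest centerline
point), assigned to eight half-open 45° sectors counterclockwise about the
normal, and averaged per sector — unweighted vertex means by default, with
one-ring-area weighting available since the averaging convention of the
source protocol is not recorded. Every section always yields exactly 8
records; empty sectors carry a `no-coverage` exclusion rather than being
dropped, so the bookkeeping identity `included + excluded = total` holds by
construction.

## Histology quantification

Masks are integer class rasters (background / intima / NC / fibrin /
macrophage / artifact) with a lumen contour and the same sector frame.
Conventions that were genuinely open and are now fixed:

* **Fibrin nests inside the necrotic-core complex**: a fibrin pixel counts
  toward both fibrin and NC area (code precedence is explicit in
  `mask_class_codes()`).
* **CD68 exclusion**: macrophage area counts CD68-positive pixels only where
  they lie on plain intima — positivity on NC, fibrin or artifact pixels is
  removed, mirroring the stain-processing rule of the source protocol.
* **Cap thickness** has no published formula in the protocol we follow; we
  define it as the per-sector *minimum*, over 1° rays from the center, of
  the distance from the lumen-contour crossing to the first NC pixel.
  Minimum cap is the rupture-relevant quantity. Sectors without NC are
  missing (`NA`), and cap-thickness models drop them listwise.
* Sectoring uses the registered center, not the lumen centroid, so the WSS
  and histology frames coincide.

Artifact filtering is a threshold on the per-sector artifact pixel fraction
(default 0: any artifact excludes the sector, reason `histology-artifact`).

## Registration QC

The registration chain itself is out of scope; its quality metrics are not.
`dice_coefficient()` is the standard overlap; "average Hausdorff distance"
is ambiguous in the field, so `average_hausdorff()` returns the symmetric
average surface distance *and* the classical maximum, and the pipeline
reports the average variant. Contours are resampled at 0.05 mm (below
histology pixel scale) and distances are point-to-segment, not
point-to-vertex. `rigid_align()` is a plain Kabsch fit over cyclic-shift
correspondences (both orientations) with an identity guard, used to exercise
the metrics on perturbed synthetic contours.

## Statistics

Absolute WSS ranges differ strongly between patients, so all comparisons use
patient-specific tertiles: linear-interpolation percentiles at 1/3 and 2/3,
labels `low` strictly below the lower boundary, `high` at or above the
upper. Ties make the assignment degenerate and are flagged. The models are

* per metric: `outcome ~ 0 + tertile + (1 | patient)`, REML via `lme4`;
* combined: cell-means coding of the TAWSS×OSI grid with a patient random
  intercept; contrasts are all within-row and within-column cell pairs
  (adjacent *and* outer, so the low-TAWSS low-vs-high-OSI comparison the
  cap-thickness finding rests on is in the family), Bonferroni-adjusted over
  the emitted family.

Pairwise tertile contrasts use Wald z with Bonferroni m = 3; the
degrees-of-freedom convention behind the source protocol's p-values is
unstated, so Wald-z is used and documented, and the type-I error of the
whole procedure is verified by simulation (500 null replicates keep the
familywise rate within binomial error of 0.05). When the mixed fit is
degenerate — zero residual variance in noise-free synthetic data — a
fixed-effects fallback reports plain group means, flagged via `backend`.

## Synthetic data: what it emulates and what it does not

The generator is the package's stated world:

* **Geometry**: straight or cosine-bump stenotic tubes (throat radius
  $(1-d)R$), or an idealized planar-Y bifurcation; flow extensions of five
  local radii at inlet and outlets. No attempt at patient anatomy — the
  statistics, not the anatomy, are the acceptance surface.
* **WSS**: constant-radius rings carry the exact Womersley series (analytic
  ground truth, closure tested at $10^{-6}$); stenotic rings the
  quasi-steady $\tau \propto R(z)^{-3}$ scaling; a configurable
  recirculation zone downstream of the throat adds a reversing sinusoid to
  create the high-OSI pocket seen distal to stenoses. Waveforms are
  parametric (steady component + 2–4 harmonics, 68 bpm default) because the
  source waveform tables are not public; only the 0.9 Pa scaling contract
  is meaningful.
* **Per-patient scale**: after scaling to 0.9 Pa, each patient's waveform is
  multiplied by a factor drawn from `wss_scale_range` (default 0.6–1.8), so
  absolute TAWSS ranges differ between patients and patient-specific
  tertiles are genuinely required, not decorative.
* **Histology**: per sector, component areas are drawn as
  `group_mean(driver tertile) + patient intercept + noise`, clipped at zero,
  then painted as radial bands (NC behind a programmed cap, fibrin nested at
  the NC's deep edge, macrophages at the outer wall) at 0.05 mm pixels —
  sub-percent quantization for mm²-scale regions. Realized (quantized)
  areas are recorded as truth, and measurement closure is exact by
  construction. Default effects mirror the qualitative findings the
  statistics should detect (NC and macrophage area up with TAWSS / down
  with OSI, fibrin null, cap largest at low OSI) with mm²-scale magnitudes
  and moderate noise (e.g. NC: means 1.0/1.2/2.0 mm², patient SD 0.3,
  residual SD 0.5).

What a green test does **not** establish: realism of the rasters (no staining
appearance, no deformation artifacts beyond coded flags), anatomical realism
of the bifurcation, or correctness of any 3D Navier–Stokes solution — the
synthetic fields are analytic/quasi-steady stand-ins, not CFD.

Repeated statistical simulations (bias and type-I-error suites) use the
generator's outcome model directly at the bin level rather than re-painting
rasters each replicate; rasterization only adds one-pixel quantization, and
the raster path is itself closure-tested once per suite. This keeps the
200–500-replicate suites within minutes on one CPU.

## Numerical choices

* Periodic trapezoid for all cycle integrals; uniform sampling makes it the
  plain mean.
* Complex Bessel series truncation at relative term size $10^{-17}$;
  $\alpha \le 50$ guard.
* Sector intervals are half-open `[k·45°, (k+1)·45°)`; points exactly at the
  section center are an error, not bin 0.
* Tertile boundaries: `quantile(type = 7)`; `<` at the lower boundary, `≥`
  at the upper — deterministic tie behavior, all-ties flagged degenerate.
* Masks/meshes exchange as text: ASCII PGM + JSON sidecar for rasters,
  legacy ASCII VTK polydata for surfaces, CSV for centerlines, waveforms and
  tables. No binary formats.

## Known limitations

* Real-data mode is limited to the documented file contracts; no image
  registration is performed, only its QC.
* The visual section-exclusion criteria of the source protocol require human
  judgement and enter only as per-record flags.
* Wald-z inference is slightly anti-conservative for very small patient
  counts; the null simulation bounds the practical effect at the study's
  scale (11 patients).
* The outflow-split table and the Carreau–Yasuda parameters are stand-ins
  with documented defaults, not measured values.
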