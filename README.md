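# shearplaque

Co-localization of pulsatile wall shear stress (WSS) metrics with
histologically determined plaque composition in carotid arteries.

## Who this is for

Vascular biomechanics and atherosclerosis researchers who relate
hemodynamics on the lumen surface to the composition of the underlying
plaque: necrotic core (NC) area, fibrin (intra-plaque hemorrhage) area,
macrophage (CD68⁺) area and fibrous-cap thickness, quantified per histology
cross-section and per 45° radial sector, and compared across
patient-specific WSS tertiles.

## What it computes

* **Boundary conditions** — Womersley pulsatile velocity/wall-shear solution
  in flow-rate form (exact flow conservation), Carreau–Yasuda blood
  viscosity, scaling of an arbitrary inflow waveform so the common-carotid
  time-averaged WSS equals 0.9 Pa, and a stenosis-degree-based ICA/ECA
  outflow split.
* **WSS metrics** — per-vertex TAWSS `= (1/T)∫|τ_w|dt` and OSI
  `= ½(1 − |∫τ_w dt| / ∫|τ_w|dt)` over one cardiac cycle (periodic
  trapezoidal quadrature on the vector series).
* **Co-localization** — ±0.3 mm axial window around each histology section,
  eight half-open 45° sectors about the registered centerline point, per-bin
  WSS means joined with per-bin plaque measures into one analysis table.
* **Histology quantification** — component areas and minimum-ray cap
  thickness per sector from class-coded label masks, with artifact-based
  sector exclusion.
* **Registration QC** — Dice coefficient, average (and max) Hausdorff
  distance, rigid 2D contour alignment.
* **Statistics** — patient-specific TAWSS/OSI tertiles, 3×3 tertile
  co-occurrence, linear mixed-effects models (`lme4`) with a patient random
  intercept, Bonferroni-adjusted pairwise Wald contrasts, and the combined
  TAWSS×OSI interaction model.
* **Synthetic studies** — vessels, analytic pulsatile WSS fields, and
  histology masks whose per-sector composition follows programmable
  tertile effects with patient random intercepts; ground truth is recorded,
  so parameter recovery and error control are testable end to end.

## Worked example

```r
library(shearplaque)

cfg <- run_config(n_patients = 4, sections_per_patient = 4, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
#> Pipeline run: 16 sections, 128 bin records (128 included, 100%)
#> Registration QC: DSC 0.983 +/- 0.003, avg HD 0.044 +/- 0.006 mm
#> Models fitted: 12

print(rep$models[["nc_area_mm2.tawss_tertile"]])
#> Mixed-model result: nc_area_mm2 by tawss_tertile (n = 128, backend = lmer)
#>  group     mean        se
#>    low 1.222974 0.1624244
#>    mid 1.218544 0.1624244
#>   high 1.983183 0.1034713
#> Pairwise contrasts (Bonferroni-adjusted):
#>    contrast  estimate     se        z     p_raw p_adjusted
#>   mid - low -0.004431 0.1825 -0.02428 9.806e-01  1.000e+00
#>  high - low  0.760209 0.1549  4.90626 9.283e-07  2.785e-06
#>  high - mid  0.764639 0.1549  4.93486 8.021e-07  2.406e-06
```

Reading the output: the synthetic default effects program NC area to grow
with the TAWSS tertile (means 1.0 / 1.2 / 2.0 mm² before patient and
residual noise), and the fitted model recovers that structure — estimated
NC area ≈ 1.2 mm² in low/mid tertile sectors versus ≈ 2.0 mm² in
high-TAWSS sectors, with the high-vs-low contrast of ≈ 0.76 mm² strongly
significant after Bonferroni adjustment. The QC line summarizes the
synthetic registration exercise (Dice overlap near 1, sub-0.05 mm average
Hausdorff distance after rigid re-alignment). `rep$cooccurrence` gives the
3×3 co-occurrence of TAWSS and OSI tertiles over included sectors, and
`rep$records` the full per-sector analysis table.

A scripted interface covers the same flow:

```sh
Rscript -e 'shearplaque::shearplaque_cli()' run --seed 1 --outdir out/
Rscript -e 'shearplaque::shearplaque_cli()' simulate --seed 1 --outdir out/
```

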