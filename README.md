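# atriakit

Quantitative analysis of atrial cine cardiovascular MR (CMR)
measurements, built for method-comparison studies of conventional
segmented bSSFP cine against highly accelerated (compressed-sensing, CS)
cine. It is aimed at imaging scientists who need a tested, reproducible
implementation of the full measurement-and-statistics chain — from contour
polygons to a publication-style agreement/diagnostics report — without
access to the original scans.

## What it computes

- **Area-length volumetry.** Left atrial volumes from 2- and 4-chamber
  contours by the biplane formula `V = 8/(3π) · A_2CH · A_4CH / L`
  (length `L` = distance from the annulus midpoint to the farthest
  contour point, minimum across views); right atrial volumes by the
  monoplane 4-chamber variant `V = 8/(3π) · A² / L`. Exact on prolate
  spheroids, which the tests exploit as a closed-form oracle.
- **Atrial function.** Landmarks of the time-volume curve (Vmax, Vmin,
  mid-diastolic Vmin at diastasis, mid-diastolic Vmax before atrial
  contraction) and the emptying fractions

      TEF = 100 (Vmax − Vmin) / Vmax            (reservoir)
      PEF = 100 (Vmax − mid-dia Vmin) / Vmax    (conduit)
      AEF = 100 (mid-dia Vmax − Vmin) / mid-dia Vmax   (booster)

- **Edge sharpness.** Myocardium/blood-pool edge sharpness of a cine
  frame: bilinear upsampling → Deriche first-derivative edge image →
  Hough longest straight line → eight orthogonal intensity profiles →
  sharpness = mean(1/d), with d the 20–80% rise distance (for a linear
  ramp of width w, d = 0.6 w).
- **Agreement & diagnostics.** Mann-Whitney U, R², two-way
  absolute-agreement ICC, Bland-Altman bias and limits of agreement,
  Fleiss' kappa, ROC/AUC with Youden cutoffs, and the DeLong test for
  paired AUCs.
- **Synthetic data.** A first-class generator for cohorts of atrial
  curves (healthy-volunteer and HFrEF phenotypes, calibrated to published
  medians/IQRs), paired-technique disagreement, repeat-reader jitter,
  invertible elliptical contour sets, and ramp-edge phantoms with known
  ground-truth sharpness.

## Worked example

```r
library(atriakit)

ph <- curve_phenotype(24, 35, 40, 70)        # landmark volumes in ml
cv <- generate_volume_curve(ph, phases = 25) # noise-free 25-phase cycle
lm <- find_landmarks(cv)
compute_function(lm)
```

```
Curve landmarks (ml): Vmax 70.0, mid-dia Vmin 35.1, mid-dia Vmax 39.9, Vmin 24.0
Atrial function: TEF 65.7%, PEF 49.8%, AEF 39.9% (TEV 46.0, PEV 34.9, AEV 15.9 ml)
```

The landmarks land within one phase of the generating control points
(24/35/40/70 ml), and the fractions follow the defining equations —
`TEF = 100·(70−24)/70 = 65.7`.

Sharpness of a synthetic 3 mm ramp edge (closed-form truth
`1/(0.6·3) = 0.556 /mm`):

```r
fr <- render_phantom_frame(phantom_config(image_size = 288,
                                          pixel_spacing_mm = 0.5,
                                          edge_width_mm = 3))
compute_sharpness(fr, sharpness_config(upsample_factor = 2))
```

```
Edge sharpness: 0.554 /mm (mean 1/d over 8/8 valid profiles; mean d 1.80 mm)
```

A full simulated study (82 healthy volunteers + 19 HFrEF patients, both
techniques, repeat readers, contour-routed volumetry):

```r
rep <- run_study(run_config("simulate", seed = 1))
rep
```

```
Technique comparison (conventional vs CS):
 parameter     conventional               cs       p   r2 bias loa_lower loa_upper  icc
    LAVmin 23.6 [17.2-33.0] 24.0 [19.3-35.4] 0.38700 0.92 -1.6      -9.7       6.5 0.95
    LAVmax      75.4 ± 26.2      71.5 ± 26.8 0.29600 0.96  3.9      -7.2      15.0 0.97
    ...
       PEF      48.1 ± 13.2      45.9 ± 14.9 0.17800 0.77  2.2     -11.9      16.3 0.86

Diagnostic performance (HV vs HFrEF):
 parameter auc_conventional ... auc_cs ... delong_p
    LAVmin             0.95        0.94      0.18000
       PEF             0.99        0.95      0.02140
    ...
```

The bias/LoA rows recover the configured disagreement model (LAVmin bias
−2 ml, LoA ≈ ±7.6 ml about it), reader ICCs sit in the high 0.99s, and
PEF and LAVmin carry the two highest AUCs. `write_study_report(rep, dir)`
serializes the tables to CSV/JSON.

A thin command-line front end sits in `inst/cli/atriakit`
(`simulate`, `volumes`, `function`, `sharpness`, `report` subcommands).

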