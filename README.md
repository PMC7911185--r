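# vertefail

Vertebra-specific prediction of incidental osteoporotic fractures from
routine quantitative CT.

Osteoporotic vertebral fractures are usually predicted from a single
summary number — the mean bone mineral density (BMD) of L1–L3 — which says
nothing about *which* vertebra is at risk. `vertefail` implements the full
per-vertebra alternative for clinicians and bone-biomechanics researchers:
from a CT volume with vertebra label masks (T5–L5) and an in-scan
calibration phantom it measures, for every vertebra,

* **trabecular BMD**, via the two-point phantom calibration
  BMD<sub>MDCT</sub> = 200/(HU<sub>b</sub> − HU<sub>w</sub>) · (HU − HU<sub>w</sub>)
  and the QCT standardization BMD<sub>QCT</sub> = 0.69 · BMD<sub>MDCT</sub> − 11 mg/mL;
* **FE failure load and failure displacement**, by meshing the vertebra
  into hexahedra, mapping HU to a transversely isotropic, density-driven
  elastic–plastic material (ρ_app = 47 + 1.122·HU, E_z = −349 + 5.82·ρ_app,
  piecewise power-law strength limits in ρ_ash), and running a
  displacement-controlled nonlinear compression whose load–displacement
  peak defines failure;

then forms **normalization ratios** K (local: against the subject's
regional T5–T12 / L1–L5 mean; global: against the L1–L3 mean) and scores
them with Mann-Whitney tests and **ROC/AUC analysis** — singly and in
logistic combinations — against incident-fracture labels. A synthetic
cohort generator builds CT-like vertebra volumes with a calibration phantom
and a configurable fracture effect, so the entire pipeline can be exercised
and tested end to end without patient data.

## Worked example

Measure one synthetic lumbar vertebra:

```r
library(vertefail)

v   <- make_vertebra_volume("L1", trabecular_hu = 130, noise_sd = 0)
cal <- calibrate(v$volume, v$mask)          # phantom rods -> HU_w = 0, HU_b = 200
roi <- place_roi(v$volume, v$mask, "L1")    # automatic trabecular ROI
mdct_to_qct(bmd_mdct(roi$mean_hu, cal))
#> [1] 78.7

mesh  <- build_mesh(v$mask, v$volume, "L1", edge_length = 2)
mesh
#> <vertefail_mesh> L1: 878 hex elements (2.0 mm edge), 1222 nodes, 109/109 boundary nodes
curve <- solve_compression(mesh, material_cards(mesh))
extract_failure(curve)
#> <failure_point> load = 1170.1 N at 0.189 mm
```

The BMD (78.7 mg/mL) is the calibrated trabecular density of the ROI; the
failure point is the peak of the simulated load–displacement curve — the
load this vertebra sustains before collapse and the compression at which it
happens (`autoplot(curve)` draws the curve).

A full cohort experiment chains the same steps over 16 subjects × 13
levels and reports discrimination of the 23 to-be-fractured vertebrae:

```r
sim <- simulate_cohort(cohort_sim_params(n_subjects = 16, seed = 101,
                                         incident_mode = "exact"))
out <- run_pipeline(sim, edge_length = 2)   # ~5 min on one CPU
out$report
#>               parameter   auc  p_value
#> 3          k_local_load 0.773 2.08e-05
#> 1           k_local_bmd 0.675 6.21e-03
#> 2  k_local_displacement 0.674 6.61e-03
#> 7          bmd_standard 0.486 8.40e-01
#> ...
#>                                          combination   auc
#> 2                         k_local_load + k_local_bmd 0.843
#> 4  k_local_load + k_local_displacement + k_local_bmd 0.841
```

Per-vertebra ratios discriminate clearly (K_load AUC 0.77 on this seed)
while the subject-level L1–3 BMD standard sits at chance — the core
vertebra-specific message. `tidy()`, `glance()` and `autoplot()` methods on
the curve, ROC and report objects give tibbles and ggplots.

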