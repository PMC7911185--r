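---
title: "Vertebra-specific fracture prediction from quantitative CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertebra-specific fracture prediction from quantitative CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

vertefail asks a clinical question: given a routine thoracic/abdominal CT of
an osteoporotic patient, *which vertebra* is likely to fracture? It answers
it by combining three per-vertebra measurements — phantom-calibrated
trabecular bone mineral density (BMD), finite-element (FE) failure load, and
FE failure displacement — normalizing each against the patient's own spine,
and scoring the normalized ratios with ROC analysis against incident-fracture
labels. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic test cohort does and does not show.

## From CT attenuation to bone mineral density

Every scan carries a two-phase calibration phantom (water- and
bone-equivalent rods at 0 and 200 mg/mL hydroxyapatite). `calibrate()`
estimates the rod mean HU values $HU_w$, $HU_b$, and `bmd_mdct()` maps any
HU through the two-point line

$$\mathrm{BMD}_{MDCT} = \frac{200}{HU_b - HU_w}\,(HU - HU_w) \quad [\mathrm{mg/mL}],$$

which is exact at both anchors and invariant to a common HU shift of scan
and phantom. Scanner-specific values are standardized with the affine
cross-calibration $\mathrm{BMD}_{QCT} = 0.69\,\mathrm{BMD}_{MDCT} - 11$
mg/mL. Negative QCT values are possible for very low HU and deliberately
propagate unchanged: clamping would bias the downstream ratio means.

The trabecular ROI is placed automatically (`place_roi()`): the most central
axial slice of the vertebra is selected, the body cross-section is separated
from the posterior elements by its row-width profile (rows narrower than 60%
of the maximal width are discarded, with a chord correction
$1/\sqrt{1-0.6^2}$ for the ellipse geometry), and an ellipse with half-axes
40% of the body half-axes is centered in the anterior half. The slice mask is
eroded by 2 voxels, which removes the thin cortical shell, and a minimum of
25 voxels is enforced. The dimensions are package choices — clinical practice
specifies the placement only qualitatively — and all are exposed as
arguments. The reference standard `bmd_standard()` is the mean QCT BMD over
L1–L3 and is reported missing (with a reason code) if any of the three
levels is absent or fractured at baseline, rather than computed from a
subset.

## From HU to material, mesh, and failure load

The FE chain treats bone as a continuum whose properties follow local CT
attenuation (`material_cards()`):

* apparent density $\rho_{app} = 47 + 1.122\,HU$ (kg/m³), ash density
  $\rho_{ash} = 0.6\,\rho_{app}$;
* transversely isotropic elasticity about the cranio-caudal axis:
  $E_z = -349 + 5.82\,\rho_{app}$ (MPa), $E_x = E_y = 0.333\,E_z$,
  $G_{xy} = 0.121\,E_z$, $G_{xz} = G_{yz} = 0.157\,E_z$,
  $\nu_{xy} = 0.381$, $\nu_{xz} = \nu_{yz} = 0.104$;
* strength: tensile principal-stress limit
  $\sigma = 137\,\rho_{ash}^{1.88}$ below 0.317 g/cm³ and
  $114\,\rho_{ash}^{1.72}$ above (the two fits meet there to within 0.03%),
  compressive limit $\sigma_{min} = 65.1\,\rho_{ash}^{1.93}$, and a
  post-yield strain capacity $\varepsilon_{AB} = -0.00315 + 0.0728\,\rho_{ash}$.

Two unit conventions deserve emphasis. Densities are computed in kg/m³, but
the strength laws consume $\rho_{ash}$ in g/cm³ — the coefficients and the
0.317 branch point are only dimensionally sensible in that unit, which is the
convention of the source cadaver regressions — so the card builder divides by
1000 at that boundary, and a dedicated test pins the bridge. With lengths in
mm and moduli in MPa, reaction forces emerge in N. The affine laws go
negative at air-like HU, so they are clamped below: density at a tiny
positive floor (1 kg/m³; a larger floor would break the exactness of the
printed relation at HU = 0), stiffness at 0.01 MPa, plastic strain at 0.
The cortical shell is deliberately *not* given its own constitutive law; it
is treated as denser trabecular bone through the same relations.

The Poisson row of the source table is ambiguous as printed (it repeats the
in-plane symbol); the package reads the second group as the out-of-plane
pair, $\nu_{xz} = \nu_{yz} = 0.104$, consistent with transverse isotropy.
Because all moduli are fixed ratios of $E_z$ and the Poisson ratios are
constants, every element elasticity matrix is $E_z$ times one unit matrix —
the solver exploits this by scaling a single reference hexahedron stiffness
per element, which is what makes a 200-vertebra cohort tractable in pure R.

`build_mesh()` coarsens the voxel mask onto a regular grid of 8-node
hexahedra (default edge 2 mm, the mesh-converged value; `convergence_sweep()`
reproduces the ladder from 1.5 to 3.0 mm and reports the coarsest edge
within 5% of the finest). An element is kept when at least half of its
volume lies inside the mask, judged against the actual number of voxel
centers its cell contains (not the nominal edge³/voxel volume — that
denominator creates parity artifacts whenever the edge is not an integer
multiple of the spacing). Hexahedral voxel coarsening was chosen over
boundary-conforming tetrahedra: it is robust on mask input, has no commercial
mesher in the loop, and linear tetrahedra are overly stiff; the geometric
price is a stair-stepped surface whose volume error the tests bound at 10%
for edges up to 2 mm.

`solve_compression()` fixes the inferior endplate nodes, drives the superior
endplate nodes downward in uniform increments (default: 2% of specimen
height over 40 steps), and applies a three-state pseudo-plastic element law
evaluated on centroid principal stresses: elastic until
$\sigma_1 > \sigma$ or $|\sigma_3| > \sigma_{min}$; then yielded, with the
tangent stiffness scaled to 5%; then failed — tangent 0.1% and the
accumulated element stress released to a 5% residual — once the
post-yield strain exceeds $\varepsilon_{AB}$. The reaction is read as the
internal force transmitted through the loaded surface; the stress release at
failure is what makes the global curve soften, so the load–displacement
curve exhibits the rise–peak–collapse shape whose maximum defines the
failure load and failure displacement (`extract_failure()`, ties broken
toward the smaller displacement; a curve that never softens returns its last
point flagged). The run stops early once the reaction drops below 70% of its
running maximum. This state-machine scheme is a deliberate surrogate for a
full return-mapping plasticity integrator: it reproduces the peak
phenomenology with far less machinery, and it is validated against
closed forms — bar stiffness $EAd/L$ and two-layer series compliance to 2%,
plastic plateau $\sigma_{min}A$ to 5%, exact elastic linearity, and exact
scaling of the failure load under joint modulus/strength scaling. State
transitions are applied at step boundaries, so stresses can overshoot a
limit by up to one increment; the step count bounds that error.

Boundary-condition fidelity vs. oracle fidelity is handled by one switch:
the default `constraint = "fixed"` fully fixes the inferior nodes (the
compression boundary condition of the clinical protocol), while
`constraint = "uniaxial"` constrains only their axial motion plus minimal
rigid-body pins, which is the configuration under which the closed forms are
exact.

## Normalization and statistics

Absolute failure load, displacement and BMD all trend along the spine, so
per-vertebra values are expressed as ratios (`normalized_ratios()`): the
global ratio divides by the subject's L1–L3 mean, the local ratio by the
subject's regional mean (T5–T12 or L1–L5). Both families are invariant to
per-subject rescaling, and the local family satisfies an exact conservation
identity (each region's included ratios average to 1). Baseline-fractured
vertebrae are excluded from every denominator *and* receive no ratio; a
vertebra that later fractures still contributes to the means, because its
baseline value predates the fracture. The denominator-exclusion rule is the
one genuine ambiguity in the protocol; exclusion was chosen for consistency
and the flag is carried so the alternative is switchable.

The statistical layer (`run_report()`) mirrors standard clinical practice:
a Lilliefors-corrected one-sample KS normality screen motivates rank-based
tests; healthy-vs-fractured comparisons use the Mann-Whitney U (min-rank
convention, exact enumeration up to combined n = 16, tie-corrected normal
approximation beyond); discrimination uses the empirical ROC with trapezoid
AUC, which the implementation *asserts* equals $U_1/(n_1 n_2)$ on every
call. Parameter combinations are scored by an in-sample binary logistic
linear predictor — no cross-validation, matching the apparent-AUC convention
of the clinical literature — with a lightly ridge-penalized fallback under
perfect separation. Orientation is automatic by the sign of the group-mean
difference (load and BMD ratios enter lower-is-positive, the displacement
ratio higher-is-positive) and is recorded per row. The statistical unit is
the vertebra; subject-level clustering is ignored, a simplification the AUC
confidence intervals inherit (they assume independent observations, so they
run slightly narrow on clustered cohorts).

One property worth stating precisely: adding a column to an in-sample
logistic model can never decrease the likelihood, but it *can* move the
apparent AUC down by a hair, because the fit maximizes likelihood, not AUC.
Near-ties between the three-parameter combination and the best pair are
therefore expected on some cohorts, and the test suite treats the strict
ordering as the scientific claim it is rather than relaxing it.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` builds the study conditions the analysis assumes:
16 subjects, vertebrae T5–L5 as elliptic-cylindrical bodies with a denser
1.5 mm shell and endplates, a posterior-element block (included in the mask,
excluded from the BMD ROI and, by its shorter height, from the loaded
surfaces), soft-tissue background near 40 HU, and a two-rod phantom whose
ground-truth HU are parameters (default 0/200, so calibration code cannot
assume an identity map). Per-vertebra trabecular BMD targets are drawn from
the regional distributions 80.47 ± 17.56 mg/mL (thoracic) and 69.77 ± 17.01
mg/mL (lumbar), truncated at 5 mg/mL; body dimensions grow linearly from T5
(18 × 14 × 13 mm) to L5 (26 × 20 × 19 mm), a desk-scale rendition of the
cranio-caudal size gradient chosen to keep a 208-vertebra cohort at 2 mm
meshes within minutes on one CPU; voxels are 1 mm isotropic with 10 HU
Gaussian noise. Incident fractures follow the reference pattern (11 subjects
with one, 3 with two, 2 with three, 23 in all, clustered at the
thoracolumbar junction) either exactly or resampled; prevalent baseline
fractures occur at rate 0.02 and are excluded everywhere. The fracture
effect is a multiplicative HU deficit (default 0.85) applied to the whole
vertebra before image synthesis, so it propagates to BMD and FE through the
same image pathway a real analysis would use.

Running the pipeline on this cohort reproduces, in kind: lower failure load
and BMD ratios in to-be-fractured vertebrae; higher absolute failure load
and displacement in lumbar than thoracic vertebrae; essentially chance-level
discrimination by the subject-level L1–L3 BMD standard; and null cohorts
(deficit 1.0) whose AUC confidence intervals cover 0.5.

Equally important is what the generator does **not** emulate, and hence what
passing tests cannot show. There is no trabecular microarchitecture, no
scanner noise spectrum or beam hardening, no contrast-agent kinetics, no
degenerative geometry. And one empirical pattern of real cohorts is
structurally out of reach of a pure density deficit: elevated failure
*displacement* in to-be-fractured vertebrae. In this material model the
failure displacement scales like
$h\,(\sigma_{min}/E + \varepsilon_{AB})$, and at the cohort's density level
the deficit lowers $\sigma_{min}$ and $\varepsilon_{AB}$ faster than $E$, so
simulated weak vertebrae fail at *smaller* displacement, moving with the
load rather than against it. A displacement elevation in real patients must
come from pathways the generator deliberately lacks (patient-specific
geometry and degeneration); the package documents this as a limitation
rather than engineering the generator to force the sign.

## Problem sizes and determinism

Default experiment sizes, chosen as the package's own desk-scale study
conditions: 16 subjects × 13 levels; ~400–1200 hexahedra per vertebra at
2 mm; 40 displacement steps with early stopping at 70% of peak; 20 seeds for
null-coverage checks; the convergence ladder 1.5–3.0 mm on a single
mid-thoracic vertebra. Everything downstream of a
(`cohort_sim_params()`, seed) pair is bit-reproducible: image synthesis is
the only stochastic stage, meshing and solving are deterministic, and the
solver's factorization order is fixed.
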