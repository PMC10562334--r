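---
title: "Modelling nasal airflow and mucosal heat transfer before and after turbinate surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nasal airflow and mucosal heat transfer before and after turbinate surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhinoflow)
```

## The problem

Inferior turbinate hypertrophy is a common cause of chronic nasal
obstruction; radiofrequency reduction of the anterior turbinates widens the
airway where most of the obstruction sits. Whether the quantities a flow
simulation computes — wall shear force on the mucosa, mucosal heat transfer,
pressure loss through the cavity — track how patients actually feel is the
scientific question this package is built to study. It provides the full
computational chain used in paired pre/post imaging studies of such surgery:
segmentation of the airway from Hounsfield-unit volumes, a steady laminar
flow and heat-transfer solve, anatomically defined surface metrics, and the
nonparametric cohort statistics. Because patient CBCT data is rarely
shareable, the chain is exercised end to end on synthetic nasal phantoms
whose ground truth is known exactly.

## The phantom

`generate_phantom()` builds an idealized bilateral airway: two
mirror-image rectangular channels (default 5 mm wide, 18 mm tall, 55 mm
from nostril plane to nasopharynx) separated by a 2 mm septum, merging into
a common nasopharynx over the last 10 mm. Each channel carries a smooth
inferior-turbinate-like bump on its lateral wall below a "middle turbinate"
level 12 mm above the channel floor: amplitude 2.5 mm by default, onset
("anterior peak") 10 mm behind the nostril plane, sin^2 profile over 25 mm.
Air is assigned -1000 HU and soft tissue +40 HU, with additive Gaussian
noise (sd 30 HU) and clipping to the scanner range [-1000, 3000] HU — the
clip at -1000 mirrors real HU scales, and keeps noisy air voxels inside the
segmentation window so the noise level does not destabilise the geometry.
An optional ellipsoidal air pocket above one channel emulates an isolated
paranasal sinus.

Virtual surgery (`apply_surgery()`) scales the bump by `1 - r` only in the
operated band 5–20 mm posterior of the anterior peak, reusing the identical
noise realization, so the postoperative image differs from the preoperative
one only inside the band.

What the phantom does **not** emulate: real turbinate shape variation (no
statistical shape model), CBCT physics (beam hardening, scatter), mucosal
compliance or the nasal cycle. Tests passing on the phantom therefore
validate the *operators* — segmentation windows, solver physics, metric
definitions, statistics — not anatomical realism.

The default voxel spacing is 0.5 mm rather than the 0.2 mm of clinical
CBCT: at 0.5 mm the full pipeline solves a ~150 000-cell domain in a couple
of minutes on one core, which is the scale this package targets. Spacing is
an ordinary parameter; the `coarse` tier of `run_config()` resamples to
1 mm for multi-subject smoke runs.

## Segmentation

`threshold_airway()` marks voxels in the closed HU window [-1000, -430] —
the standard air window for nasal CBCT. `remove_isolated_regions()` labels
6-connected components and keeps those that intersect both the nostril and
nasopharynx planes; "no possible airflow" is thus operationalized as
failure to connect inlet to outlet, and components below 10 voxels are
dropped as reconstruction artefacts. `crop_domain()` restricts the mask to
the nostril–nasopharynx slab and extrudes the nasopharynx cross-section
50 mm downstream as an outlet buffer; the extension belongs to the solver
domain but never to anatomical metrics.

`extract_surface()` produces the blocky (voxel-face) isosurface rather
than a marching-cubes surface: it is watertight by construction, its area
for a single voxel is exactly `6 a^2`, and — because all metric integration
happens on the solver's wall faces, not on the display mesh — nothing
downstream depends on surface smoothing. STL export (binary and ASCII) is
provided for inspection in external tools.

## Flow model

The solver treats inspiratory airflow as steady, laminar and
incompressible, with air properties fixed at room-temperature values
(density 1.18 kg/m³, viscosity 1.85e-5 Pa·s, conductivity 0.0262 W/m·K,
specific heat 1006 J/kg·K) and temperature carried as a passive scalar.
Discretization is a voxel-native staggered (MAC) finite-volume grid:
first-order upwind convection, central diffusion, SIMPLE pressure–velocity
coupling with a Jacobi-preconditioned conjugate-gradient pressure solve.
Stair-step walls are the price of skipping body-fitted meshing; the plane
Poiseuille oracles quantify that price (pressure gradient within a fraction
of a percent at 20 cells across the gap, one-sided wall shear within a few
percent).

Boundary conditions follow the clinical setup: a uniform *total* pressure
(gauge 0) over the nostril faces, so the inlet static pressure is
`-rho |u|^2 / 2` with the velocity profile free to develop; a uniform
outlet velocity chosen to deliver the target flow rate; rigid no-slip
walls. The flow rate is patient-specific: mean inspiratory rate
`1.36 M^0.44` L/min for males and `1.89 M^0.32` for females at weight `M`
kg, doubled for the steady solve (peak of a sinusoidal breath), and
identical for a subject's pre and post runs.

Numerical parameters: under-relaxation 0.5 (velocity) / 0.2 (pressure) —
chosen after the conventional 0.7/0.3 pairing proved unstable with this
matrix-free Gauss–Seidel momentum scheme at physiological Reynolds numbers
(a few hundred); on a transient divergence the solver automatically retries
with 0.6x relaxation, which handles sharply constricted coarse-grid cases.
Convergence demands a scaled momentum residual below 1e-5 *and* a scaled
continuity residual below 1e-7; at that point the net inlet/outlet mass
imbalance is below 1e-6 of the flow rate and the achieved rate is within
0.1 % of target.

## Mucosal heat transfer

Each mucosal wall face obeys a Robin law: the local flux from mucosa to
air is `q = h_m (T_body - T_w)` with `T_body` = 310.15 K and a single
uniform coefficient `h_m` (default 50 W/m²K). Flux continuity with
one-sided conduction into the near-wall air cell,
`q = k (T_w - T_cell) / (d/2)`, determines the local surface temperature

`T_w = (h_m T_body + (2k/d) T_cell) / (h_m + 2k/d)`.

Two limits anchor the model: with no local heat transfer the mucosa sits at
body temperature, 37 °C; as `h_m -> 0` walls become adiabatic and take the
air temperature. Inlet air enters at 20 °C ambient, the outlet is
zero-gradient, and upwind advection keeps every cell inside
[T_amb, T_body]. `calibrate_h_m()` bisects `h_m` until the area-weighted
mean mucosal temperature over the anatomical airway matches a clinical
target (32 °C by default, the mean measured on healthy mucosa); because
temperature is passive, only the scalar equation is re-solved, so
calibration costs seconds. On the default phantom at the 70-kg-male doubled
flow rate, `h_m = 50` W/m²K lands the mean mucosal temperature near 31 °C,
and the calibration returns a coefficient of the same order — the
agreement is geometry-dependent and is logged, not hard-asserted, since an
idealized channel pair is not a nose.

## Surface metrics

`wall_field()` evaluates, per wall face: the one-sided shear stress
`tau = mu u_t / (d/2)` from the tangential cell-centre velocity, and the
Robin-consistent pair (`T_w`, `q`). The operated region (`define_roi()`) is
the wall surface 5–20 mm (closed band) posterior of the anterior turbinate
peak, below the lowest middle-turbinate level, selected per side by the
septum midline; posterior distance is measured along the y axis (not
geodesically), matching how the band is defined on sagittal images.
`integrate_wall_force()` reports the scalar integral of |tau| (both sides
summed), `integrate_heat_transfer()` the integral of `q`, and
`pressure_loss()` the drop from ambient total pressure to the area-averaged
*static* pressure on the nasopharynx plane (the choice between static and
total there is a convention; static is documented and used throughout).
Because integration uses solver faces, ROI and complement integrals sum to
the whole-wall integral exactly, and the whole-domain heat integral matches
the enthalpy rise `rho c_p Q (T_out - T_amb)` to solver tolerance.

## Cohort statistics

The statistics layer mirrors paired-study reporting: medians with
interquartile ranges (linear-interpolation percentiles, R type 7),
change = post − pre, two-sided Wilcoxon signed-rank tests, and Spearman
correlations on pooled (2n rows) and change (n rows) tables. The Wilcoxon
implementation drops zero differences, mid-ranks ties, and uses the exact
null distribution (dynamic programming over doubled midranks, so ties are
handled exactly) up to n = 25, a tie-corrected normal approximation with
continuity correction above — the exact-with-ties small-n path is the
reason this is not a plain `wilcox.test` call, which refuses exactness
under ties; agreement with `wilcox.test` in the tie-free case is tested.
Spearman uses average ranks, permutation-exact p below n = 9, the t
approximation above, and pairwise deletion for missing outcomes (so one
missing rhinometry subject yields n = 48 pooled / n = 24 change cells).
P-values are reported unadjusted, as is conventional in these studies.

## The synthetic cohort

`generate_cohort()` draws sex (1:1), weight (normal by sex, truncated),
per-subject turbinate amplitude, and a surgical reduction fraction
(uniform on [0.2, 0.8] by default — clinical per-patient reduction
fractions are not established quantities, so they remain free parameters).
Outcome scores are coupled to geometry through a fast analytic surrogate of
the operated-band wall shear force (`wall_force_surrogate()`: a
one-dimensional lubrication model with the flow split by per-side viscous
resistance). The VAS change follows a Gaussian copula on the surrogate
change whose Pearson parameter `2 sin(pi rho_s / 6)` yields a target
Spearman correlation `rho_s` (default 0.4, a moderate coupling of symptom
relief to shear reduction); GHSI improves linearly as VAS falls, plus
noise; the acoustic-rhinometry proxy is the analytic airway volume in the
20–50 mm band plus measurement noise. Scores are clipped into their scales
(VAS 0–10, GHSI 0–100), which perturbs the coupling only when subjects
saturate. Recovery of the target correlation is verified at n = 200 over
50 seeds; everything is a pure function of the cohort seed.

## Problem sizes and reproducibility

The shipped configuration solves the default phantom
(~150 000 fluid cells at 0.5 mm) in roughly two minutes on one core and the
1 mm coarse tier in a few seconds, which keeps a four-point surgery sweep,
the channel validation ladder and a small end-to-end cohort run inside a
routine test session. Every stochastic element (image noise, cohort draws)
is seeded; `run_config()` hashes its own serialization and stamps every
artifact with the hash, and `run_cohort()` resumes from completed per-subject
CSVs rather than re-solving.

## Known limitations

- Stair-step voxel walls overestimate wall area locally; integrated forces
  carry a resolution-dependent bias that the refinement tests bound but do
  not remove.
- First-order upwinding adds numerical diffusion; recirculation details
  behind the turbinate bump are smoothed at coarse spacing.
- The phantom's rectangular channels make no claim to anatomical shear or
  heat-flux magnitudes; only model-defined quantities (temperature limits,
  conservation, calibration behaviour, effect signs) are asserted in tests.
- Inspiration only, rigid walls, dry air: no expiration phase, no mucosal
  compliance, no humidity transport.
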