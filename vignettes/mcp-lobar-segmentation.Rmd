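---
title: "Vessel-specific lobar segmentation: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-specific lobar segmentation: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mcplobes)
```

## The model

`mcplobes` assigns every lung voxel to a lobar territory using only the
pulmonary arterial tree. The premise is physiological: lung tissue is
perfused by the nearest supplying artery, so the lobe of a voxel is the
lobe of the arterial subtree it is closest to. Formally, for each of the
six lobar subtrees $S_l$ (left upper, left lower, right upper, right
middle, right lower, and the accessory lobe of the porcine lung) we solve
the eikonal equation

$$|\nabla T_l(x)| = 1 \quad \text{inside the lung mask}, \qquad
  T_l = 0 \ \text{on} \ S_l,$$

whose solution is the geodesic distance (mm) from $x$ to $S_l$ *within the
lung*, and label $x$ with $\arg\min_l T_l(x)$. The domain is restricted to
the lung mask because supplying arteries cannot cross pleural boundaries;
an unconstrained Euclidean distance could let one lung's artery claim
tissue in the other lung across the mediastinum. The speed is uniform
inside the mask — the front is a pure distance transform, not intensity
weighted.

Mass quantification uses the linear air–tissue decomposition of the
noncontrast HU scale. A voxel's non-air volumetric fraction is

$$T_f = \frac{\mathrm{HU} - \mathrm{HU}_{air}}
             {\mathrm{HU}_{tissue} - \mathrm{HU}_{air}},
  \qquad \mathrm{HU}_{air} = -1000, \ \mathrm{HU}_{tissue} = 50,$$

and its mass is $T_f \times V_{voxel}\,[\mathrm{cm}^3] \times 1.053$ g/mL,
the density of lung parenchymal tissue. $T_f$ is clamped to $[0, 1]$ —
dense vessel voxels above 50 HU would otherwise exceed unity — and the
number of clamped voxels is reported. Volume is voxel counting times the
voxel volume (mm³ → mL by $\times 10^{-3}$); all unit conversions live in
one place. Because the territories tile the lung mask exactly (see below),
lobar masses add up to the global mass by construction; this conservation
is asserted to $10^{-9}$ relative in the tests.

## Pipeline stages and the parameters that matter

| Stage | Parameter | Default | Why |
|---|---|---|---|
| Lung segmentation | HU threshold | −300 HU | includes parenchyma (≈ −750 HU), excludes chest wall/mediastinum (≈ +40 HU) |
| | closing radius | 2 mm | recovers vessels as lung interior; rounds fissure-scale concavities |
| | min component | 50 mL | rejects airway/noise components at clinical scale (use ~1 mL for desk-scale phantoms) |
| Vessel growing | HU floor | −100 HU | vessels sit near soft tissue (≈ 30–50 HU), far above air-dominated parenchyma |
| Fast marching | exact-init radius | 3 voxels | removes the point-source error of the first-order scheme (see Numerics) |
| Quantification | HU endpoints, density | −1000 / 50 HU, 1.053 g/mL | the air–tissue decomposition constants |

The subtree partition needs one user click (marker) per lobe. Markers are
snapped to the nearest centerline point (tolerance 3 voxels) and every
centerline point takes the label of the geodesically nearest marker along
the 26-connected skeleton graph with Euclidean edge lengths — formalising
the study-style manual division of the tree with minimal input. When seeds
come from a different acquisition of the same subject, `snap_seeds()`
first moves each click to the *deepest* nearby vessel voxel (the vessel
core), as an observer clicking a bright vessel centre would.

## The synthetic phantom: what it emulates, and what it does not

No real swine scans ship with the package, so every downstream stage is
validated on synthetic phantoms with analytic ground truth:

* two lung ellipsoids plus a small accessory-lobe ellipsoid attached to
  the right lung by a narrow neck (porcine anatomy); lobar territories cut
  by gently rippled (fissure-like) surfaces — used only for ground truth,
  never by the algorithm;
* one bifurcating arterial subtree per lobe. Branches are grown
  *demand-driven*: each branch runs from its entry point to the jittered
  centroid of the sub-territory it supplies, which is then split along its
  principal axis for the two children (depth 6, radius decay 0.75 per
  generation, root radius 1.4 mm). This mirrors how real arterial trees
  ramify to perfuse their whole territory — which is the premise the MCP
  technique rests on — and gives roughly uniform terminal coverage. A
  purely random-direction tree leaves coverage holes that no real vascular
  bed has, and through them one lobe's territory bleeds into another's;
* an HU model with parenchyma $\mathcal N(-750, 40)$, vessels
  $\mathcal N(30, 15)$, soft-tissue background $\mathcal N(40, 10)$, and a
  0.6 mm Gaussian point-spread blur of the pleural interface. The blur
  matters: scanners blur the boundary in *every* acquisition, and a
  razor-sharp first acquisition compared against an interpolation-smoothed
  repeat acquisition produces a systematic partial-volume mass bias that
  real paired scans do not have. Vessels are painted after the blur; their
  HU blending is mass-neutral because mass is linear in HU;
* per-subject anatomy: lung semi-axes scaled by $\mathcal N(1, 0.05)$ and
  fissure positions jittered by $\mathcal N(0, 0.015)$ (fraction of the
  z-extent) per phantom, giving a realistic ~15% between-animal volume CV —
  without it, between-subject regression and ICC would be degenerate;
* repeat acquisitions: rigid motion uniform within ±2 voxels per axis,
  additive $\mathcal N(0, 20)$ HU noise, global HU drift uniform in
  ±5 HU. In paired studies *both* acquisitions are drawn through this
  model with independent seeds, mirroring a paired helical-scan protocol;
* simulated observers: seed/marker jitter within 2 voxels,
  rejection-sampled to stay on the arterial tree.

What passing phantom tests shows: the pipeline recovers territories
defined by vascular supply, conserves mass, and is reproducible under
acquisition noise of realistic magnitude. What it does not show:
robustness to pathology, incomplete vessel trees, airway confounders,
cardiac motion, beam hardening, or scanner-specific noise spectra — none
of which the phantom models.

Default study sizes: the label-recovery phantom is $128^3$ voxels at the
clinical spacing 0.625 × 0.625 × 0.5 mm; the paired-acquisition study uses
20 phantom pairs and the observer study 10 phantoms × 3 observers at
$96^3$ (same spacing), which preserves recovery quality (per-lobe Dice
within ~0.01 of the $128^3$ values) at a fraction of the cost.

## Numerical choices

**Fast marching.** First-order upwind Godunov discretisation with exact
per-axis spacing in the quadratic update, min-heap front propagation.
Voxels within 3 voxels of a seed are initialised with their exact
Euclidean distance *when the straight line to the seed stays inside the
mask* — the plain first-order scheme over-estimates badly near point
sources (at a face-diagonal neighbour it yields $1 + 1/\sqrt2 \approx 1.71$
instead of $\sqrt2$), and exact initialisation removes that source error;
the line-of-sight restriction prevents the initialisation from undercutting
geodesics across thin walls. In an open volume the solver stays within
~5% of the exact Euclidean distance everywhere.

**Why the 26-neighbour Dijkstra check is bounded away from zero.** The
natural discrete oracle — Dijkstra over the 26-connected voxel graph with
Euclidean edge weights — itself over-estimates true geodesic distance by
up to ~12.6% (worst near direction $(1, 0.36, 0.36)$; e.g. the offset
$(3,1,1)$ costs $\sqrt3 + 2 \approx 3.73$ on the graph against the true
$\sqrt{11} \approx 3.32$). A solver that tracks the continuous distance
therefore *must* deviate from that oracle by up to that margin, and in
masks containing configurations that are 26-connected but not
face-connected the graph can additionally shortcut through diagonal
"cracks" impassable to the face-propagating front. The package therefore
validates arrival times against exact Euclidean distances, and validates
*assignments* (which is what the technique uses) against the Dijkstra
oracle: argmin labels agree on ≥ 99% of voxels once near-ties (arrival gap
below one voxel diagonal) are excluded.

**Ties and degenerate inputs.** Exact arrival-time ties take the lowest
lobe label — deterministic and independent of evaluation order; the same
rule applies in the skeleton partition. Lung-mask voxels unreachable from
every subtree (isolated islands) receive the Euclidean-nearest-seed label
so the partition property always holds, and their count is reported. The
six arrival maps are streamed through a running argmin (one map in memory
at a time); the result is bit-identical to materialising all six.
Identical paired measurements (zero-variance differences) give a paired-t
p-value of 1 by convention rather than an error.

**Registration.** The optional rigid alignment of paired acquisitions uses
a mean-squared-HU metric with a coarse integer-voxel translation search,
per-axis rotation sweeps, and two Nelder–Mead refinement levels. The
metric is evaluated on an eroded interior (6-voxel margin): near the grid
boundary the overlap and fill wedges vary with the candidate transform and
otherwise bias the optimum away from the true alignment. Registration is
not part of the measurement path — per-acquisition totals need no voxel
correspondence — it exists for side-by-side territory visualisation.

**Statistics.** Lin's CCC uses sample variances with the Fisher-z CI and
Lin's variance; ICC(2,1) comes from closed-form two-way ANOVA mean squares
with McGraw–Wong F-based confidence bounds (the estimate is clamped at 1,
which it cannot mathematically exceed, against floating-point rounding on
near-perfect data). The normalised RMSE divides by the grand mean of both
measurement vectors; percent differences divide by the pair mean — the
standard companion of Bland–Altman analysis. Bland–Altman limits are
$\bar d \pm 1.96\,\mathrm{sd}(d)$. All tests are two-sided at
$\alpha = 0.05$.

## Known limitations

* The speed function is binary (lung / not-lung); an HU-weighted front
  that prefers travelling along vessels is a plausible refinement the
  package does not implement.
* Airways are not removed from the lung mask; in real scans the trachea
  and main bronchi would need handling that the phantom does not exercise.
* The marker-based subtree partition assumes each lobe's subtree is
  reachable from its marker along the skeleton; heavily fragmented vessel
  segmentations fall back to Euclidean-nearest labelling with a warning.
* Rigid registration only; respiratory-phase or deformable correction is
  out of scope.
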