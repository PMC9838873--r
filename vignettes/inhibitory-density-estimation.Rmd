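---
title: "Estimating consistent inhibitory neuron densities in an annotated brain volume"
author: "inhibitoryAtlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating consistent inhibitory neuron densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibitoryAtlas)
```

## The problem

Counting GABAergic (inhibitory) neurons and their main subtypes — cells
immunoreactive for parvalbumin (PV), somatostatin (SST) and vasoactive
intestinal peptide (VIP) — across every region of a whole mouse brain is
beyond any single experiment. What exists instead is heterogeneous:
published counts, densities and percentages for scattered subsets of
regions; whole-brain *in situ* hybridization (ISH) volumes whose pixel
intensity correlates with, but does not directly measure, cell density;
and a Nissl-stained reference volume from which total cell and neuron
numbers per region can be calibrated. This package turns those three
ingredients into a single, hierarchy-consistent table of per-region
counts for GAD67+ (all GABAergic), PV+, SST+, VIP+ and the residual
inhibitory population, and finally into explicit 3D cell positions.

## The model

Regions come from an ontology tree; every voxel of the annotation volume
carries one region id (0 = outside the brain). Two balance equations link
the populations in every region $r$:

$$ nNeu_r = nInh_r + nExc_r + nOther_r, \qquad
   nGAD_r = nPV_r + nSST_r + nVIP_r + nRest_r, $$

under the assumptions that GAD67 marks exactly the GABAergic neurons, that
PV/SST/VIP are mutually exclusive and all GABAergic, and that composition
is homogeneous within the finest regions. Counts, not densities, are the
canonical internal unit: the hierarchy constraint below is additive in
counts, and densities are derived views (count / region volume in mm³).

### Unconstrained estimates

For every region and type the pipeline produces an unconstrained estimate
$\eta$ with standard deviation $\sigma$, resolved in priority order:

1. **Purely-inhibitory rule.** Designated regions (canonically isocortex
   layer 1, the cerebellar molecular layer, the thalamic reticular
   nucleus) are taken to be entirely GABAergic: $\eta_{GAD} = nNeu_r$.
2. **Literature.** Records are parsed from a spreadsheet-style review
   table (CSV,
   one row per source-marker-region measurement), converted to counts (densities ×
   region volume; percentages × neuron or cell counts), filtered by a
   conflict rule — a source is dropped for a region when its mean is at
   least 5× larger or smaller than *every* other source's mean there —
   and aggregated as the mean of the source means; $\sigma$ is the mean
   of the available source standard deviations.
3. **Transfer functions.** ISH section stacks are assembled into volumes
   by per-pixel linear interpolation between sections, binarized at an
   Otsu threshold, and summarized per region as the mean binarized
   intensity $x$ over the region's subtree. A through-origin line
   $y = \alpha x$ is fit per marker and region group (cerebellum,
   isocortex, rest) to the cloud of (intensity, literature density)
   points: $\alpha = \sum x_iy_i / \sum x_i^2$, with
   $\mathrm{sd}(\alpha) = \sqrt{\sum(y_i-\alpha x_i)^2 / ((n-1)\sum x_i^2)}$.
   The through-origin form is deliberate: zero expression must imply zero
   density. Fit quality is reported as
   $R^2 = S_f / (S_f + S_{res})$ with $S_f = \sum(f(x_i)-\bar y)^2$ —
   an explained/(explained+residual) form that equals 1 exactly when all
   residuals vanish. Predictions are used only where no literature
   exists.
4. **Aggregation.** Parents with no direct evidence inherit the sum of
   their children's estimates (σ combined in quadrature), plus an
   own-voxel prediction where intensity is available.

A floor $\sigma \ge 0.1\,\max(\eta, 1)$ is applied throughout because the
optimization weight is $1/\sigma$ and some sources report no spread.

### Reconciliation

Independent estimates need not respect the balances (a fitted PV count
can exceed GAD67) nor the tree (a parent need not equal its children's
sum). Reconciled counts $x$ minimize the weighted corrections

$$ \min \sum_{r,t} \frac{|x_{r,t} - \eta_{r,t}|}{\sigma_{r,t}}
   \quad\text{s.t.}\quad
   0 \le x \le nNeu_r,\;
   -nNeu_r \le x_{PV}+x_{SST}+x_{VIP}-x_{GAD} \le 0,\;
   x_{parent} = x_{own} + \textstyle\sum_{children} x_c , $$

linearized with slack variables $z \ge |x - \eta|$ so the objective
becomes $\sum z/\sigma$. The own-voxel term $x_{own}$ (counts in a
parent's directly labeled voxels) is an explicit auxiliary variable with
the same bounds and subtype-sum window but *no* slack term: the objective
carries exactly one term per region and type, and given the totals the
equality constraints determine the own variable uniquely. Imposing the
subtype-sum window on own variables as well guarantees that the placement
preconditions hold on the voxel sets where cells are actually dropped.

Before the LP, a two-stage pre-pass produces a feasible initial solution
and a sanity bound on the optimum, processing regions deepest-first:

* **Capping**: where $nGAD > nNeu$ or $nPV+nSST+nVIP > nNeu$, the excess
  is removed — GAD67 clipped to $nNeu$, subtypes reduced proportionally
  to their current ratios, freezing any value that reaches the bottom of
  its interval $[\eta-\sigma, \eta+\sigma]$ and redistributing the
  remainder.
* **Coherence**: where $nGAD < nPV+nSST+nVIP$, the smallest fraction
  $q \in [0,1]$ is found (by bisection on a monotone gap function, 60
  iterations) such that raising GAD67 by $q\sigma_{GAD}$ and lowering
  each subtype by $q\sigma$, clamped at the interval edges, restores the
  inequality; if $q = 1$ is insufficient the subtypes are rescaled
  proportionally onto GAD67 and the region is logged as out-of-interval.

The LP itself is solved by a dense two-phase primal simplex implemented
in C++ (Dantzig pricing with a permanent switch to Bland's rule after 50
non-improving pivots, which guarantees termination under degeneracy;
pivot tolerance 1e-9). Solutions are verified against every constraint at
a relative tolerance of 1e-7, and $x=0, z=\eta$ is always feasible, so a
failure indicates a malformed problem rather than genuine infeasibility.
In the test suite the solver is cross-checked on over a hundred random
toy problems against an independently formulated program solved by
`boot::simplex` (1e-6) and against exhaustive grid search on
integer-valued problems (1e-3).

Estimates whose corrected value leaves $\eta \pm \sigma$ are flagged, per
estimate and per region. Residual populations follow by subtraction:
$nRest = x_{GAD} - (x_{PV}+x_{SST}+x_{VIP})$ and
$nExcOther = nNeu - x_{GAD}$, both non-negative by the constraints.

### Placement

Cell positions are drawn per region from the voxels directly labeled
with the region id, with probability proportional to the calibrated cell
density and no per-voxel capacity (none is physically motivated at 25 µm
voxels, and occupancy is tracked). Solved fractional counts are rounded
by largest remainder within each region so the five labels (PV, SST, VIP,
InhR, ExcOther) sum exactly to the region's rounded neuron count. Type
labels are then assigned by nested uniform selection: an inhibitory
subset of size $nGAD$, then PV, SST and VIP drawn successively from the
still-unlabeled inhibitory cells — equivalent in law to the
voxel-conditioned description, with exact counts by construction.
Finally each cell gets a uniform position inside its voxel. One master
seed spawns deterministic per-stage substreams, so every stage is
independently reproducible.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| voxel size | 25 | µm/axis | atlas convention; anisotropic sizes supported |
| σ floor fraction | 0.1 | — | the objective divides by σ; sources without spread |
| outlier ratio | 5 | fold | fold-change separating a minority outlier from consensus |
| Otsu bins | 256 | — | histogram resolution on min–max-scaled in-brain values |
| LP tolerance | 1e-7 | relative | constraint verification after solving |
| section period | 8 planes | 200 µm at 25 µm voxels | coronal ISH sampling rate |
| neuron fraction | 0.5 | — | Nissl calibration split of cells into neurons |

Otsu is computed per combined marker volume over in-brain, covered voxels
only (background would otherwise pin the threshold at 0), with strict
`>` for foreground; whether to threshold per section or per volume is not
determined by the data model, and per-volume was chosen for robustness to
sparse sections. Voxels outside the imaged section range are excluded
from region means rather than counted as zero, which would bias means
downward in partially covered brains.

## The synthetic generator

`makeToyAtlas()` builds a nested-box annotation volume for a configurable
hierarchy (default 3 levels, 3×2×2 branching, 22 regions on a 64×20×20
grid of 25 µm voxels; every parent keeps a 2-plane slab of directly
labeled voxels). Per-region ground-truth densities are drawn so that all
constraints hold exactly: neuron densities 3–12 ×10⁴ cells/mm³ (×3 in
the cerebellum-like subtree), GABAergic fractions 8–45 % (100 % in one
designated purely-inhibitory leaf), and PV+SST+VIP carrying 50–90 % of
GAD67. The Nissl volume is proportional to total cell density. ISH
stacks are rendered so a region's foreground pixel fraction equals
density/α, with cumulative (error-diffused) rounding across planes so
the region mean matches to about one pixel; the true slopes are
0.8–6 ×10⁵ cells/mm³ per unit intensity, in the magnitude range expected
for these markers. Literature tables draw a seeded subset of regions
(default 50 %) with 1–3 records per region and marker, means perturbed
by multiplicative log-normal noise (CV 0.2 by default — densities are
positive and published spreads span multiples, so multiplicative noise
is the natural model), mixed among density, count and
percentage-of-neurons record kinds.

What the generator does *not* emulate: realistic anatomy (box regions,
not brain shapes), registration error beyond a rigid in-plane shift,
intensity artifacts of real ISH (soma-size variation, expression-level
gradients, slice damage), inter-animal variability, or literature whose
errors correlate across regions. Passing tests therefore demonstrate
correctness of the algorithms under the model's assumptions, not
accuracy on real atlas data, whose headline numbers additionally depend
on the actual reference volumes.

### What the tests establish

On the noise-free generator (full coverage, zero CV, every plane
sectioned) the pipeline returns the ground truth exactly, with LP
objective 0 — the truth satisfies all constraints, so any deviation
would be a defect. Under the standard noisy conditions (CV 0.2, coverage
0.5) the median relative count error stays below 0.2, and fitted slopes
recover the truth within 3 estimated standard deviations in ≥99 % of
simulations. The validation experiments re-run the full
fit-assemble-optimize path on literature subsets: across fractions
0.70–0.95 with 20 trials each, the mean cross-trial standard deviation
of the solved densities decreases as more literature is integrated, and
per-region values are extrapolated to full coverage by a least-squares
line in the fraction evaluated at 1 and floored at 0 (the extrapolation
method is a package choice; a one-parameter linear trend is the least
structured option for 6 support points). Hold-out runs (90 % kept)
predict most withheld literature densities within the withheld records'
mean ± sd. Problem sizes in the shipped tests and acceptance script — a
22-region standard fixture, random toy programs up to 12 regions, and a
structural build at 861 regions — were chosen so the whole suite
exercises every path at interactive runtimes; all results above are
recomputed at run time by `tests/testthat/` and
`scripts/acceptance.R`.

## Numerical choices and degenerate inputs

* Ties in the Otsu argmax take the smallest candidate threshold;
  constant input is an error ("no threshold separates classes").
* Regions with zero annotated volume get volume 0 and are reported, not
  errors; density records for them are errors at conversion time.
* Regions with $nNeu_r = 0$ have all four counts forced to 0 by the
  bound constraints.
* If the 5× rule would exclude *every* source of a region (mutually
  conflicting pair), nothing is excluded — the rule marks minority
  outliers, not whole regions.
* A negative fitted slope (possible with pathological clouds) is clipped
  to 0 with a warning; densities cannot be negative.
* Depth ordering breaks ties by ascending region id, making the pre-pass
  deterministic.
* Largest-remainder rounding breaks remainder ties by position.
* The coverage-summary skewness $s = \tfrac1n\sum((CV_r - \overline{CV})/
  \mathrm{sd}(CV))^3$ uses the sample standard deviation; coefficients of
  variation are computed on density-scale means, as published values are.
* The hierarchy constraint is an equality (the balance is written as an
  identity, and two inequalities would leave mass unaccounted).

## Known limitations

The linear transfer function is the simplest monotone choice; saturating
(sigmoidal) responses and soma-size stratification are out of scope. σ
weighting in the objective treats all deviations symmetrically on the
count scale. The striatum-like situation — fitted GAD67 exceeding the
neuron count — is resolved by the optimization making such regions fully
inhibitory rather than by a hard rule. Glia are carried only as the
complement of the neuron fraction; subdividing them is out of scope.
Realignment of sections to the reference volume is upstream of this
package: inputs are assumed registered, and the only misalignment the
generator models is a rigid in-plane shift used to probe sensitivity.
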