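---
title: "Evaluating multi-structure delineations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-structure delineations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskeval)
```

## The problem

Automatic delineation of radiotherapy target volumes — the gross tumour
volume (GTV) and involved lymph nodes in head-and-neck cancer being the
motivating case — produces a 3D binary mask that must be compared against an
expert's manual mask. A single patient typically carries *several* disjoint
malignant structures: one primary tumour and a variable number of nodes.
Whole-mask ("patient-wise") metrics behave badly in exactly this setting:

* if the automatic method invents a spurious structure far from the target,
  every boundary distance measured from that structure is huge, and the
  patient-wise Hausdorff-type metrics explode even though all real
  structures were delineated well;
* if it misses a small node, distance metrics again conflate a *detection*
  failure with poor *boundary* quality.

`maskeval` therefore computes two complementary families of metrics: the
established patient-wise panel, and a structure-wise panel that first
decides which structures were actually detected and only then measures
boundary quality for those.

## Patient-wise metrics

For ground truth $X$ and prediction $\hat X$ (voxel sets on a common grid):

$$\mathrm{Dice}(X,\hat X) = \frac{|X\cap \hat X|}{\tfrac12|X| + \tfrac12|\hat X|}$$

For every boundary voxel $i$ of the prediction, the directed distance to the
truth boundary $\tilde X$ is

$$D_i = \min_{\tilde{x}_j\in \tilde X}\ \mathrm{dist}(\hat{\tilde x}_i, \tilde x_j),$$

with $\mathrm{dist}$ the Euclidean distance between voxel centres in
physical millimetres (anisotropic spacing is honoured componentwise). From
the multiset $\{D_i\}$ we report **HD95** (95th percentile — severity of the
largest errors, robust to single outliers), **ASD** (mean — typical error)
and **MSD** (median). The set is *directed*, prediction → truth, as the
definition above states; `patientwise_surface(..., symmetric = TRUE)` pools
both directions for users who prefer the symmetric convention, but the
directed form is the default and is what all package results use.

A *boundary voxel* is an in-mask voxel with at least one of its six face
neighbours out-of-mask; voxels on the grid edge count as boundary. This is
the standard morphological inner boundary and stays on the voxel grid — no
marching-cubes/sub-voxel surface is constructed, which keeps every quantity
an exact function of the two masks.

## Structure-wise metrics

A **structure** is a maximal connected component of a mask. For a structure
$\hat X_k$ of the prediction, the **coverage fraction** against the whole
truth mask is

$$\mathrm{CFrac}(\hat X_k, X) = \frac{|\hat X_k \cap X|}{|\hat X_k|}.$$

The denominator is always the queried structure, which makes the quantity
directional. A predicted structure with $\mathrm{CFrac} > 0.5$ is *detected*
(a true positive from the prediction's perspective); a truth structure whose
coverage by the whole predicted mask exceeds 0.5 was *found* (a true
positive from the truth's perspective). From the two directions:

$$\mathrm{PPV_{CNN}} = \frac{TP_{CNN}}{TP_{CNN}+FP}, \qquad
  \mathrm{Sens_{GT}} = \frac{TP_{GT}}{TP_{GT}+FN}.$$

`Volume_true` and `Volume_false` are the mean volumes of detected and
undetected predicted structures (cm³ in reports). Finally, HD95/ASD/MSD are
recomputed *per detected predicted structure*, with distances from that
structure's boundary to the whole truth boundary; undetected structures are
excluded entirely, so a false blob cannot contaminate these summaries.

```{r worked}
ex <- worked_example_pair()
evaluate_pair(ex$truth, ex$prediction, patient_id = "worked-example")
```

The built-in worked example above (three predicted structures of which one
overlaps nothing; two truth structures of which one is a large lesion marked
only by a small predicted blob) gives $TP_{CNN}=2$, $FP=1$, so
$\mathrm{PPV_{CNN}}=2/3$, and $TP_{GT}=1$, $FN=1$, so
$\mathrm{Sens_{GT}}=0.5$.

## Parameters that matter

* **Coverage threshold** (`threshold`, default 0.5, dimensionless): the
  detection cut on CFrac. The comparison is *strict* (`> 0.5`): a structure
  exactly half-covered is not detected. Half-coverage is a genuinely
  ambiguous boundary case; we pin the strict reading and expose both the
  threshold and the strictness (`strict = FALSE` gives `>=`) so
  sensitivity analyses are one argument away.
* **Connectivity** (`connectivity`, default 26): which voxel adjacencies
  join a component — 6 (faces), 18 (+edges), 26 (+corners). Clinically
  contiguous lesions drawn slice-by-slice often touch only diagonally
  between slices, and 26-connectivity avoids fragmenting one lesion into
  many; it is a convention, not a fact about any dataset, so it is
  configurable. Component counts are monotone: coarser connectivity never
  yields fewer components.
* **Percentile method**: HD95 uses linear interpolation between closest
  order statistics (`stats::quantile` type 7), pinned for bit-for-bit
  reproducibility; nearest-rank conventions differ by a fraction of a voxel
  on realistic boundary sets.
* **Structure-wise reference boundary**: distances from a detected
  structure run to the *whole* truth boundary, not only to the overlapped
  truth structure. This is the minimal reading — the nearest truth boundary
  can only be as close as or closer than any particular structure's
  boundary, so it never overstates error.
* **CT window** (`hu_window`, centre 70 HU, width 200 HU): clips to
  [−30, 170] HU — the soft-tissue range in which tumours and nodes live —
  and rescales linearly to [0, 1]. Rescaling (rather than leaving clipped
  HU) is pinned so downstream consumers see a deterministic range; mapping
  the output affinely back to HU and re-windowing is the identity.

## Degenerate inputs

Ratios with empty denominators are **never** coerced to 0 or 1: with no
predicted structures PPV is `NA`; with no truth structures sensitivity is
`NA`; with either mask empty the distance summaries are `NA`. Each case
appends a named flag to the report so cohort code can count and exclude it.
The single exception is Dice on two empty masks, which defaults to 1 (a
prediction that correctly finds nothing should not score 0) with a warning
and a flag; `both_empty = NA` opts out. Cohort summaries exclude `NA`
values from means and report the exclusion count — silently coercing them
would bias cohort averages.

## Cohort aggregation

`summarize_cohort()` reports mean ± sample standard deviation per metric in
the conventional units (percent for Dice/Sens/PPV, mm for distances, cm³
for volumes). Structure-wise metrics are pooled **per patient first** (mean
over that patient's detected structures) and then across patients, so a
patient with many nodes does not dominate the cohort figure. This pooling
order is a design choice — per-structure pooling is equally defensible —
and is deliberately the one that matches per-patient clinical review.

## The synthetic phantom generator

`phantom_spec()`/`render_phantom()` build masks from ellipsoids: a voxel is
in-mask iff its physical centre lies inside some ellipsoid. Ellipsoids are
chosen *because* they are unrealistic in a useful way: volumes, overlaps and
surface offsets all have analytic references, so every metric can be checked
against closed forms or brute-force recomputation. `perturb()` applies
error modes with known metric signatures — translation (moves all
distances), dilation/erosion (boundary offset of ~1 voxel per iteration),
`add_false_structure` (lowers PPV and inflates patient-wise distances,
leaves sensitivity and structure-wise distances fixed), `delete_structure`
(lowers sensitivity), and seeded boundary jitter (roughens surfaces).
`random_phantom()` derives everything from one integer seed and restores
the global RNG state.

What the phantoms do **not** emulate: irregular, lobulated tumour shapes;
partial-volume and contouring noise correlated along slices; anisotropic
inter-observer disagreement; intensity information of any kind. Passing
tests therefore demonstrate that the *metrics* are computed correctly, not
that any delineation algorithm performs well on clinical images.

## Numerical and implementation notes

* Distances are voxel-centre to voxel-centre; all metrics are invariant to
  translating both masks together and scale linearly in spacing — both
  properties are asserted in the test suite.
* Directed ASD under pure translation of a large cube converges to one
  *third* of the shift, not the full shift: only the two faces
  perpendicular to the motion sit at the shift distance, while the four
  parallel faces contribute near-zero distances. The test suite pins this
  k/3 limit against a brute-force all-pairs oracle. Dilation by one
  isotropic voxel, by contrast, gives ASD of exactly one voxel on large
  cubes (corner voxels are a vanishing fraction).
* Component labelling is deterministic (components numbered in ascending
  column-major scan order of their first voxel), so reports are
  byte-reproducible.
* Nearest-boundary search is an exhaustive scan over boundary voxel pairs
  in compiled code; boundary sets are two-dimensional surfaces, so this is
  comfortably fast at clinical grid sizes and is verified against an
  independent O(n²) R implementation at 1e-9 mm.
* Test and demonstration problem sizes (grids of 34³–48³ voxels, ~200
  randomized small mask pairs for the oracle-equivalence suite) were chosen
  so the full suite runs in well under a minute while still exercising
  multi-structure geometry; all expected values are either closed-form or
  recomputed by the independent oracles at run time.

## Known limitations

* Masks must share a voxel grid; no resampling or registration is
  performed, and orientation metadata from NIfTI headers is recorded but
  not acted on.
* NIfTI is the only file interchange format; DICOM-RT structure sets and
  NRRD are out of scope.
* Structure matching is by whole-mask coverage only — there is no
  one-to-one assignment (Hungarian matching), so one predicted structure
  spanning two truth structures counts both truth structures as found.
* Soft/probabilistic masks are not supported; inputs are binarised at
  read time (any nonzero voxel is in-mask).
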