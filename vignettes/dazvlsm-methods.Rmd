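---
title: "Attachment-focused lesion-symptom mapping: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attachment-focused lesion-symptom mapping: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dazvlsm)
```

## The problem and the model

Voxel-based lesion-symptom mapping (VLSM) relates lesion location to a
clinical variable by mass-univariate testing in a common template space:
binary lesion masks from many patients are stacked on one grid, and at
every voxel the patients lesioned there are compared with those who are
not.  `dazvlsm` implements this machinery for *extra-axial* tumors
(meningiomas being the motivating case), whose defining feature is a
dural site of origin: the tumor displaces brain tissue as it grows, so
the whole-tumor mask (total tumor volume, TTV) mixes "where the tumor
started" with "how big it got".  The package therefore supports a second
mask type, the dural attachment zone (DAZ): the intersection of the
tumor mask with a labeled dural template (convexity/skull-base shell,
falx, tentorium).  Mapping on the DAZ asks where tumors *anchor*, not
where they *reach*, and thereby removes most of the volume-driven
spatial spillover that inflates TTV maps.

At an included voxel $v$ the model is the univariable linear regression

$$y_i = \beta_0 + \beta_1 L_{iv} + \varepsilon_i,$$

where $L_{iv} \in \{0,1\}$ indicates lesion presence and $y_i$ is the
endpoint (a dummy-coded 0/1 group label, 0 = reference, or a continuous
outcome).  The slope $t$-statistic with $n-2$ degrees of freedom is, for
a binary regressor, algebraically the pooled two-sample $t$ comparing
lesioned and non-lesioned patients; the test suite verifies this
equivalence against `t.test(var.equal = TRUE)` to $10^{-10}$ relative
tolerance.  One-sided $p$-values ($\beta_1 > 0$: the observational group
is enriched at lesioned voxels) are converted to standardized Z-scores
through the exact Student-$t$ CDF and the normal quantile.

Voxels lesioned in fewer than `min_overlap` patients are excluded before
testing.  Sparsely covered voxels are exactly the places where one or
two patients can produce large apparent effects and where registration
or segmentation jitter bites hardest, so the filter buys stability at
the cost of coverage.

## Multiple-comparison corrections

Three corrections are provided, spanning the usual
conservatism-sensitivity range:

* **Bonferroni** — per-voxel threshold $\alpha/m$ over the $m$
  non-degenerate included voxels.  Simple and very strict at whole-brain
  voxel counts.
* **Benjamini–Hochberg FDR** — the standard step-up (computed via
  `stats::p.adjust`; an exhaustive step-up oracle double-checks it in the
  tests).  Bonferroni rejections are provably a subset of BH rejections
  at the same level, and the acceptance suite confirms this on every
  simulated map.
* **Permutation max-statistic** — the outcome vector is permuted jointly
  across voxels (preserving the lesion maps' spatial covariance), the
  map is recomputed, and the maximum is recorded; corrected
  $p(v) = (1 + \#\{b : \max_b \ge \mathrm{obs}(v)\})/(B+1)$, so $p$ is
  never zero and ties count as exceedances.  The maximum is taken over
  the z-map (`maxz`) or over the TFCE-enhanced map (`tfce`).

**TFCE** (threshold-free cluster enhancement) integrates cluster support
over all thresholds,
$\mathrm{TFCE}(v) = \sum_{h = dh, 2dh, \dots \le z(v)} e(h,v)^{E}\, h^{H}\, dh$,
with $e(h,v)$ the extent of $v$'s connected component in
$\{z \ge h\}$.  Defaults $H = 2$, $E = 0.5$ are the standard 3D
choices; `dh` defaults to (max observed z)/100 and is held fixed across
permutations so observed and null maps share one enhancement scale.
Enhancement is one-sided (negative z clamped to 0), matching the
one-tailed tests.  The implementation is validated against an exact
piecewise-constant integration oracle (integrating analytically between
the sorted distinct heights) and against hand-computed toy maps.

## Key parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_overlap` | 10 | patients | cohort-scale published value; desk-scale phantom analyses use 10 where attachments concentrate (hotspot) and 5 where they are uniform, since attainable overlap scales with cohort size and attachment concentration |
| `binarize_threshold` | 0.5 | fraction | rebinarization of interpolated masks; integer masks pass through |
| `daz_dilation` | 1 | voxels | tolerates ~1 mm registration/segmentation jitter so thin dural sheets are not missed; 0 gives the literal intersection |
| `midline_band_mm` | 2 | mm | masks whose centre of mass is within the band (falcine/parasagittal) are not flipped |
| `alpha` | 0.05 | — | conventional |
| TFCE `H`, `E` | 2, 0.5 | — | standard 3D enhancement exponents |
| TFCE `dh` | max z / 100 | z units | common discretization; halving `dh` changes scores by <2% on smooth maps |
| `connectivity` | 26 | — | standard for 3D cluster-based neuroimaging inference |
| `n_permutations` | 5000 | — | cohort-scale default; calibration experiments use 200 to keep 200-cohort simulations tractable |

Voxel indices are 1-based throughout the R API; world coordinates come
from the NIfTI affine applied to the 0-based index, the template is
assumed RAS+ ("right" = larger world x), and the midsagittal plane
defaults to world $x = 0$.

## The phantom: what it emulates and what it does not

All statistical claims are exercised on synthetic cohorts from the
phantom module, because the real patient MRIs behind the motivating
analyses are not distributable.  The phantom provides:

* an ellipsoidal "brain" (semi-axes 24/27/21 mm on a 64³, 1 mm grid) and
  a closed dural shell of 2 mm, with a planar falx along the midline and
  a planar tentorium over the posterior fossa, partitioned into named
  compartments;
* tumors as balls grown from a dural attachment voxel, clipped to the
  intracranial + dural domain — displacing, non-infiltrating growth with
  no mass-effect deformation, which is adequate because every statistic
  under test depends only on mask geometry;
* a lognormal volume law.  The desk-scale default is 4 ml mean with the
  clinical coefficient of variation (sd/mean = 17.6/31.6).  Tumors are
  deliberately *larger relative to the phantom head* than clinical
  tumors are relative to a real head: at desk cohort sizes (40-200
  patients versus 350) this keeps the ≥`min_overlap` filter meaningful.
  The cohort table records the sampled (equivalent-sphere) volume that
  drives the radius; the realized clipped mask volume is kept in the
  truth sidecar;
* binary endpoints from a logistic model,
  $\mathrm{logit}(q) = \mathrm{logit}(p_0) + \mathbb{1}[\text{hot}]\,(\mathrm{logit}(p_1)-\mathrm{logit}(p_0)) + s\,(V - \bar V)$,
  with probabilities clamped to $[0.001, 0.999]$.

Three presets define the study conditions:

* **null** — $p_0 = p_1$, no volume effect; used for error-rate
  calibration.
* **hotspot** — a 6 mm spherical hot region on the right convexity
  mid-shell; half the attachments are drawn from it, with $p_1 = 0.6$
  inside versus $p_0 = 0.1$ outside.  The tight radius is what makes the
  implanted effect localizable at $n = 60$ with a binary endpoint: hot
  tumors then share a common attachment core whose per-voxel overlap
  approaches the number of hot patients.
* **volume-confound** — endpoint driven only by volume (6 ml mean,
  logistic slope 1.5 per ml, i.e. nearly a step function of volume —
  comparable in decisiveness to the clinical association between size
  and grade).  The volume-bias experiment runs at $n = 200$: the
  TTV-vs-DAZ contrast lives at deep voxels reached only by large tumors,
  and below roughly a hundred patients the BH step-up on this diffuse
  signal is an all-or-nothing affair whose outcome flips from seed to
  seed.  This is a power statement about volume-bias detection, not a
  defect of the correction.

The phantom does **not** emulate: MRI intensities, edema, mass-effect
deformation, registration error, skull anatomy, or realistic dural
curvature (ellipsoid instead of gyral/fossa geometry).  Passing tests
therefore demonstrate the correctness and calibration of the *mapping
machinery* on known ground truth — not that any particular clinical
cohort will yield localized findings.

## Numerical and design choices

* **Mirroring rule.** The laterality-collapsing step flips a mask iff
  its centre of mass lies more than 2 mm left of the midline plane;
  midline-straddling masks stay put.  Whether midline tumors should flip
  is genuinely underdetermined; both behaviors are selectable
  (`force = "flip"` / `"none"`).
* **Degenerate voxels** (constant lesion column or zero residual
  variance, e.g. perfect separation) carry $z = 0$ and are excluded from
  inference rather than propagated as $\pm\infty$; this keeps TFCE
  finite.  $|z|$ is additionally clamped at 8.2, the practical limit of
  double-precision normal quantiles.
* **Unattached tumors** (empty DAZ) are excluded from DAZ analyses with
  a message; a hard-error mode exists.  Phantom tumors always attach by
  construction, so the unattached path is exercised by a dedicated
  interior-ball fixture in the tests.
* **Permutation p-values** use the $(1+\text{count})/(B+1)$ estimator
  with ties as exceedances: valid (never anticonservative) for any $B$.
  With *binary* endpoints at small $n$ this makes max-statistic
  inference measurably conservative: the permutation null of the map
  maximum has a large atom at the best achievable group split, which a
  substantial fraction of permutations attains.  The FWER calibration
  experiment therefore uses a lesion-independent Gaussian outcome, for
  which the null is effectively continuous and the empirical FWER sits
  inside the binomial band around $\alpha$; a separate test asserts the
  binary-endpoint rate stays *below* nominal.  Users mapping binary
  endpoints should read permutation-corrected results as conservative.
* **Recovery metric.** Localization experiments report the centre of
  mass of the *largest* 26-connected significant cluster, compared
  against the centroid of the implanted hot dural voxel set.  The
  centroid (rather than the hot sphere's centre point) is the right
  reference because any voxel-set centroid on a curved shell is pulled
  toward the interior; the largest-cluster rule makes the summary robust
  to satellite clusters.
* **Analytic vs permutation corrections.** Bonferroni and FDR operate
  on the analytic one-sided $p$-values; only the max-statistic methods
  use the permutation null.  This split matches common VLSM toolbox
  behavior.
* **Determinism.** Every stochastic stage takes a seed, cohort
  generation restores the caller's RNG state, and the pipeline manifest
  records per-stage counts plus output checksums; identical
  config + seed reproduces outputs bit-identically.

## Problem sizes used by the experiments

The calibration and demonstration experiments run on the 64³ desk-scale
phantom: 200 null cohorts of 40 patients with 200 permutations each for
FWER; 100 simulated 5000-voxel maps for FDR; 20 hotspot cohorts of 60
patients; 20 volume-confound cohorts of 200 patients.  A 96³ "high-res"
space (`build_phantom_space(c(96, 96, 96), c(38, 42, 34))`) accepts the
clinical 31.6 ± 17.6 ml volume law directly for larger-scale
exploration.

## Known limitations

* Only univariable models: no lesion-volume covariate adjustment, no
  multivariable or multivariate lesion mapping.
* Continuous outcomes are tested with the same $t$ machinery; no
  rank-based alternatives (e.g. Brunner–Munzel).
* Masks must already live on one template grid; registration,
  resampling between spaces, and DICOM ingestion are out of scope.
* The dural template is trusted as given; partial-volume dural modeling
  and surface meshes are not attempted.
* Mirroring assumes the grid is left-right symmetric about the midline
  plane (true for the phantom and for standard MNI-space grids).
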