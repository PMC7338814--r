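---
title: "Segmenting white matter hyperintensities with an inlier/outlier mixture model"
author: "wmhseg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting white matter hyperintensities with an inlier/outlier mixture model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhseg)
```

## The problem

White matter hyperintensities (WMH) are bright regions on FLAIR MRI, dark
on T1, of presumed vascular origin. They range from small punctate spheres
through confluent patches deep in the white matter to periventricular caps,
and their volume correlates with cognitive decline. Quantifying them at the
scale of modern imaging cohorts requires automation; validating that
automation requires a carefully constructed human gold standard and metrics
that say not just *how much* two segmentations disagree but *why* and
*where*.

`wmhseg` implements that whole loop in one package: an automated segmenter
built on a per-tissue inlier/outlier Gaussian mixture, the semi-automated
thresholding protocol used to build rater gold standards, a nested
majority-vote consensus, agreement and error-decomposition statistics, and
a bullseye parcellation for spatial summaries. A seeded multimodal phantom
generator makes every stage testable with no external data.

## The model

Let $y_v \in \mathbb{R}^2$ hold the (T1, FLAIR) intensities of voxel $v$
and $a_{vc}$ the atlas prior of tissue class
$c \in \{\mathrm{GM}, \mathrm{WM}, \mathrm{CSF}, \text{non-brain}\}$. The
likelihood is

$$p(y_v) \;=\; \sum_c a_{vc} \sum_{j \in c} \pi_{cj}\,
  \mathcal{N}(y_v;\, \mu_{cj}, \Sigma_{cj}),$$

where each class carries one or more *inlier* components for normal tissue
and one broad *outlier* component (covariance $\kappa$ times the inlier's,
$\kappa = 10$) for unexpected intensities. Fitting is plain EM with
closed-form M-steps; the log-likelihood is non-decreasing at fixed
structure, and covariances are regularised (smallest eigenvalue lifted to
$10^{-6}\,\mathrm{tr}\Sigma/d$) only when numerically degenerate, so the
monotonicity guarantee is not blurred in the regular case.

Three mechanisms around the basic EM do the scientific work:

**Robust initialisation.** Class moments are initialised from
atlas-weighted sample moments. Because lesions sit inside the WM atlas
support, the raw WM covariance at heavy lesion load (around 10 ml, a third
of phantom WM) spans both the normal and the lesion mode, and a single
Gaussian happily absorbs both — after which nothing downstream can ever
call the lesions outliers. `robustify_model()` therefore iterates a
trimmed moment estimate (voxels within the $\chi^2_{0.9}$ ball of the
current estimate, re-estimated until the mean stabilises — an MCD-style
fixed point) so the inlier moments converge onto the dominant
normal-tissue mode before EM starts.

**Outlier re-seeding.** After the one-component-per-class fit converges,
each voxel gets an *initial outlier score*: the squared Mahalanobis
distance to the inlier components of its maximum-prior class. Voxels above
the $\chi^2_{0.95}$ quantile (df = number of modalities) re-seed the
per-class outlier weights and moments, sharpening sensitivity before the
final fit.

**Split-and-merge model selection.** The number of inlier components per
class is chosen dynamically: the component whose responsibility-weighted
squared distances deviate most from the $\chi^2$ reference (a weighted KS
statistic) is proposed for a split, the most similar same-class pair
(symmetric KL) for a merge; a proposal is kept when BIC over the masked
voxels improves after a short EM refit. The split direction is the
principal axis of the *whole class's* responsibility-weighted scatter, not
the component's own covariance — substructure parked in the outlier part
(e.g. deep grey nuclei inside the GM class) would otherwise be invisible
to the proposal. One admissibility constraint applies: a split outcome may
not leave any WM inlier brighter on FLAIR than the brightest GM inlier.
Inlier components represent normal tissue, and normal WM never outshines
GM on FLAIR; without the constraint, heavy lesion loads are "explained"
by a new WM inlier and the segmentation collapses to empty.

**Bias field.** Intensities are log-transformed so the multiplicative
scanner field becomes additive. The per-voxel residual (log intensity
minus log of the responsibility-weighted predicted mean) is fitted with
polynomials up to order 3 over normalised coordinates. Each class mean
already absorbs the average bias over that class's spatially clustered
voxels, which would leak class-shaped steps into the field, so per-class
nuisance intercepts are estimated alongside the polynomial and discarded
from the returned field. Correction is `exp(log y - field)`, and the model
is refitted on the corrected intensities.

## From outlier part to lesion mask

Candidate voxels are scored by squared Mahalanobis distance to the nearest
WM inlier (the "outlierness"), kept only where the outlier responsibility
exceeds the inlier responsibility *and* FLAIR exceeds the WM inlier mean.
Selection then proceeds:

1. **Primary threshold** $T = \chi^2_{0.95}$ (df = modalities), inclusive.
2. **Rescue pass**: connected clusters of the score $\ge 2T/3$ field that
   are disjoint from every primary candidate and strictly smaller than 60
   voxels are added — small lesions suffer partial-volume dilution and
   would otherwise be missed. The 60-voxel bound is strict (59 qualifies,
   60 does not).
3. **Connectivity**: components are classified in two consecutive steps,
   18-neighbourhood then 6-neighbourhood, so rules act on fine
   6-subcomponents while the 18-parent remains available — a cluster of
   mixed origin (artefact touching true lesion) is not discarded
   wholesale.
4. **False-positive rules**, applied per 6-subcomponent: (a) more than
   half outside the brain mask; (b) mean CSF prior above 0.5 (choroid
   plexus proxy); (c) mean FLAIR not above *every* normal parenchymal
   class — the maximum of the WM and GM inlier FLAIR means, since WMH
   outshine grey matter too (deep-grey rims whose smoothed atlas prior
   reads WM are the dominant false-positive mode otherwise); (d) outside
   the supratentorial mask; (e) fewer than 5 voxels (isolated voxels in
   the noise tail are indistinguishable from artefact); (f) mean WM atlas
   prior below 0.2 (wrongly-classified grey-matter structures).
5. **Volumes** integrate the surviving voxels' outlier-part
   responsibilities times the voxel volume; binary masks cut the
   probability at 0.5.

Both threshold comparisons are inclusive ($\ge$); the semi-automated
protocol exposes a `strict_gt` flag for the strictly-greater reading.

## The gold-standard protocol and consensus

The semi-automated protocol thresholds FLAIR at a percentage of the median
whole-brain intensity — 130%/120% (high/low) for Siemens and Philips,
raised to 145%/130% for GE because those scans carry a hyperintense
posterior region; maximum viewing intensities are 238% and 340%
respectively. Raters place seeds that grow into connected suprathreshold
components (3-D, 6-connectivity by default; the in-plane 2-D reading of
the protocol is config-exposed) and then edit manually; removals take
precedence over additions on conflict.

Four raters are fused by nested majority voting: each leave-one-out
triplet votes a voxel positive at $\ge 2$ of 3, and the consensus requires
$\ge 3$ of the 4 triplet votes. Exhaustive enumeration of all 16 rater
patterns shows this equals direct $\ge 3$-of-4 voting; the strict rule
resolves the 2–2 tie downward, and a `overall_min = 2` switch gives the
permissive alternative (equal to $\ge 2$-of-4).

## Agreement metrics

Disagreement between a segmentation S and reference R is split by
connected component (18-neighbourhood by default, matching the segmenter's
first stage): components of S that share no voxel with R are *detection
error* false positives, components of R absent from S detection-error
false negatives; within shared lesions, surplus S voxels are *outline
error* false positives and missing ones outline-error false negatives.
The counts obey exact conservation ($\mathrm{OEFP}+\mathrm{DEFP} =
|S \setminus R|$, $\mathrm{OEFN}+\mathrm{DEFN} = |R \setminus S|$) and
reconstruct Dice exactly. Volume agreement uses the two-way random-effects
absolute-agreement single-measure ICC (the "agreement" flavour: a constant
offset between raters lowers it) with the standard F-based interval,
Bland–Altman limits (mean difference ± 1.96 sample SD), and paired t-tests
on log2 volumes (WMH volumes are right-skewed; a unit mean difference is a
volume doubling). Empty-versus-empty Dice is defined as 1.

## Bullseye parcellation

The WM + deep-GM domain between the ventricular surface and the cortical
sheet is assigned a potential $\varphi$ by solving the Laplace equation
with Dirichlet values 0 on the ventricles and 1 on the cortex (7-point
stencil, spacing-aware weights, direct sparse Cholesky; faces with no
neighbour act as no-flux boundaries). $\varphi$ is binned into 4
equidistant layers (half-open bins, top bin closed) and crossed with 9
lobar labels — frontal/parietal/temporal/occipital × left/right plus one
subcortical label; infratentorial tissue is excluded since the segmenter
is supratentorial — giving 36 regions. Error maps are aggregated per
region as raw ml and as proportions of total error or of true-positive
volume.

On a slab the discrete solution is exactly linear (the solver reproduces
$\varphi = z/L$ to numerical precision). On concentric spheres a genuine
discretisation effect appears: a voxelised ball of radius 5 has a harmonic
capacity radius of about 4.7 — sub-voxel smaller than nominal — so the
field matches the $1/r$ closed form only after the boundary radii are
taken as their effective (fitted, within half a voxel of nominal) values,
and within 0.02 only one voxel away from the staircase boundary. The
binned layers are unaffected, since they are monotone functions of
$\varphi$.

## The phantom

The generator builds nested ellipsoids — a non-brain shell, a cortical GM
ribbon, a WM interior, two ellipsoidal ventricles and two deep-GM nuclei —
on a default 64×72×64 grid of 1 mm voxels (about 62 ml of brain, 30 ml of
WM). Noiseless intensities per tissue are config-exposed
(`default_tissue_means()`); lesions multiply the WM means by 1.5 on FLAIR
and 0.7 on T1 by default, values chosen as a strong but realistic contrast
since no quantitative lesion contrast is standard. Three morphologies are
planted: periventricular caps (layered shells grown from the ventricular
border), confluent patches (top-k voxels of a smoothed Gaussian random
field) and punctate spheres of radius 1–3 voxels in deep WM with exclusion
zones that keep components disjoint; layer-exact and count-exact selection
makes the realised load land within 15% of target (examined over seeds),
with a border-growing top-up if crowded geometry leaves a shortfall. A
multiplicative polynomial bias field (order ≤ 3, mean 1 over the brain,
span ±amplitude) and additive Gaussian noise (SD 5 against tissue
contrasts of 20–50 units) degrade both modalities; Gaussian rather than
Rician noise keeps the generator consistent with the model's assumptions.
All randomness flows from one seed; the same spec and seed reproduce the
phantom bit for bit.

What the phantom deliberately does not emulate: partial-volume mixing at
tissue boundaries, realistic cortical folding, Rician noise statistics,
motion or ghosting artefacts, and multi-scanner intensity families.
Passing tests therefore demonstrate the machinery is correct under the
model's own assumptions, not that clinical-grade accuracy transfers to
acquired MRI — on phantoms the segmenter's Dice is far above what any
method achieves on real scans, precisely because the phantom honours the
generative model.

## Numerical choices and problem sizes

EM stops at relative log-likelihood change below $10^{-5}$ (cap 60
iterations in the pipeline); split/merge proposals are evaluated with
15-iteration refits and accepted on BIC improvements beyond $10^{-6}$;
the Laplace system is solved directly with residuals checked against
$10^{-5}$. The packaged test-suite and the acceptance script run phantoms
at the default 64×72×64 grid for end-to-end checks (about 120k masked
voxels per fit) and a 40×44×40 grid for unit-level fixtures; the
20-phantom quality suite uses lesion loads from 2 to 10 ml, the range
from low to high burden found in aging cohorts.

## Known limitations

- The lesion-contrast defaults are generator conventions, not measured
  acquisition physics; weak-contrast behaviour (FLAIR multiplier below
  about 1.2) is untested and rule (c) will start rejecting true lesions
  near GM brightness.
- The split-and-merge search is greedy and local; it can settle at
  different component counts on statistically equivalent data.
- Lobe labels in the phantom are angular sectors, not anatomy; the
  bullseye machinery treats them as opaque categories, so this affects
  realism only.
- The false-positive rules (e) and (f) and the GM-referenced rule (c) are
  this package's concrete realisation of the "clinical knowledge"
  correction; they are config-exposed and documented rather than claimed
  canonical.
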