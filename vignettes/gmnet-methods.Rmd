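---
title: "Grey-matter network extraction and tau association analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grey-matter network extraction and tau association analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmnet)
```

## The model

gmnet builds *single-subject grey-matter covariance networks*: graphs in
which the nodes are small patches of a subject's grey-matter (GM) density
image and an edge marks a pair of patches with statistically similar
intensity patterns. The premise is that brain regions that develop and
function together express similar cortical morphology, so within-subject
similarity of local GM texture is a proxy for structural connectivity.
Disease processes that disrupt cortical micro-structure — here,
neurofibrillary tau pathology in Alzheimer's disease — degrade that
similarity structure, and the degradation is quantified with graph
measures, most compactly the small-world coefficient.

### Nodes

The GM volume (2 mm isotropic by convention) is tiled into non-overlapping
cubes of 3×3×3 voxels (6×6×6 mm³), the smallest patch that still captures
cortical folding while keeping the pairwise-correlation matrix tractable.
A cube becomes a node when it contains any positive GM intensity and its
fraction of GM-positive voxels reaches `min_gm_fraction` (default 0, i.e.
any GM-containing cube). Each node carries its atlas label — the majority
label over its GM-positive voxels, background ignored, ties resolved to
the smallest region id — and its GM volume (the intensity sum).

### Edges

Similarity between cubes *i* and *j* is the maximum Pearson correlation
over a discrete set of spatial rotations of one cube, so the measure is
insensitive to local cortical orientation:

$$s_{ij} = \max_{r \in \mathcal{R}} \; \mathrm{cor}\!\left(x_i,\; r(x_j)\right).$$

$\mathcal{R}$ contains all rotations composed from multiples of 45° about
the three axes, realised on the discrete 3×3×3 grid by mapping voxel
centres and snapping to the nearest grid point. Maps that collapse two
voxels are discarded and duplicates removed; brute-force enumeration
yields **96** distinct permutations, containing the identity and closed
under inverse (which guarantees $s_{ij}=s_{ji}$). The set is frozen as a
generated constant with a regression test, because the choice of discrete
realisation is otherwise a silent source of irreproducibility. Cubes with
zero intensity variance have no defined correlation; they are assigned 0,
which guarantees exclusion at any positive threshold.

The similarity matrix is binarised at a subject-specific threshold
calibrated so that the expected fraction of spurious connections is held
at `alpha` (default 0.05). A null distribution is built by repeatedly
drawing pairs of the subject's own cubes, independently shuffling the 27
intensities within each cube — destroying spatial structure while
preserving each cube's intensity histogram — and recording the
rotation-maximised correlation. The threshold is the empirical
$1-\alpha/M$ quantile of that null, with $M = n(n-1)/2$ the number of
node pairs, i.e. a multiple-comparison-corrected per-edge level. Edges
require the correlation to *strictly exceed* the threshold; since the
threshold is positive, only positive correlations form connections. The
exact mapping from "5% spurious connections" to a quantile rule admits
more than one dialect; the one implemented here is recorded in the
`gmnet_threshold` object (alpha, per-edge level, null sample, seed) so a
run is fully auditable. Its calibration is verified empirically: on pure
i.i.d. noise images the retained-edge fraction stays well below alpha
(the acceptance script recomputes this number).

### Graph measures

Per network we report: size (node count), degree (mean node degree; the
total edge count is also emitted), connectivity density, mean
Watts–Strogatz clustering $C$ (degree-<2 nodes contribute 0), and
characteristic path length $L$ (mean shortest path over connected pairs;
pairs in different components are excluded, which keeps $L$ defined for
the near-connected graphs this method produces and degrades gracefully).
Normalisation against randomness uses degree-preserving double-edge-swap
reference networks (default 5, 10 attempted swaps per edge):

$$\gamma = C / \bar{C}_{\mathrm{rand}}, \qquad
  \lambda = L / \bar{L}_{\mathrm{rand}}, \qquad
  \sigma = \gamma / \lambda,$$

using ratio-of-means across references (the common convention; the
mean-of-ratios alternative differs only at second order). $\sigma$
declines toward 1 as a clustered network randomises. Regional summaries
average the nodal values — degree, local clustering, nodal path length
(mean finite distance to all other nodes), GM volume — over the nodes
carrying each atlas label; regions with no nodes are reported missing,
not zero. Standard graph algorithms are delegated to igraph; the test
suite checks them against independent brute-force implementations
(triangle enumeration, all-pairs BFS) exactly on all graphs up to
n = 200.

### Tau composites

Tau-PET SUVR is summarised over composite regions following the Braak
staging of neurofibrillary pathology: stage I–II (hippocampal formation),
III–IV (limbic/inferolateral temporal), V–VI (widespread neocortex), and
the temporal meta-ROI (union of stages I–IV), the primary tau measure.
Composites are volume-weighted averages,
$\sum_r \mathrm{SUVR}_r v_r / \sum_r v_r$, with region volumes taken from
the subject's label volume (voxel count × voxel volume) — the natural
reading of "volume-weighted" when only a parcellation is available.
Membership lists live in an editable YAML file so different atlas versions
can be supplied; the bundled mapping targets the synthetic 10-region
atlas.

### Statistics

Network outcomes are z-scored to the control group's mean and SD so
effect sizes are comparable across measures. Associations use ordinary
least squares adjusted for age, sex and total intracranial volume, with
connectivity density added for the higher-order measures (clustering,
path length, γ, λ, σ), which are known to depend on the number of edges.
Multiplicity is handled in two tiers mirroring the analysis design:
Benjamini–Hochberg FDR across the global outcomes, Bonferroni across
regions. Group comparisons use one-way ANOVA (continuous) and Pearson
chi-squared (categorical).

Mediation (tau → network topology → cognition) uses the linear
product-of-coefficients estimator: $a$ from
`mediator ~ treatment + covariates`, $b$ and $c'$ from
`outcome ~ treatment + mediator + covariates`, total effect $c$ from
`outcome ~ treatment + covariates`; ACME $= ab$, which in nested linear
models on the same sample equals $c - c'$ exactly (asserted to 1e-10 in
every bootstrap replicate), and proportion mediated $= ab/c$. Confidence
intervals are nonparametric percentile bootstrap over subjects,
deterministic given the seed. The proportion mediated is reported even
when outside [0, 1] but flagged, as it is unstable when the total effect
is near zero. Non-finite network measures (degenerate graphs) are treated
as missing and excluded case-wise — the analogue of excluding subjects
for network calculation failure — and exclusions are warned about, never
silent.

## The synthetic cohort generator

Real cohorts of this kind are not publicly downloadable, so the package
ships a seeded generator whose statistical structure matches what the
analysis assumes, making every downstream stage testable:

* **Causal chain.** Per-subject meta-ROI tau is drawn around its
  diagnostic-group mean (defaults 1.2, 1.5, 1.9, 2.5 SUVR for controls,
  preclinical, prodromal and dementia — a plausible span from
  amyloid-negative ageing to AD dementia). Tau drives a latent
  degradation $d = d_0 + s\,\max(0, \mathrm{tau} - \mu_{\mathrm{ctrl}})$,
  which mixes noise into the image; cognition is generated as
  `intercept + direct·tau + mediated·integrity + noise`, where integrity
  $e^{-d}$ is the *analytic* expectation of network preservation. Using
  the analytic mediator rather than the realised σ avoids circularity —
  generation never runs the network extractor — while the realised σ
  still tracks it.
* **Images.** A library of 27-voxel texture prototypes is drawn once per
  cohort (standard normal) and shared across subjects, so cross-subject
  network differences reflect only degradation. Each cube is
  $(1-m)\,\mathrm{prototype}(\mathrm{region}) + m\,\varepsilon$ with
  $m = 1 - e^{-d} \in [0, 1)$, clipped at zero. Regions cycle through
  the prototype library, so with fewer prototypes than regions some
  region pairs share a texture and correlate across region boundaries.
* **Atlas.** Contiguous slabs aligned to the cube grid, so each cube
  falls entirely in one region; with 10 regions the slabs carry the
  anatomical names used by the bundled Braak mapping.
* **Degradation calibration.** The defaults $d_0 = 0.2$,
  $s = 0.2$ per SUVR were fixed so that the dementia end of the tau range
  keeps networks in a non-degenerate regime: binarisation is a cliff, and
  past a point the within-region correlations drop wholesale below the
  threshold, collapsing density below 1% and making γ and σ erratic
  (reference networks of near-empty graphs have near-zero clustering).
  Cohorts in this literature show nearly constant density across disease
  stages, so a collapse regime would emulate the wrong phenomenon.
  Within the calibrated range, realised σ declines monotonically with
  degradation, which the recovery tests exploit.
* **Cognition.** Scores are left unbounded (no 0–30 clamping): the
  downstream models are linear and clamping would bias the recovery
  tests. The memory score mirrors the global score with opposite signs
  (recall errors rise with tau, fall with integrity).

What the generator does **not** emulate: real neuroanatomy and cortical
folding, scanner noise spectra, spatial autocorrelation beyond the cube
scale, partial-volume effects, PET physics, or longitudinal change.
Passing recovery tests therefore demonstrates that the pipeline's
machinery is correct and calibrated under its own assumptions — not that
those assumptions hold in any clinical data set.

## Problem sizes and numerical choices

The test suite runs at desk scale, chosen so the full suite completes in
minutes on one CPU: noise-calibration images at 30×30×30 voxels (1000
cubes, the default toy scale), recovery cohorts of n = 200 subjects at
15×15×15 voxels with 5 regions, mediation cohorts of n = 500 with 1000
bootstrap replicates, and pipeline-determinism cohorts of n = 72 at
12×12×30 with the full 10-region atlas. Clinical-scale images (~7000
nodes) use the same code paths; only the similarity matrix grows.

Other conventions fixed here because the method description leaves them
open: global degree is reported as *mean node degree* (the magnitudes
reported for cohorts of ~7000-node networks are only consistent with the
mean, not the raw edge count; both are emitted); nodal path length in
regional summaries is the mean finite distance from the node; threshold
ties are excluded (strict inequality); the permutation null shuffles
intensities *within* cubes (preserving each cube's histogram); reference
seeds for the randomised networks are derived from one master seed; and
all seeded code paths restore the caller's RNG state, so library calls
never perturb user scripts.

## Limitations

The binarisation dialect (quantile rule mapping "5% spurious" to a
per-edge level) and the discrete rotation realisation are defensible
choices among several; both are recorded in the run outputs. Weighted
networks, modularity/betweenness-type measures, voxelwise statistics and
longitudinal models are out of scope. The mediation estimator is the
linear bootstrap form; quasi-Bayesian intervals from other
implementations will differ slightly in small samples, though the point
estimates agree asymptotically.
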