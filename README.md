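# gmnet — single-subject grey-matter networks and tau-PET association analysis

`gmnet` implements an end-to-end pipeline for studying how tau pathology
relates to the organisation of structural brain networks in Alzheimer's
disease:

1. **Network extraction.** From one subject's 3D grey-matter intensity
   image, nodes are 3×3×3-voxel cubes; the similarity of two cubes is
   the maximum Pearson correlation over a discrete set of 96 rotations
   (multiples of 45° about all axes, realised on the voxel grid), so the
   measure ignores local cortical orientation:
   s<sub>ij</sub> = max<sub>r∈R</sub> cor(x<sub>i</sub>, r(x<sub>j</sub>)).
   The similarity matrix is binarised at a subject-specific threshold
   calibrated by a within-cube permutation null so that the expected
   fraction of spurious connections is at most α = 0.05.
2. **Graph measures.** Size, mean degree, connectivity density, mean
   clustering C, characteristic path length L, and the small-world
   normalisation against degree-preserving random reference networks:
   γ = C/C<sub>rand</sub>, λ = L/L<sub>rand</sub>, σ = γ/λ. σ declines
   toward 1 as a clustered network randomises. Regional summaries
   average the nodal values per atlas region.
3. **Tau composites.** Braak-stage composite ROIs (I–II, III–IV, V–VI)
   and the temporal meta-ROI (stages I–IV), as volume-weighted average
   SUVR over member regions.
4. **Statistics.** Network measures z-scored to the control group;
   OLS associations adjusted for age, sex, TIV (plus density for
   higher-order measures) with FDR (global) / Bonferroni (regional)
   correction; group comparisons; and bootstrap product-of-coefficients
   mediation (tau → network topology → cognition) with the exact linear
   identity c − c′ = a·b.
5. **Synthetic cohorts.** A seeded generator produces GM images with
   controllable texture degradation driven by tau, an atlas, covariates
   and cognition with known direct and mediated effects, so the whole
   pipeline is testable without clinical data.

It is aimed at neuroimaging methodologists who want a reproducible,
fully tested reference implementation of the grey-matter covariance
network approach and its downstream association machinery.

## Worked example

Simulate a 200-subject cohort (50 per diagnostic group, 15×15×15-voxel
images, 5 regions), extract one subject's network, and test the
tau–network associations:

```r
library(gmnet)

cfg <- cohort_config(n_per_group = c(control = 50, preclinical = 50,
                                     prodromal = 50, dementia = 50),
                     image_shape = c(15, 15, 15), n_regions = 5, seed = 42)
coh <- simulate_cohort(cfg)

net <- gmnet(coh$subjects[[1]]$gm_image, coh$atlas,
             n_permutations = 500, seed = 11)
print(net)
#> Single-subject grey-matter network
#>   nodes: 125 cube(s) of 3x3x3 voxels
#>   edges: 1427 (density 0.184)
#>   threshold: r > 0.8535 (alpha = 0.05, 500 permutations)

summary(net, n_reference = 5, seed = 21)$global
#> Global network measures
#>   size        125 nodes
#>   degree      22.83 (mean; 1427 edges)
#>   density     0.1841
#>   clustering  0.9683    path length 1.0487
#>   gamma 5.473  lambda 0.574  sigma 9.543  (5 reference networks)
```

This control subject's network is dense and highly clustered: cubes in
the same region share a texture prototype, so within-region correlations
survive the calibrated threshold (r > 0.85) almost everywhere.

Computing global metrics for all 200 subjects and regressing each
z-scored measure on meta-ROI tau SUVR (adjusted for age, sex, TIV, and
density for the higher-order measures; FDR across outcomes):

```r
run_association_suite(tab, c("density", "clustering", "path_length",
                             "gamma", "lambda", "sigma"), "tau_meta")
#>      outcome    beta    se        p p_adjusted
#>      density -10.017 0.263 2.26e-92   1.35e-91
#>   clustering  -1.614 0.450 4.22e-04   5.07e-04
#>  path_length   5.640 0.524 1.73e-21   5.18e-21
#>        gamma  -0.137 1.876 9.42e-01   9.42e-01
#>       lambda   4.492 0.443 1.14e-19   2.29e-19
#>        sigma  -2.562 0.395 7.01e-10   1.05e-09
```

The injected degradation is recovered: higher tau predicts lower
density, clustering and small-world coefficient (β = −2.56 z-units per
SUVR, p<sub>FDR</sub> ≈ 10⁻⁹). The betas are z-scored outcome per SUVR,
the effect-size convention used throughout.

Mediation of the tau–cognition association through small-world topology:

```r
tab$sigma_z <- zscore_to_reference(tab$sigma, tab$group == "control")
mediation_analysis(tab, "tau_meta", "sigma_z", "cognition_global",
                   covariates = c("age", "sex", "tiv"),
                   n_boot = 1000, seed = 31)
#> Mediation: tau_meta -> sigma_z -> cognition_global (n = 199, 1000 bootstraps)
#>   a (T->M)         -1.495  [-1.852, -1.074]
#>   b (M->Y|T)       -0.066  [-0.179, 0.071]
#>   c (total)        -1.935  [-2.223, -1.674]
#>   c' (direct)      -2.034  [-2.306, -1.696]
#>   acme (a*b)        0.099  [-0.116, 0.273]
#>   prop_mediated    -0.051  [-0.150, 0.058]
#>   note: proportion mediated unstable (total effect near zero or outside [0, 1])
```

Here the path a (tau lowers σ) is strong, but conditional on tau the
measured σ adds no information about cognition (b ≈ 0): in the
generator, cognition depends on the *expected* network integrity, which
is a deterministic function of tau, so the realised σ mediates nothing
beyond it — the analysis correctly reports an ACME compatible with zero.
Mediation estimator recovery itself (proportion mediated within ±0.05 of
the analytic value of a linear Gaussian model) is exercised in the test
suite on designs where the mediator carries independent variation.

A one-command version of the whole pipeline (simulate → networks →
metrics → composites → associations → mediation, with a reproducibility
manifest) is:

```r
res <- run_pipeline(pipeline_config(cohort = cfg), "results/run1")
```

A thin command-line wrapper with `simulate`, `network`, `metrics` and
`run` subcommands is installed at `inst/cli/gmnet.R`.

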