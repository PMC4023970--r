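# chiadiff

Bayesian classification of differential protein-mediated chromatin
interactions from two-sample ChIA-PET count data.

## The problem

ChIA-PET measures genome-wide chromatin interactions mediated by one
protein: each *fragment pair* (two genomic intervals joined by ligated
paired-end reads) carries one read-pair count per library. Counts mix
genuine mediated loops (*true pairs*) with random ligation collisions
(*false pairs*). Given two libraries — two cell types, two conditions —
`chiadiff` classifies every pair jointly into six categories: true in
both samples with decreased / equal / increased intensity (0/1/2), true
only in sample one (3), true only in sample two (4), or false in both
(5).

## The models

Counts are normalized to a common depth and screened at a threshold
`T` (default 2). Two routes classify the screened pairs:

* **One-Step model** — a six-component mixture whose components are
  jointly truncated products of two Poisson laws
  (`max(x1, x2) >= T`), one intensity pair per category, with order
  restrictions (`lam0_1 > lam0_2`, `lam2_1 < lam2_2`, every true
  intensity above the matching false intensity) tying components to
  categories. Each pair's mixture weights get a Dirichlet prior built
  from two covariates: the *marginal count* `mc` (sum of counts of all
  pairs sharing a fragment with the pair — within-sample dependency)
  and the *anchoring distance* `dist` (minimum over orientations of
  anchor-to-nearest-TFBS plus other-anchor-to-nearest-TSS). With
  `r_j = mc_j / dist` and directional marginal-count differences
  `dmc`, the prior routes mass toward true categories for pairs near a
  binding site and a promoter, and toward the differential categories
  along the direction of the marginal-count difference.
* **Two-Step pipeline** — step one fits, per sample, a two-component
  truncated-Poisson true/false mixture with a per-pair
  `Beta(eta * r_j, 1)` weight prior; step two resolves pairs true in
  both samples into 0/1/2 with a three-component mixture and Dirichlet
  priors from the marginal-count differences.

Inference is Metropolis-within-Gibbs MCMC in C++ (collapsed over the
per-pair weights; log-normal random walks for intensities and gamma
hyperparameters, reflected-uniform moves for the prior scale), fully
reproducible given a seed. A count-level simulator reproduces the
models' evaluation design — a 170-fragment library, 4,912 pairs,
6 : 3 : 1 sampling weights with dataset-two perturbations, 50,000
multinomial draws per dataset and ligation-success thinning — with known
per-pair truth, and evaluation utilities supply confusion matrices,
Cohen's kappa, per-sample type-I error / power and Gelman–Rubin
diagnostics. The methods vignette
(`vignettes/differential-chromatin-loops.Rmd`) documents the model,
priors, sampler and design choices.

## Worked example

Simulate the two-dataset study, fit the One-Step model, and score it
against the truth:

```r
library(chiadiff)
sim <- makeJointDataset(seed = 1)                       # 4,912 pairs
scr <- screenPairs(normalizeCounts(sim$pairs), T = 2, mode = "joint_max")
feats <- pairFeatures(scr, sim$tfbs, sim$tss)
fit <- runOnestep(scr, feats,
                  chainConfig(nIter = 100000, burnIn = 40000, seed = 1021))
truth <- sim$truth[match(pairIds(scr), pairIds(sim$pairs))]
confusionMatrix(truth, mapLabels(fit))
#>       classified
#> actual  0    1  2  3  4    5
#>      0  0   18  0  2  0    0
#>      1 26 1322 38  8 23   83
#>      2  0   15 22  0  3    0
#>      3  5    2  0 30  0    3
#>      4  0    3  0  0  2    5
#>      5  0    0  0  0  1 3179
cohenKappa(confusionMatrix(truth, mapLabels(fit)))
#> [1] 0.8928013
```

The rows are the designed truth, the columns the MAP classification:
false pairs (category 5, random collisions) are recovered almost
perfectly, the dominant unchanged-loop category 1 is recovered at
~88%, and the kappa of about 0.85–0.89 (seed-dependent) indicates
strong chance-corrected agreement. The same objects drive the Two-Step
route (`runTwostep`) and the per-sample true/false step alone
(`runMcdist`). File-based workflows are available through
`cmdSimulate()` / `cmdFit()` / `cmdEvaluate()` or the thin CLI at
`inst/cli/chiadiff.R`.

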