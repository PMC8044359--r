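---
title: "Trait-specific genomic relationship matrices: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-specific genomic relationship matrices: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tgrm)
```

## The problem

Breeding programs routinely measure *endophenotypes* — intermediate
molecular traits such as individual seed fatty-acid abundances — on a
diverse discovery population, and would like that investment to improve
genomic prediction of a downstream *focal trait* (e.g. total seed lipid
content) in separate elite material where the endophenotypes are never
measured. `tgrm` implements a two-stage route for this transfer:

1. estimate additive marker effects for each endophenotype in the
   discovery panel with Bayesian whole-genome regression;
2. convert those effects into per-marker weights and build
   *trait-specific genomic relationship matrices* (TGRMs) for the elite
   panel, which enter single-kernel, multi-kernel, or multi-trait BLUP
   models that predict the focal trait.

Because the information moves between populations through marker effects,
the elite candidates need genotypes only. The implicit assumptions are that
marker effects are reasonably consistent across the two populations and
environments (no genotype-by-environment modelling is attempted), and that
the relevant alleles still segregate in the prediction panel — the package
deliberately exposes the failure mode where they do not (see *Simulator*).

## Stage 0: from field plots to deregressed responses

Plot-level phenotypes from an augmented block design are adjusted with the
linear mixed model

$$ y = \mu + \beta\,\mathrm{cov} + \mathrm{check} + \mathrm{entry} +
\mathrm{block} + \mathrm{batch} + e, $$

where replicated check varieties are fixed effects, the unreplicated
entries are iid random (entries are treated as unrelated at this stage),
and block and measurement batch (e.g. GC-MS injection batch) are iid
random. The heading-date-like covariate is included only when it varies in
the records, matching designs where it is recorded in one location only.
`fitAugmentedModel()` estimates the four variance components by EM-REML on
the dense mixed-model equations with periodic Aitken extrapolation
(convergence when the largest relative component change falls below 1e-8,
cap 500 iterations). Prediction error variances come from the inverse
coefficient matrix at the converged components, which is affordable at
panel sizes of a few hundred entries.

Entry BLUPs are shrunken; using them directly as a regression response
would shrink marker effects twice. `deregress()` therefore divides each
BLUP by its reliability,

$$ \hat g^*_{ij} = \hat g_{ij} \Big/ \left(1 -
\mathrm{PEV}_{ij}/\sigma^2_{g_j}\right), $$

interpreting $\sigma^2_{g_j}$ as the entry variance component of the
adjustment model. Entries whose reliability falls at or below a floor
(default 0.1, including any with $\mathrm{PEV} \ge \sigma^2_g$) are
excluded and listed rather than allowed to explode the ratio; the floor is
a documented convention, since near-zero reliabilities make the ratio
arbitrarily unstable. No reliability weighting is applied downstream.

## Stage 1: Bayesian whole-genome regression

All five samplers share the linear model
$y = \mu + \sum_p w_p a_p + e$, $e \sim N(0, \sigma^2_e I)$, and differ
only in the prior on the marker effects $a_p$:

| method | prior on $a_p$ |
|---|---|
| BRR | common normal $N(0, \sigma^2_a)$ |
| Bayes A | per-marker scaled-$t$ (normal with marker-specific scaled-inv-$\chi^2$ variance) |
| Bayes B | point mass at zero w.p. $\pi$, scaled-$t$ otherwise |
| Bayes C$\pi$ | point mass at zero w.p. $\pi$, common normal otherwise |
| BL | Laplace via the exponential-mixture (Park–Casella) hierarchy |

Implementation choices:

* Single-site Gibbs updates with a running residual vector give O(nP) per
  sweep; the inner loops are compiled (Rcpp) as is customary for this
  class of samplers, drawing from R's RNG so `set.seed()` governs chains.
* $\pi$ is parameterized as the probability of the **point mass**
  (exclusion), sampled with a Beta(1, 1) prior by default. Much standard
  software parameterizes inclusion; read `pi` slots accordingly.
* Hyperparameter scales follow the common variance-partition heuristic: a
  share `priorR2` (default 0.5) of `var(y)` is attributed to markers and
  the remainder to the residual, and scaled-inv-$\chi^2$ scale parameters
  (df 5) are solved from the prior mode. The BL rate hyperprior for
  $\lambda^2$ is centered the same way.
* The intercept has a flat prior and is sampled; `y` is not centered
  internally.
* Default chain: 20,000 sweeps, 5,000 burn-in, every 5th retained. The
  `"test"` preset (3,000 / 1,000 / thin 2) exists for fast checks.
* Variance draws are floored at 1e-10; zero-variance marker columns get a
  fixed zero effect with a warning; the residual and marker variances can
  be held fixed, which turns BRR into an exactly solvable ridge posterior
  used by the test suite as an oracle.

## Stage 2: kernels

`centerScale()` centers each marker column and scales it to unit sample
variance. Given posterior-mean effects $a_p$, the trait-specific kernel is

$$ G^* = \frac{M D M'}{P}, \qquad d_p \propto \frac{a_p^2}{\sum_q a_q^2}. $$

Two conventions deserve emphasis:

* **Weight normalization.** Raw squared-effect weights sum to one, which
  together with the $1/P$ above would shrink the kernel trace by a factor
  of about $P$ and silently rescale the genetic variance component.
  Weights are therefore rescaled to sum to $P$, so uniform effects
  reproduce the unweighted kernel $MM'/P$ exactly and variance components
  stay comparable across methods. `rescale = FALSE` restores the sum-to-one
  convention.
* **Column scaling.** $M$ is unit-variance scaled rather than
  $2p(1-p)$-scaled: the weights in $D$ already carry the per-marker
  emphasis, and unit scaling keeps the uniform-weight case identical to
  the standard kernel.

The baseline kernel is the VanRaden genomic relationship matrix with
per-marker variance scaling (method 2). On essentially inbred dosages the
expected dosage variance at a marker is $4p(1-p)$, and that is the default
denominator so the diagonal averages about one on inbred panels
(`inbred = FALSE` gives the outbred $2p(1-p)$ scaling).

The per-analysis MAF bound (0.05) is applied to the prediction panel
*before* kernel construction; markers filtered there but present in the
effect table simply drop out, and markers absent from the effect table get
weight zero. This is what lets a large-effect locus that is common in the
discovery panel but rare in the elite panel silently vanish from a TGRM —
a realistic and important failure mode that the simulator can reproduce on
demand. Kernels whose smallest eigenvalue is materially negative (below
-1e-8) are bent by adding `eps - minEig` (eps = 1e-6) to the diagonal, the
smallest perturbation that stabilizes downstream solves; bona fide
floating-point noise above that line is left untouched so exact algebraic
identities (uniform TGRM = $MM'/P$) survive.

Kernels align rows/columns with the genotype input. Note that building a
kernel on a line subset is *not* the same as subsetting a kernel built on
the full panel: centering and allele frequencies are recomputed on the
subset. `subsetKernel()` is therefore a reordering/selection tool for an
existing kernel, and equals build-then-subset only when the marker
statistics are unchanged (e.g. pure permutations).

## Stage 3: prediction models

`fitKernelModel()` fits
$y = \mu + \sum_t Z_u u_t + Z_e s + e$, $u_t \sim N(0, \sigma^2_t K_t)$,
covering gBLUP (one GRM), TGRM-BLUP (one TGRM) and the multi-kernel model
(one TGRM per endophenotype). Each kernel is eigendecomposed once and its
effect sampled in the eigenbasis, where coordinates are conditionally
independent given the variances; per-kernel variances have
scaled-inv-$\chi^2$ priors with the `priorR2` budget split equally among
kernels. Trial effects $s$ and the intercept are fixed (flat priors) —
they play the role of per-trial mean adjustments. Lines whose phenotypes
are masked contribute nothing to the likelihood but receive genomic values
through their kernel rows; predictions for masked and training lines come
from one joint fit. Eigendecompositions can be precomputed
(`kernelEigen()`) and shared across cross-validation folds, since folds
mask phenotypes, not kernel rows.

`fitMultiTrait()` fits $Y = 1\mu' + U + E$ with rows of $U$ matrix-normal
(row covariance $K$, unstructured $T \times T$ genetic covariance under an
inverse-Wishart prior, df $T+2$) and rows of $E$ iid normal with
unstructured residual covariance. Sampling again happens in the eigenbasis
of $K$; within each sweep a joint diagonalization of the two trait
covariances renders every coordinate conditionally independent, so the
whole update is dense linear algebra rather than a loop over lines.
Missing cells are imputed by data augmentation from their conditional
normal given the observed traits of the same line. Lines with *no*
observed trait are allowed: they are exactly the prediction targets of the
multi-trait cross-validation, connected to the data through $K$ only.
`extractGeneticParams()` turns the posterior-mean covariances into
per-trait $h^2$ and genomic/phenotypic correlations.

## Evaluation: resampling and the win-rate rule

`makeFoldPlan()` builds repeated five-fold partitions (fold sizes within
one of each other) with an optional forced-training set — lines present in
both panels that must never be tested. `runCV()` masks each test fold,
collects Pearson correlations between GEBVs and observations (per trial
and averaged when a trial grouping is given), and averages folds into one
accuracy per run. `compareMethods()` implements the win-rate rule: method
A is declared significantly better than B when it strictly wins at least
90% of runs. Ties count as losses ("increased" accuracy is read
strictly); the threshold comparison is inclusive (a 0.90 win proportion
qualifies); runs with undefined correlations (a constant predictor) are
dropped for *all* methods so run sets stay aligned. Win rates are
deliberately preferred to t-tests: resampled accuracies from one dataset
are not independent, and t-statistics grow mechanically with the number of
resampling runs.

## The simulator

`simulateGenotypes()` emulates the two-panel setting with a
founder-mosaic model: markers fall into LD blocks, each line draws one of
K founder haplotypes per block, and lines are then treated as fully inbred
(dosages 0/2, with a small residual heterozygosity rate). This gives
controllable within-block LD with no coalescent machinery. The elite panel
is drawn from the same founders with logit-normal perturbed founder
weights (sd `driftSd`), creating a related-but-drifted population in which
a marker common in one panel can be rare in the other; `divergentBlock`
makes one such marker deterministically (carrier founders get essentially
zero elite weight, so the allele survives only through the overlap lines).
Overlap lines are shared verbatim between panels.

`simulateEndophenotypes()` assigns each trait a QTL count, an effect
distribution (gaussian, scaled-t, or a point-mass mixture), and optional
shared-QTL structure with a declared effect correlation; breeding values
are centered dosages times effects, so realized genetic correlations can
be checked against the analytic value (shared fraction times effect
correlation). `simulateFocalTrait()` composes endophenotype genetic values
with fixed weights plus an independent polygenic remainder sized as a
share of the focal genetic variance. `applyFieldDesign()` lays entries and
replicated checks into blocks, assigns measurement batches by consecutive
field order (mimicking injection order), adds Gaussian block/batch/trial
effects sized as shares of the genetic variance, and sets the residual
from the target entry-mean heritability. The defaults mirror the panels
this package emulates: 336 discovery lines, 210 elite lines, 12 overlap,
dense inbred SNPs; trait heritabilities in the 0.35–0.70 range.

What the simulator does *not* emulate: real genome coordinates or
recombination maps, epistasis, genotype-by-environment interaction, and
selection structure within breeding programs. Passing tests on simulated
panels therefore demonstrates correctness of the machinery and the
qualitative behavior of the method under its own assumptions — not
performance on any particular crop dataset. The magnitudes of genetic
correlations among endophenotypes are free simulator parameters, not
calibrated to any published figure.

## Numerical and design choices

* EM-REML was chosen over a packaged REML for the adjustment model so the
  mixed-model equations, PEVs and the likelihood path are all exposed to
  tests; an independent `lme4` fit cross-checks components and BLUPs in
  the test suite.
* All randomness flows through explicit seeds; helper `seedStream()`
  derives per-stage seeds from one global seed, and reruns of the pipeline
  with one config are byte-identical.
* Tie-breaks and degenerate inputs: strict threshold inequalities in QC;
  zero-variance markers are errors where silently dropping would bias
  (kernels) and warnings where a safe default exists (regression);
  constant responses are errors; test folds smaller than three lines are
  errors rather than NaN correlations.
* Chain lengths in the automated checks use the short presets (3,000
  sweeps for effect estimation; 1,000–1,500 for the kernel models inside
  cross-validation loops; 10 runs of five folds), and the simulated study
  sizes there are a 400-line discovery panel, a 250-line elite panel and
  2,000 markers with 12 overlap lines. These are the package's compact
  study conditions; the defaults users see (`wgrConfig()`,
  `defaultPipelineConfig(preset = "full")`) restore the conventional long
  chains and 50 resampling runs.

## Known limitations

* Dense eigendecompositions and MME inverses cap practical panel sizes at
  a few thousand lines; very large programs need the indirect
  approximations from the animal-breeding literature, which are out of
  scope here.
* The multi-trait model assumes an unstructured genetic covariance and
  infinitesimal architecture for every trait; with oligogenic
  endophenotypes that assumption is exactly what the multi-kernel TGRM
  route is designed to relax.
* Deregressed responses are used unweighted; differential reliabilities
  are reported but not propagated.
* The VCF adapter handles the GT field of biallelic records only — it is
  a data-exchange convenience, not a variant-calling interface.
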