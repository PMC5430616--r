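---
title: "Models and methods behind admixscan"
author: "admixscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A cohort with recent tri-continental admixture mixes, within every genome,
allele frequencies of three latent ancestral populations.  Two quantities
are needed before any downstream genetics: per-individual ancestry
proportions `Q` (samples × K) and per-component allele frequencies `P`
(K × SNPs).  With those in hand, per-SNP differentiation statistics on the
*components* can scan for loci whose focal ancestry drifted or was selected
away from the others — differentiation that is invisible in the pooled
cohort frequencies.

# The admixture model

Genotypes are diploid A1-allele dosages.  The model is the standard
binomial independent-loci admixture likelihood:

$$ g_{ij} \sim \mathrm{Binomial}\!\left(2,\; f_{ij}\right),\qquad
   f_{ij} = \sum_k q_{ik}\, p_{kj} . $$

Assumptions worth stating: loci are independent (hence the LD-pruning step
before fitting), individuals are unrelated, and each individual's two
alleles at a locus are independent draws from its personal mixture
frequency.  Missing genotypes contribute nothing to the likelihood.

## Fitting

`fit_unsupervised()` and `fit_supervised()` maximize the likelihood by EM.
The E/M updates are the classical ones for this model; because plain EM
crawls near the optimum, each iteration also proposes an over-relaxed step
`x0 + s (x1 − x0)` along the EM direction (projected back onto the simplex
and the frequency box) and keeps it only if it improves the likelihood, so
the accepted log-likelihood sequence is non-decreasing by construction.
The step length `s` grows to at most 16 while extrapolations keep
succeeding and shrinks back to 2 when they fail.

Convergence is declared when the relative log-likelihood change drops
below `tol`.  The default is `tol = 1e-7`: with cohort-scale likelihoods of
magnitude 1e5–1e6 this corresponds to absolute changes of order 0.01–0.1
log-units; looser values (e.g. 1e-4 relative) stop unsupervised fits long
before the ancestry estimates stabilize.  Restarts (default 3 seeds, best
likelihood kept) guard against local optima; the seed of every fit is
recorded in the result.  Component allele frequencies are clamped to
`[1e-6, 1 − 1e-6]` so that a discordant genotype can never produce an
infinite log-likelihood; boundary frequencies print as 0.000/1.000 after
rounding.

In supervised mode the `Q` rows of designated proxy samples are pinned to
pure indicator vectors through every update — the proxies *define* the
components.  Panel sizes are expected to be equal across ancestries
(unequal sizes only warn) because unequal panels weight the likelihood
toward the larger panel's ancestry.

## Identifiability and why supervision matters

On a cohort in which every individual is substantially admixed (a
concentrated Dirichlet), the decomposition is weakly identified: many
rotations of `(Q, P)` fit almost equally well, and unsupervised estimates
are biased even at the true K.  Near-pure individuals anchor the
components.  This is visible in the package's own simulations — with the
default concentration the unsupervised mean absolute error of `Q` plateaus
around 0.1 while a supervised fit with 30-sample panels reaches ~0.03 on
the same data — and it reproduces the rationale for supervised estimation
with proxy panels.  The paired supervised-vs-unsupervised comparison in the
acceptance checks therefore fits the unsupervised model on the admixed
cohort alone (the realistic unsupervised workflow) and the supervised model
on cohort plus panels.

## Choosing K

`cross_validate_K()` partitions non-missing genotype *cells* into folds
(default 10), masks one fold, refits, and scores masked cells by squared
error against the prediction `2 f_ij`.  Squared error is used as the
held-out loss; the cross-validated error is minimized at the generating K
on simulated cohorts provided the cohort contains identifiable structure
(the packaged experiments include the nearly-pure pool individuals in the
CV cohort for this reason).

## Extending P to un-pruned SNPs

Fits use the LD-pruned SNP set, but scans want every QC-passing SNP.
`component_freqs_given_Q()` maximizes each SNP's likelihood over its K
component frequencies with `Q` held fixed — a per-locus EM that runs all
loci in parallel.  This is the package's explicit reconstruction of
"jointly fitted SNP allele frequencies" on an arbitrary SNP set.

# Differentiation statistics

`fst_param(p1, p2)` is Hudson's Fst with frequencies treated as known
parameters.  When both frequencies are 0 (or both 1) the statistic is 0 by
convention: the populations are identical at that locus.  This convention
is forced by published per-SNP tables in which loci with two monomorphic
populations still carry a finite branch Fst.

`fst_sample()` is the Bhatia/Hudson estimator with finite-sample
correction; its per-locus ratio may legitimately be negative and is never
truncated.  Genome-wide estimates aggregate as a ratio of averages
`ΣN̂/ΣD̂`, never as a mean of per-locus ratios.  Confidence intervals are
percentile bootstrap over loci (default B = 10,000).  Note what the loci
bootstrap targets: variability of the genome-wide summary under re-drawing
of *loci*, so its CI covers the model (super-population) Fst — for two
Balding–Nichols populations at drift F, exactly F — rather than the
realized value on the finite locus set.

The focal branch length at a SNP is `LSBL = (F12 + F23 − F13)/2` with
population 2 focal; the three branch lengths sum to `(F12+F23+F13)/2` and
two branches sum exactly to their pairwise Fst.  `pbs()` applies the same
construction after `T = −log(1 − Fst)`; the two statistics rank loci almost
identically when no pairwise Fst approaches 1, which the package verifies
by simulation (Spearman > 0.99 below Fst 0.9).

When comparing a fitted component against a genotyped reference population,
the parameter form is used for published-table recomputation (it is what
reproduces those printed values), while the sample-corrected form is
available when real counts exist; for an admixture *component* of an
N-sample cohort with mean focal proportion `q̄`, the documented effective
haploid count is `2 N q̄`.  The mode is always explicit.

Scan ranking breaks ties by (chromosome, position).  Top-k SNPs group into
regions by single linkage at 1 Mb — a merge distance chosen because it
reproduces both published top-10 groupings (5 regions for the branch scan,
8 for the Asian comparison); it is configurable.

# Proxy selection

References are ranked by signed coordinate on a principal component
(`rank_by_pc()`, stable with lexicographic tie-breaks), panels take the
`n` most extreme candidates per pole, and a candidate appearing at two
poles goes to the pole where its rank is more extreme.  `assign_poles()`
derives the pole→ancestry mapping from *labeled* candidate samples (their
centroids in standardized PC space); the labels must come from the caller —
automatic continental labeling is out of scope.  `proxy_size_curve()`
bootstraps loci (panels fixed) to estimate the standard error of the
cohort-mean ancestry as a function of panel size; resampling loci (rather
than samples) matches the locus bootstrap used for Fst CIs and keeps the
panel definition fixed across replicates.  The SE reported is of the
cohort-mean ancestry vector (mean over components; per-component values are
also returned) — an alternative averaging of per-individual SEs would
answer a different question.

# PCA geometry

`pca_fit()` standardizes dosages per SNP by the defining samples' mean
`2p̂` and the binomial scale `sqrt(2p̂(1−p̂))` (the EIGENSOFT convention;
the scaling can be switched off), excludes SNPs monomorphic in the defining
set, imputes missing dosages to 0 after centering, and takes the SVD of the
defining-sample matrix only.  Other samples are projected with the stored
means/scales.  Out-of-sample projections shrink toward the origin and no
correction is applied — rankings by extremity, which is all the proxy
selection needs, are unaffected.  Loading signs follow the
largest-magnitude-element-positive convention for reproducibility.

# The synthetic-cohort generator

`make_study()` draws, from a single seed with fixed per-stage offsets:

* per-locus ancestral frequencies `p_anc ~ U(0.05, 0.95)`;
* per-ancestry drifted frequencies
  `p_kj ~ Beta(p_anc(1−F_k)/F_k, (1−p_anc)(1−F_k)/F_k)` (Balding–Nichols:
  mean `p_anc`, variance `F_k p_anc(1−p_anc)`), default `F_k = 0.15` — a
  continental-scale divergence;
* Dirichlet ancestry proportions with mean 0.57/0.20/0.23 and
  concentration 8, emulating a cohort with predominant European ancestry
  and broad individual ranges;
* proxy-pool individuals `Q = (1−c)·indicator + c·Dirichlet` with
  contamination `c` (default 0);
* binomial genotypes, optional uniform missingness.

Outlier loci are *overwritten* (not shifted) to a target frequency in one
ancestry so recovery tests have unambiguous truth; emulating the published
frequency pattern (focal ancestry near 0.9, others near 0) additionally
requires choosing loci whose ancestral frequency is low, which the packaged
experiments do by selecting injection sites with `p_anc < 0.3`.

What the generator does **not** emulate: linkage disequilibrium (loci are
exchangeable and independent — matching the inference model's assumption,
so these tests validate the estimator, not robustness to LD), realistic
site-frequency spectra, genotyping error, relatedness, or sex chromosomes.
Passing recovery tests on this generator therefore demonstrates
correctness of the estimators under their own model, not performance on
array data with residual LD.

# Problem sizes and numerical choices in the packaged experiments

The validation experiments run at desk scale, chosen once as the smallest
sizes at which each property is statistically comfortable: supervised
recovery on 500 admixed samples × 3,000 SNPs with 30 proxies per ancestry
(mean |Q̂−Q| well under 0.05); ten paired 150 × 800 replicates for the
supervised/unsupervised contrast; ten 80-admixed + 60-pool × 400-SNP
replicates for cross-validated K selection; 200 datasets of 2,000 loci with
B = 2,000 bootstrap replicates for CI coverage; and a 4-sample × 3-SNP
K = 2 instance for the exhaustive grid-search cross-check of the EM
optimum.  That instance was constructed so its maximum-likelihood solution
is exactly representable on the 0.02 grid (the saturated fit
`q = (1, ½, 0, ½)`, `p = (1, ½, 0)/(0, ½, 1)` reproduces every observed
genotype frequency), which makes the reference value sharp: the grid
optimum, the closed-form saturated likelihood and the EM optimum must all
coincide to well within the 1e-3 comparison tolerance.

Other numerical decisions: dosages count the A1 (first/reference) allele
everywhere; coordinates are 1-based physical positions; strand-ambiguous
A/T and C/G SNPs are dropped when intersecting datasets (the safe
convention when strand provenance is unknown); LD-pruning uses a 50-SNP
window advancing by 5 with the lower-MAF member of an offending pair
dropped first (ties: later map position) — window and step are conventional
choices, configurable; bootstrap replicates inside the proxy-size curve use
a reduced EM tolerance (1e-5) for speed while final fits use the full
tolerance.

# Known limitations

* Unsupervised fits on fully admixed cohorts are weakly identified (see
  above); interpret their `Q` only through the supervised route or with
  anchor individuals present.
* The EM (even accelerated) is a desk-scale optimizer; genome-scale fits
  (hundreds of thousands of SNPs) will be slow compared to specialized
  quasi-Newton implementations.
* `component_freqs_given_Q()` conditions on a point estimate of `Q`;
  uncertainty in `Q` is not propagated into the per-SNP frequencies or the
  scan statistics.
* The scan is a ranking exercise — no per-SNP significance is attached, by
  design.
* VCF support reads the GT field only; indels and multi-allelic records
  are skipped.
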