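---
title: "Models and methods for two-transect hybrid-zone analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for two-transect hybrid-zone analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hzclines` implements the statistical machinery of a replicated hybrid-zone
study: two parental bird species meeting along two geographically remote
transects, genotyped at genome scale, analysed for hybrid ancestry,
per-locus introgression, geographic cline shape, Z-linked inversions and,
by forward simulation, for the relative roles of selection strength and
zone movement. This vignette explains each model, its assumptions, the
defaults, and what the synthetic test system does and does not establish.

## Hybrid index

The hybrid index *h* of an individual is the proportion of its allele
copies at species-diagnostic loci that derive from the P1 parental species.
Diagnostic loci are SNPs fixed for alternative alleles between the two
allopatric reference panels (per-SNP Weir–Cockerham F_ST = 1 after
missing-data exclusion), thinned to one SNP per 10 kb window to reduce
physical linkage (`select_diagnostic()`). Given *n* observed allele copies
of which *k* are P1-derived, each copy is modelled as P1 with probability
*h* independently; the prior is Beta(0.5, 0.5) (Jeffreys; configurable).
`estimate_hybrid_index()` samples the posterior by random-walk Metropolis
on logit(*h*), adapting the proposal during burn-in to a 20–50% acceptance
rate, with defaults of 5,000 burn-in and 10,000 retained iterations. The
posterior is conjugate (Beta), which the test suite exploits as an exact
oracle: the MCMC mean must match (k + ½)/(n + 1).

Hemizygous entries — female Z loci — contribute a single allele copy to the
likelihood rather than being excluded. Interspecific heterozygosity is the
fraction of an individual's diploid diagnostic loci with one allele from
each species; F1 hybrids sit at the apex of the triangle plot
(heterozygosity 1, *h* = 0.5), and the classifier (`classify_hybrid()`)
uses that definition with thresholds derived from the least-admixed filter
(*h* < 0.1 or > 0.9, heterozygosity < 0.1), all configurable.

## Genomic clines

For a diagnostic locus, the probability that an allele copy carried by an
individual with hybrid index *h* is P1-derived is modelled as

  phi(h) = logistic( v · (logit h − logit c) ),

with steepness *v* > 0 and centre *c* in (0, 1). At *v* = 1, *c* = 0.5 the
locus tracks the genome-wide average (phi = *h*); *v* > 1 is a steeper,
sigmoidal transition indicating introgression restricted relative to the
genomic background. `fit_genomic_cline()` samples (ln *v*, logit *c*) by
Metropolis–Hastings under independent Normal(0, 1.5²) priors, treating the
per-sample *h* as fixed (no propagation of hybrid-index uncertainty — a
deliberate simplification over a joint model). The two-sided tail
probability p_v = 2·min(Pr(ln v > 0), Pr(ln v < 0)) is computed from the
retained draws, and a locus is called *restricted* when the posterior mean
*v* exceeds 1 with p_v < 0.05. No multiple-testing correction is applied by
default, mirroring the per-locus α = 0.05 outlier rule; the posterior
*median* of *v* is also reported because the right-skewed posterior
inflates the mean for weakly informed loci.

Two degenerate designs deserve note: samples with *h* only at 0/1 carry no
information about *v* (the interval spans 1), and a locus monomorphic among
admixed samples yields a wide interval with a warning.

## Geographic clines

Samples are projected onto the transect line by orthogonal projection in a
local equirectangular plane (longitudes scaled by cos of the line's mean
latitude) — adequate below ~5° of latitude span; distances are km from the
line's start. The ancestry proxy is PC1 of the thinned genotype PCA,
affinely anchored so the allopatric panel means map to 0 and 1 (resolving
PC1's sign ambiguity); a hybrid index passes through essentially unchanged.

The cline model is the two-parameter sigmoid
S(x) = 1/(1 + exp(−4(x − c)/w)) — *w* is the inverse of the maximum slope —
with optional exponential tails. For x ≤ c − δ_L the left tail is

  S(c − δ_L) · exp( 4 τ_L (x − (c − δ_L)) / (w (1 + exp(−4 δ_L / w))) ),

continuous at the junction, with δ the distance from the centre where the
tail begins and τ in (0, 1] the tail-slope ratio; the right tail is the
mirror image. Five configurations are fitted: none, left, right, mirror
(shared δ, τ) and both (independent tails), with pmin/pmax free throughout
— a deliberate collapse of the larger model matrix some cline software
exposes. Observations are Gaussian around the cline with a single estimated
residual SD (homoscedastic; the observation model is this package's
choice). Fitting is componentwise adaptive random-walk MH; AICc is computed
from the maximum log-likelihood visited and the parameter count (5, 7, 7,
7, 9), ties breaking toward fewer parameters; the width support interval
collects widths of all draws within two log-likelihood units of the
maximum. Cline orientation (rising or falling) is auto-detected from the
rank correlation of x and y, so reversing a transect reflects the centre
and leaves the width unchanged.

## Differentiation statistics

Per-SNP F_ST is Weir & Cockerham's (1984) θ̂ from the two-population
variance components a, b, c, computed over diploid entries (hemizygous Z
entries are excluded); negative estimates are reported, not clipped, and
loci monomorphic across both populations are undefined (NA), not zero.
Windowed F_ST uses 25 kb windows sliding by 5 kb, anchored at position 1
(anchoring is configurable; the alternative of anchoring at the first SNP
is not the default), and is the *ratio of sums* Σa / Σ(a+b+c) — not the
mean of per-SNP ratios. Per-individual inbreeding F is the
method-of-moments estimator F = (O_hom − E_hom)/(L − E_hom) with
E_hom = Σ_l (1 − 2 p_l (1 − p_l) n_l/(n_l − 1)); inversion heterozygotes
show strongly negative values over the inverted region, which is used as a
validation statistic. Mitotypes are assigned by nearest reference-clade
centroid in the top-2 PC plane of the mtDNA variants, ties breaking
deterministically toward the earlier clade label.

## Inversion detection

Large polymorphic inversions suppress recombination and segregate as three
multilocus haplotype states, visible as three PCA clusters and as stepwise
blocks of SNP–PC association. `snp_pc_association()` scores each SNP by a
likelihood-ratio test of a logistic model of PC-halves membership (above /
below the median of each of the top-k PCs) on genotype; the score is the
max over PCs of −log10 p. `detect_boundaries()` fits an exact two-
changepoint least-squares segmentation of the score track (implemented here
as a vectorized O(n²) search; the region is called only if its mean score
exceeds the outside mean 3-fold and spans ≥5% of the chromosome). Length is
reported as (end − start)/10⁶ Mb to one decimal — matching the convention
of subtracting printed breakpoints directly, not end − start + 1. One
region is called per invocation; nested or multiple inversions are found by
re-running on masked input (the higher-mean region wins, with a warning).

Haplotype groups are assigned by a 1-D Gaussian mixture on PC1 of the
region (BIC over 1–3 components, equal-variance model — robust when the
heterozygote group is very small), the middle cluster labelled AB and
validated against mean individual F (flagged if AB is not lowest). A
practical caveat demonstrated in the analysis scripts: the association
*scan* needs samples without genome-wide admixture structure (the
within-species, allopatric setting), otherwise every diagnostic locus
associates with PC1; the haplotype *grouping*, by contrast, works on all
samples because the block dominates the local PCA.

## Tension-zone simulation

The forward model is a 1-D stepping stone: D demes of N diploids, L
unlinked selected loci plus `L_neutral` unlinked neutral loci, initialized
as a secondary-contact step function. Each generation: (1) migration — each
individual moves to a uniformly chosen adjacent deme with probability m,
reflecting at the edges; (2) viability selection — fitness
(1 − s)^(# heterozygous selected loci) × (1 − s_env)^(mismatch), where
mismatch is the fraction of selected allele copies not matching the side of
an environmental boundary at b(t) = b(0) + r·t; (3) soft selection —
exactly N offspring per deme, parents drawn with probability proportional
to fitness (with replacement), free recombination. Zone movement therefore
acts only through the ecotonal term: with s_env = 0 the r axis is inert by
construction. The neutral case reduces, at m = 0, to independent
Wright–Fisher demes, which the tests exploit as a drift-variance oracle.

The steepness experiment (`run_experiment_grid()`) measures, per (s, r)
cell, the mean posterior-median genomic-cline steepness of the selected
loci against the genome-wide hybrid index computed from *all* loci —
the same construction as the empirical pipeline, where the background is
dominated by loci introgressing freely. This design choice matters: if the
background were the average of the selected loci alone, exchangeability
would force v = 1 at every selection strength and the experiment would be
vacuous. With a neutral-dominated background, v̄ is ≈1 at s = 0 (slightly
above 1 at desk scale, because admixture linkage disequilibrium among a
finite locus set makes the conditional expectation of any one locus
slightly steeper than the noisy background — an effect that vanishes as the
background panel grows), rises steeply with s, and responds only weakly to
r at matched grid spans — the qualitative ordering the simulation study is
designed to probe. Zone width is measured by fitting the no-tail geographic
cline to the selected-loci ancestry profile; widths below ~2 demes are at
the lattice resolution and correspondingly noisy, so equilibrium checks
average the width over several recorded generations and replicate seeds.

## The synthetic data generator

`synth_config()` fixes the study conditions for all tests and analysis
scripts: allopatric panels of 15 and 11 (the sampling structure of the
system this package emulates), transects of ~100–130 samples, 800–1,000
diagnostic loci on a 10-kb grid across two autosomes and a Z chromosome,
background loci with Balding–Nichols drift (F = 0.05), genome-wide ancestry
drawn as Beta around the sigmoid 1/(1 + exp(−4(x − c)/w)) with
concentration 50, an mtDNA pseudo-chromosome ("MT", haploid, three clade
patterns with 1% flip noise), and an optional Z-linked inversion block that
overrides diagnostic genotypes with one of three non-recombined states
drawn per sample. Allele copies are independent given the ancestry q (no
linkage outside the inversion block) — adequate for estimators that assume
thinned, unlinked loci, but it means the fixtures cannot probe linked
selection, local ancestry tracts, or realistic LD decay; passing tests
establish estimator correctness and calibration under the stated model,
not robustness to those violations. The planted inversion is deliberately
independent of ancestry so that the detection scan has signal on a flat
background; real species-diagnostic inversions are ancestry-associated,
which is why the analysis scripts exclude the region from the hybrid-index
panel.

## Numerical choices and problem sizes

All MCMC samplers are adaptive random-walk Metropolis with acceptance
targeted to 20–50% during burn-in; per-locus seeds are derived
deterministically from a user seed, and every generator and simulator is
exactly reproducible from its seed. Likelihood evaluations clamp
probabilities to [1e−12, 1 − 1e−12]. Window arithmetic is fixed-origin
(first window starts at position 1) with the lowest-position SNP retained
per thinning window — both deterministic tie-breaks. The test and analysis
problem sizes (hundreds of loci, 100–300 samples, demes of 50–150, grids of
a few (s, r) cells with 2 replicates) were chosen as the smallest scales at
which the stochastic properties under test are stable; they are stated in
the scripts alongside the checks that use them.

## Known limitations

Parental panels are treated as fixed (no joint estimation of panel allele
frequencies); hybrid-index uncertainty is not propagated into cline fits;
the geographic cline set omits the three-part stepped-cline variant; the
inversion scan calls one region per invocation and does not attempt
breakpoint confirmation; the simulator has no 2-D geography, assortative
mating, or explicit climate coupling.
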