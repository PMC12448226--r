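# hzclines

Analysis toolkit for avian hybrid zones sampled along replicate geographic
transects. Where two parental species meet and hybridize, the transition in
ancestry along a transect (a **geographic cline**), the transition of each
locus against genome-wide ancestry (a **genomic cline**), and the behaviour
of recombination-suppressed **Z-chromosome inversions** together describe
how strongly, and where in the genome, reproductive barriers act. `hzclines`
implements that full pipeline for biallelic SNP data, plus a forward-time
tension-zone simulator for asking whether selection strength or the rate of
climate-driven zone movement better explains differences in introgression
between transects. A synthetic-data generator reproduces the statistical
structure of such a study (parental panels, admixed transects, mtDNA
clades, a planted inversion), so everything is testable without external
data.

## The models in brief

- **Hybrid index** *h*: proportion of an individual's allele copies at
  species-diagnostic loci (per-SNP Weir–Cockerham F_ST = 1 between
  allopatric panels, thinned to 1 SNP / 10 kb) that derive from species P1.
  Estimated by MCMC under a binomial likelihood with a Beta(½, ½) prior
  (5,000 burn-in / 10,000 retained by default). Interspecific
  heterozygosity is the fraction of diagnostic loci with one allele from
  each species; an F1 has heterozygosity 1 and *h* = 0.5.
- **Genomic cline**: phi(h) = logistic(v·(logit h − logit c)); *v* = 1 is
  the genome-wide average transition, and a locus with posterior mean
  *v* > 1 and two-sided MCMC tail probability p_v < 0.05 is called
  restricted.
- **Geographic cline**: S(x) = 1/(1 + exp(−4(x − c)/w)) with optional
  exponential introgression tails (five tail configurations), fitted by
  Metropolis–Hastings with AICc model selection and two-log-likelihood
  width support limits.
- **Inversion scan**: per-SNP association with local PCA coordinates,
  exact two-changepoint segmentation of the score track, length in Mb as
  (end − start)/10⁶, and three-state haplotype-group assignment validated
  by individual inbreeding F (heterozygotes lowest).
- **Tension-zone simulation**: stepping-stone demes, underdominant
  selection of strength *s*, ecotonal selection tracking a boundary moving
  at *r* demes/generation, neutral background loci; the experiment grid
  measures mean genomic-cline steepness and zone width per (s, r).

## Worked example

```r
library(hzclines)

cfg <- synth_config(seed = 7)              # panels + a 120-sample transect
pan <- make_parental_panels(cfg)
tra <- make_transect(cfg)

nuclear <- which(pan$gm$loci$chrom != "MT")
p0 <- pan$samples$sample_id[pan$samples$population_label == "allopatric-P0"]
p1 <- pan$samples$sample_id[pan$samples$population_label == "allopatric-P1"]
panel <- select_diagnostic(gm_subset(pan$gm, p0, loci = nuclear),
                           gm_subset(pan$gm, p1, loci = nuclear))
nrow(panel)
#> [1] 1000

hi <- estimate_hybrid_index(tra$gm, panel, burn = 500, keep = 1000, seed = 1)
range(hi$h_mean)
#> [1] 0.0002036486 0.9997931649
mean(abs(hi$h_mean - tra$samples$q_true))   # recovery of the generating ancestry
#> [1] 0.002805483
```

The hybrid indices span the full parental-to-parental range and track the
generating ancestry to within ~0.003 — the transect is a continuum of
backcrossed ancestry, exactly the structure the classifier and the cline
fits downstream consume.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data,
writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | two transects (east: narrow cline; west: wide), planted Z inversion, mtDNA, toy gene models |
| `02_hybrid_indices.R` | diagnostic panel, hybrid indices, heterozygosity, hybrid classes |
| `03_genomic_clines.R` | per-locus (v, centre) fits and the v > 1, p < 0.05 outlier rule |
| `04_geographic_clines.R` | PC1 ancestry proxy, transect projection, five-model AICc selection |
| `05_fst_scan.R` | least-admixed filter, windowed Weir–Cockerham F_ST (25 kb / 5 kb) |
| `06_inversion_scan.R` | Z-chromosome association track, boundaries, haplotype groups, F validation |
| `07_zone_simulation.R` | (s, r) experiment grid: steepness and width per cell |
| `08_report.R` | cross-transect overlaps, chromosome shares, gene matching, region shares |

Run them in order, e.g. `for f in analysis/0*.R; do Rscript "$f"; done`.
On the default seeds the geographic fits recover the generating clines
(east: centre 55.2 km, width 10.4 km against a 55/10 truth; west: 45.2 km
and 25.8 km against 45/28), the genomic-cline outlier rule calls ~5% of
neutral loci (its nominal rate), both transects recover the planted
inversion boundaries with three haplotype groups and the heterozygote group
lowest in F, and the simulation grid shows mean steepness rising from ~1.1
(s = 0) to ~2.3 (s = 0.2) while varying the movement rate over the same
span shifts it by ~0.1.

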