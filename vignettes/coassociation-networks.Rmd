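---
title: "Co-association networks for multivariate genotype–environment association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-association networks for multivariate genotype–environment association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coassocnet)
```

## The problem

Local adaptation in widespread species is often driven by several distinct
aspects of the environment at once: aridity, winter cold, geography. A
standard genotype–environment association (GEA) scan tests each SNP
against each environmental variable separately and returns a long list of
locus–variable pairs. That list answers "which SNPs associate with
something", but not the question that matters for understanding the
architecture of adaptation: *how many distinct environmental factors are
loci actually responding to, and which loci respond to the same one?*

`coassocnet` answers that question with **co-association networks**. Each
candidate SNP is summarized by its *association profile*: the vector of
its rank correlations with every measured environmental variable. Two
SNPs responding to the same selective factor have nearly identical
profiles — wherever that factor is strong, both alleles shift together —
even when the factor itself was never measured. Clustering and graphing
profiles therefore groups loci by selective environment, not by genomic
position or by which single variable happened to score highest.

## The pipeline

### 1. Data and associations

The entry objects are a `snp_table` (individual genotypes, 0..ploidy
copies of the derived allele, with SNP-to-contig annotation and
individual-to-population mapping), from which `population_frequencies()`
produces a `freq_matrix` (populations × SNPs), and an `env_matrix`
(populations × variables). `spearman_matrix()` computes the association
layer: Spearman's rho and its P value per SNP × variable cell, using the
t approximation for 10 or more populations and the exact permutation
distribution below that. Rank correlation is used throughout because
allele-frequency clines need not be linear in any measured variable.

Population structure inflates these raw associations: neighboring
populations share history, so any spatially autocorrelated variable
correlates with any drifting allele. The corrected layer
(`corrected_associations()`) estimates the population covariance from
standardized frequencies (`estimate_pop_covariance()`), whitens the
frequency matrix with the inverse Cholesky factor
(`whiten_frequencies()`), and attaches a conjugate g-prior log10 Bayes
factor per cell (`approx_log10_bf()`): a closed-form, deterministic
analog of MCMC-based structure-corrected GEA. The closed form
`BF10 = (1+g)^(-1/2) (1 - g/(1+g) R²)^(-n/2)` with `g = n` is validated
in the test suite against direct numerical integration of the marginal
likelihoods.

### 2. Top candidates

Candidate detection is deliberately two-stage and conservative:

* **Genes.** `flag_outlier_snps()` marks a SNP for a variable when its
  |rho| strictly exceeds the genome-wide 0.99 quantile for that variable.
  `top_candidate_genes()` then computes, per contig with n SNPs and k
  outliers, the binomial tail P(X ≥ k | n, p̄) with p̄ the genome-wide
  outlier fraction. Because SNPs within a contig are correlated, this is
  an enrichment *index*, not an exact P value; the restrictive default
  cutoff (1e-9) compensates.
* **SNPs.** Within candidate genes, `top_candidate_snps()` keeps SNPs
  passing a **dual criterion** in at least one variable: uncorrected
  Spearman P below the Bonferroni cutoff `0.05 / (n_snps × n_envs)`
  *and* structure-corrected log10 BF above 2. The two criteria fail in
  different ways — the raw P is vulnerable to structure, the corrected BF
  to covariance misestimation — so their intersection is robust. On
  neutral-only simulations (below), the dual criterion yields zero false
  positives in all three demographic scenarios while the
  Bonferroni-only criterion does not.

### 3. Networks, groups, pleiotropy

`association_distance_matrix()` computes Euclidean distances between
signed association profiles. Two views are built on it:

* `ward_cluster_groups()`: Ward.D2 hierarchical clustering cut into k
  broad groups (default 4, a visualization convention — e.g. Aridity /
  Freezing / Geography / Multi).
* `build_coassociation_graph()`: an edge joins two SNPs when their
  profile distance is strictly below 0.1 (in rho units across 22
  variables, this demands near-identical profiles). Connected components
  are the **co-association modules**, each interpreted as one distinct
  selective factor. `threshold_stability()` reports how modules merge or
  fragment as the threshold moves ±0.05, and
  `sweep_edge_threshold()` chooses a threshold on simulated data by
  maximizing mean selected-locus degree minus mean neutral-locus degree.

`pleiotropy_table()` gives per-gene proportions of candidate SNPs across
modules: a gene spread over several modules is a candidate for
*environmental pleiotropy* — association with multiple distinct aspects
of the multivariate environment.

### 4. Galaxy biplots

`biplot_coordinates()` plots each SNP's association with one variable
against another. The genome-wide null backdrop is the bivariate
prediction ellipse (`prediction_ellipse()`): semi-axes
`l_j = sqrt(lambda_j × qchisq(1 − alpha, 2))` from the eigenvalues of the
2×2 covariance of associations, orientation from the leading eigenvector.
Candidates far outside the ellipse associate more strongly than the
genome-wide covariance of the two variables explains;
`ellipse_coverage()` verifies the 95% construction by Monte Carlo.
Because derived alleles are coded 1, allele recoding reflects points
through the origin; SNPs with unknown derived state can be dropped.

### 5. Linkage disequilibrium

`gene_pair_mean_ld()` computes mean r² (squared Pearson correlation of
genotype codes, complete pairs) between and within genes, excluding
self-pairs on the diagonal and SNPs genotyped in fewer than 250
individuals by default (lower this for small panels).
`module_ld_summary()` aggregates r² within and between co-association
modules: elevated within-module LD indicates the profile clustering
tracks statistical associations among genotypes rather than artifacts.

## The landscape simulator

Because co-association networks are a descriptive tool, the package
ships a forward-time simulator to ask when they are trustworthy.
Independent haploid loci evolve on a `width × height` deme grid
(`sim_config()`, `simulate_landscape()`; the loop is in C++):

1. **Migration**: truncated discretized Gaussian kernel (sd `sigma`,
   radius `ceiling(3 sigma)`, circular mask), renormalized over occupied
   sources; reflecting boundaries by default, torus optional.
2. **Selection**: haploid `p' = p(1 + s_d)/(1 + p s_d)` with
   `s_d = s × surface(deme)`, where the surface
   (`selection_surface()`) mixes a south–north cline with a smoothed
   noise field, rescaled to [−1, 1] — an allele favored in the north is
   disfavored in the south (allelic antagonistic pleiotropy).
3. **Drift**: binomial resampling of K haploids; `capacity = Inf` gives
   the exact deterministic recurrence used by conservation tests.

Three demographies: `IBD` (whole grid at equilibrium), `1R` (expansion
from a mid-south refugium), `2R` (expansion from the two southern
corners), with fronts advancing one Chebyshev ring per generation and new
demes founded by kernel-weighted averages of occupied neighbors. Desk
scale is 32×32 with 200 (IBD) or 100 (expansion) generations, a 10:1
ratio mirroring the full-scale design this emulates.

`weir_fst()` is the variance-ratio estimator `Var(p)/(p̄(1−p̄))`
(divide-by-n variance; with equal K per deme no sample-size weighting is
needed). `calibrate_capacity()` bisects K on a log scale until mean
neutral F_ST matches a target (default 0.05) within tolerance, averaging
replicate seeds per evaluation.

`synthetic_environments()` generates the observed environment: 22
variables with a pine-like block correlation structure
(`pine_env_correlation()`: Aridity, Freezing, Geography blocks), built by
exact empirical construction so the *sample* correlation matrix equals
the target exactly, plus a hidden selective variable whose absolute
correlation with every observed variable is confined to a weak band
(≤ 0.2 by construction). This encodes the hard case for GEA: selection
driven by a factor only weakly proxied by anything measured.
`interpolate_environments()` (inverse-distance weighting with
convex-hull guard) transfers real site data onto simulated locations.

The evaluation module closes the loop: `apply_candidate_criteria()`
counts false/true positives under strict (dual) vs relaxed
(Bonferroni-only) criteria against the simulator's truth table;
`degree_by_selection()` and `sweep_edge_threshold()` quantify the
network signature of selection (selected loci share a surface, so they
form high-degree cliques; neutral false positives scatter); and
`pca_environment_associations()` implements the comparator analysis —
associations with principal components of the environment — whose
`group_pc_overlap()` output shows which co-association groups a PCA-first
analysis would miss.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
cfg <- sim_config(width = 16, height = 16, capacity = 16,
                  n_neutral = 300, n_selected = 6, s_values = 0.1,
                  generations = 150, cline_weight = 1, seed = 31)
st  <- simulate_landscape(cfg)
smp <- sample_populations(st, n_pops = 50, seed = 32)

# observed environments: 22 correlated variables, weakly coupled
# to the true selective surface
env <- synthetic_environments(n_pops = 50, seed = 33,
                              hidden = smp$hidden_env)
ev <- env$envs
rownames(ev$values) <- rownames(smp$freqs$freq)

raw  <- spearman_matrix(smp$freqs, ev)
corr <- corrected_associations(smp$freqs, ev)
res  <- apply_candidate_criteria(raw, st$s, "strict",
                                 assoc_corrected = corr)
res$fp; res$tp

hits <- names(res$passing)[res$passing]
d    <- association_distance_matrix(assoc_matrix(raw$rho[hits, ]))
g    <- build_coassociation_graph(d, threshold = 0.1)
g$modules
```

See the README for the same pipeline executed with its printed output.

## Parameters and desk-scale choices

* Grid 32×32 (full-scale analog 360×360); generations 200/100.
* Edge threshold 0.1 and quantile 0.99, Bonferroni α 0.05, BF cutoff 2,
  gene cutoff 1e-9: the empirical-analysis defaults, all overridable.
* `min_genotyped = 250` in LD gene means assumes a large panel; lower it
  for simulations.
* k = 4 Ward groups is a display convention; modules (components) are
  the inferential unit.

## Limitations

* The Bayes factor is a closed-form conjugate approximation, not MCMC;
  it shares the linear-model assumption of its target but not its exact
  posterior.
* The binomial gene test treats SNPs within a contig as exchangeable
  draws; LD within contigs makes it an index, hence the severe cutoff.
* Co-association modules are descriptive: loci under selection by the
  same factor cluster, but clustering alone does not prove shared
  selection — hence the simulator and the degree-by-selection and LD
  diagnostics.
* At desk scale, a heterogeneous selection surface rougher than the
  migration smoothing scale weakens the correlation between equilibrium
  frequencies and the local surface value; pure-cline settings give the
  cleanest signal and are used in the worked example.
* The simulator evolves unlinked haploid loci; recombination and diploid
  dominance are out of scope.
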