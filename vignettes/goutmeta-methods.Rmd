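---
title: "Methods and design of the goutmeta pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the goutmeta pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goutmeta)
```

goutmeta implements the analysis chain of a shotgun-metagenome case-control
study of the gut microbiome in gout: read-mapping counts over a reference
gene catalog are turned into relative-abundance profiles, aggregated to
taxonomic and functional (KO) levels, and interrogated for richness,
diversity, enterotypes, differential abundance, pathway enrichment,
species–pathway–clinical associations and a gene-level disease classifier.
This vignette documents the statistical machinery, the tunable parameters,
and the design decisions taken where reasonable alternatives existed.

## The gene-abundance model

A mapped read is either *unique* (it matches a single catalog gene) or
*multi-mapped* (its alignment is ambiguous among a candidate set of $N \ge 2$
genes). For gene $i$ with length $L_i$ and $U_i$ unique reads, the unique
abundance is

$$\mathrm{Ab}(U)_i = U_i / L_i .$$

Each multi-read group with count $M$ over candidate set $S$ is redistributed
proportional to the unique abundance of its candidates,

$$\mathrm{Co}_i = \frac{\mathrm{Ab}(U)_i}{\sum_{j \in S} \mathrm{Ab}(U)_j},
\qquad
\mathrm{Ab}(M)_i \mathrel{+}= \frac{M \cdot \mathrm{Co}_i}{L_i},$$

and the relative abundance is the per-sample normalisation
$\mathrm{Ab}(G)_i = (\mathrm{Ab}(U)_i + \mathrm{Ab}(M)_i) /
\sum_j (\mathrm{Ab}(U)_j + \mathrm{Ab}(M)_j)$, so gene-level rows sum to 1.

Numerical choices:

* **Degenerate candidate sets.** When every candidate of a multi-read group
  has zero unique abundance the coefficient is undefined; the group is split
  equally among its candidates rather than dropped, conserving read mass. A
  message flags how many groups this touched.
* **Per-group coefficients.** The coefficient is computed once per
  (sample, candidate-set) group; because the coefficient depends only on the
  unique abundances, this is identical to redistributing read by read, and
  the test suite verifies exact (1e-12) agreement with a per-read
  enumeration oracle on fuzzed instances.
* **Zero-abundance samples** return an all-zero row with a warning rather
  than NaNs.

Taxonomy is assigned per gene from alignment hits by rank-wise consensus:
hits with coverage < 70% or identity < 65% are discarded; at each rank only
hits whose identity exceeds the rank threshold (phylum > 65%, genus > 85%,
species > 95%) vote, and the rank is assigned when one taxon reaches at
least 50% of the votes. An exact 50/50 tie between two taxa is treated as no
consensus (a tie is not a majority), and a child rank is blanked when its
parent is unassigned. Aggregated (taxon or KO) profiles sum member-gene
abundances and are deliberately *not* renormalised: the shortfall from 1 is
the unannotated mass, which is information, not noise.

## Richness and diversity

* **Chao2** uses the incidence (presence across samples) form. The default
  is the bias-corrected estimator
  $S_{obs} + q_1(q_1-1)/(2(q_2+1))$, which stays defined when no doubleton
  features exist; the classic $S_{obs} + q_1^2/(2 q_2)$ is available by
  flag. Rarefaction draws `n_resamples = 100` bootstrap cohorts per sample
  count $k$. At $k = 1$ the curve reports mean observed richness (Chao2
  needs two samples). Simulation shows the bias-corrected estimator
  systematically overshoots at $k = 2$ (many singletons, almost no
  doubletons), so the curve's monotonicity should only be read from
  $k \ge 3$.
* **Shannon index** uses the natural logarithm (the base only rescales, and
  every downstream comparison is rank-based). **Bray–Curtis** and
  **PERMANOVA** delegate to vegan (`vegdist`, `adonis2`); PERMANOVA defaults
  to 9999 permutations and uses the $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$
  permutation P, which cannot be exactly zero.
* **PCA** is centred and unscaled by default (relative abundances share a
  scale; unit-variance scaling would inflate rare features), with a flag to
  scale. PCoA truncates negative eigenvalues to zero for explained-variance
  shares.
* **Enterotyping** clusters genus profiles with PAM for each candidate $k$
  (default 2–6) and picks the $k$ maximising the Calinski–Harabasz index,
  computed from the distance matrix via the within/total sum-of-squares
  identity. The default distance is root Jensen–Shannon divergence — the
  canonical enterotype choice — with Bray–Curtis by flag; the choice is
  recorded in the output. $k = 1$ is excluded by construction (the index is
  undefined there).

## Differential abundance

Each feature is tested by a two-sided Wilcoxon rank-sum test (exact
distribution for small tie-free samples, normal approximation with
continuity correction otherwise, as implemented by `wilcox.test`), with
Benjamini–Hochberg control applied across all features of one level (gene,
genus, species, KO) — each level is its own FDR family. Enrichment direction
is the group with the higher mean rank, which is invariant to monotone
per-feature transforms. Constant features are kept with $P = 1$ rather than
dropped, so family sizes stay comparable across cohorts. Zero-inflated
features are tested as-is: rank tests tolerate zeros and a pseudocount
would only perturb ranks.

Replication across cohorts requires significance in the discovery cohort
and significance *with the same direction* in validation; the validation
threshold can be applied to q (default) or raw P, since studies differ in
how strictly they gate the validation arm.

## Reporter scores

Each KO's two-sided P becomes a signed Z,
$Z = \Phi^{-1}(1 - p/2)$ with the sign of its enrichment direction, so one
score carries strength and direction. A pathway with $k$ scored members
aggregates $Z_{pw} = \sum Z / \sqrt{k}$ and is corrected against
`n_background = 1000` random size-$k$ KO sets drawn from all scored KOs:
$(Z_{pw} - \mu_k)/\sigma_k$. Significance is $|score| > 1.65$, the one-sided
95% normal quantile as conventionally printed. Under a global null the
corrected score is approximately standard normal, and about 5% of pathways
exceed 1.65 — the test suite checks this calibration over 50 simulated
datasets. The background universe is all KOs with a computed P in the
dataset; a pathway covering (almost) the whole universe has no background
and errors out. A constant-Z universe gives background sd 0 and is reported
as score 0 (no enrichment is expressible).

## The three-pronged association

For a species vector $s$ and pathway $P$ with member KOs $\mathcal{K}_P$:
Spearman correlations $\rho_j = \rho(s, \mathrm{KO}_j)$ are computed for
*every* scored KO; the association is

$$\mathrm{median}_{j \in \mathcal{K}_P}\, \rho_j \;-\;
  \mathrm{median}_{j \notin \mathcal{K}_P}\, \rho_j ,$$

with a Wilcoxon rank-sum P between the two $\rho$ sets. Subtracting the
out-of-pathway median removes global shifts of the correlation distribution
— notably those induced by compositionality — so the statistic is invariant
to adding a constant to every $\rho$. The same machinery associates
pathways with clinical indices (the clinical vector replaces the species),
and species–clinical associations are plain Spearman correlations, with a
BMI-adjusted variant computed as a first-order partial correlation on ranks
(Pearson of ranks residualised against the covariate's ranks, t
approximation with $n-3$ df). A constant covariate falls back to the plain
correlation with a warning. BH families follow the three prongs: all
species × pathway cells together; species × clinical per index; all
pathway × clinical cells together. Both adjusted and unadjusted
species–clinical outputs are emitted, since the adjustment question applies
per analysis, not per package. Pathways with fewer than 2 scored member KOs
are reported unscored.

## The gene classifier

Candidates are the top differentially abundant genes (default 100), ordered
by q, then raw P, then descending mean-rank gap so the ordering is
deterministic under ties. Five trials of stratified 10-fold
cross-validation are run; within each training fold a random forest ranks
the candidates by mean decrease in Gini impurity and genes are added
sequentially, recording held-out misclassification error for each top-$m$
set. Re-ranking inside each fold is the default because ranking on all data
leaks the held-out fold into feature selection; the global variant is
available by flag for fidelity with pipelines that rank once.

Selection uses the minimum-plus-standard-deviation rule: the cutoff is the
minimum of the averaged error curve plus the across-trial standard
deviation at that point, and the smallest gene set whose mean error does
not exceed the cutoff wins. Comparisons carry a 1e-10 numeric slack so
curves stated at printed precision (0.20 versus 0.18 + 0.02) behave as a
reader expects; on continuous CV errors ties are measure-zero and the rule
coincides with a strict reading. The rule is a pure function of the curve
and is unit-tested in isolation.

AUC uses the Mann–Whitney rank identity (tied pairs count one half), which
the tests verify against a brute-force concordance count and against pROC.
Forests default to 500 trees; all hyperparameters, the seed, the curve and
the selected set are written to the model manifest.

## What the synthetic generator emulates — and what it does not

The generator plants known ground truth so every stage is testable offline:

* **Community composition.** Per-species base log2 abundances
  $\mu_s \sim N(0, 2)$ are drawn once per catalog — they are a property of
  the simulated population, so every cohort drawn from one catalog shares
  them. Per-sample abundances are $2^{\mu_s + N(0,1)}$ renormalised to the
  simplex. The log2 scale is used so planted effect sizes (log2 fold
  changes added in cases) and between-sample noise share units; with
  $\sigma = 1$ on that scale, effects of one log2 unit sit at the detection
  margin of a rank test at $n = 40$ per group, which is where such a study
  operates.
* **Planted effects.** The default planted set is 50 species with
  alternating directions and magnitudes spread over $[1, 2.5]$ log2 units —
  moderate-to-strong effects balanced in direction so compositional
  spillover onto null species stays small.
* **Read mapping.** Reads are assigned multinomially to genes proportional
  to species abundance × within-species gene-length weight. Multi-mapped
  reads are drawn only on paralog-family genes (families span at least two
  species), with probability `multiread_rate`; the realised multi-mapped
  fraction is therefore `multiread_rate` times the paralog mass share.
  Unique plus multi-read counts always sum to the design depth.
* **Clinical indices** are intercept + coefficients × centred
  log10 abundance (pseudocount 1e-6 avoids $-\infty$ for absent species) +
  Gaussian noise, truncated below at a small positive floor. Noise is
  Gaussian on the index scale, which is adequate because every downstream
  use is rank-based. Defaults mimic a gout panel: serum uric acid driven
  negatively by a control-enriched species (a urate-degrading commensal
  proxy), CRP/ESR positively by a case-enriched species.
* **Longitudinal follow-up** moves case samples' log2 abundances a fraction
  $f$ toward the control centroid before regenerating reads; $f = 0$
  reproduces baseline, $f = 1$ erases the planted differences.

Not emulated: nucleotide sequences and alignment (no FASTQ), unmapped
reads (every emitted read maps; real cohorts map ~70–75% of reads),
sequencing error, strain-level variation, and covariate structure such as
age or diet effects on composition. Passing tests therefore demonstrate the
*statistical machinery* — calibration, power against planted effects,
determinism — not robustness to alignment artefacts or confounding in real
cohorts.

## Problem sizes used by the test and acceptance suites

The suites run planted-truth simulations sized so each property is measured
with useful precision: differential sensitivity/FDR at 1000 species, 50
planted, $n = 40/40$, 20 seeds; PERMANOVA type-I error over 200 null
datasets at 999 permutations; reporter calibration over 50 datasets of 200
KOs × 40 pathways; tripartite recovery over 20 datasets of 100 samples ×
80 KOs; classifier transfer on 400-gene catalogs with a 30/30 discovery and
20/20 validation cohort; end-to-end determinism on a 200-gene smoke
configuration. These sizes are the package's chosen trade-off between
Monte-Carlo precision and a test suite that runs in minutes on one core.

## Known limitations

* The consensus-taxonomy tie rule ("50% or higher") treats an exact
  two-way tie as unassigned; pipelines that break ties lexicographically
  will assign slightly more genes.
* Aggregated profiles are not renormalised, so taxon-level Bray–Curtis
  distances depend on the annotated fraction.
* The reporter background resamples KO sets without regard to inter-KO
  correlation; strongly co-abundant pathways inherit some of that
  correlation into their scores, as in the standard formulation.
* The classifier's published-marker genes cannot be re-derived here — they
  are specific to the study's catalog and cohort; only the selection
  machinery and its behaviour on planted signal are reproducible, and the
  synthetic held-out AUC (≥ 0.9 on strong effects, ~0.5 under permutation)
  matches the published pattern qualitatively, not numerically.
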