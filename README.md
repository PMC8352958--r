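# goutmeta

Case-control analysis of shotgun gut metagenomes, built around the question
of how the gut microbiome differs in gout: which taxa and gene functions
shift, how they relate to clinical chemistry (serum uric acid, CRP, renal
indices), and whether a handful of microbial genes can classify disease.
The package is aimed at microbiome researchers who quantify reads against a
reference gene catalog and want the whole downstream chain — profiling,
diversity, differential abundance, pathway enrichment, clinical
association, classification — as tested, reusable R functions rather than
one-off scripts.

## What it computes

**Gene profiles with multi-read redistribution.** Reads unique to gene *i*
give Ab(U)ᵢ = Uᵢ/Lᵢ; a read ambiguous among a candidate set S is split by
the coefficient Coᵢ = Ab(U)ᵢ / Σ_{j∈S} Ab(U)ⱼ, contributing M·Coᵢ/Lᵢ; the
relative abundance Ab(G) normalises the sum per sample. Taxon and KO
profiles aggregate member genes (without renormalising away the
unannotated mass). Consensus taxonomy uses rank-wise identity thresholds
(phylum > 65%, genus > 85%, species > 95%) with a ≥ 50% majority rule.

**Diversity and community structure.** Chao2 incidence richness (bias
corrected) with bootstrap rarefaction curves; Shannon index; Bray–Curtis
distances; PCA/PCoA; PERMANOVA (9999 permutations); PAM enterotyping on
root Jensen–Shannon genus distances with the Calinski–Harabasz index
choosing k; within- versus between-group distance comparisons, including a
longitudinal distance-from-baseline mode.

**Differential abundance.** Two-sided Wilcoxon rank-sum per feature,
Benjamini–Hochberg control per level, direction by higher mean rank; paired
signed-rank tests for longitudinal samples; discovery/validation
replication requiring concordant direction.

**Reporter scores.** KO P values become signed Z scores; a pathway scores
ΣZ/√k, corrected against 1000 random same-size KO sets; |score| > 1.65
flags enrichment in either direction.

**Three-pronged association.** Species × pathway cells are the median
Spearman correlation of the species with in-pathway KOs minus the
out-of-pathway median (background correction), tested by Wilcoxon between
the two correlation sets; species × clinical by Spearman with a
BMI-adjusted partial variant; pathway × clinical by the same corrected
machinery.

**Classifier.** Random forest over top differential genes, five trials of
stratified 10-fold CV with fold-internal importance ranking, the
minimum-plus-SD rule picking the smallest gene set, and rank-formulation
ROC/AUC.

**Synthetic cohorts.** A generator plants known species effects, paralog
multi-mapping structure, clinical indices driven by chosen species, and
longitudinal recovery, so every stage above is testable against ground
truth offline.

## Worked example

```r
library(goutmeta)

catalog <- generate_catalog(n_genes = 800, n_species = 80, n_kos = 120,
                            n_pathways = 10, seed = 1)
planted <- default_planted(catalog, n = 20, seed = 1)
design  <- cohort_design(n_case = 25, n_control = 25, planted = planted,
                         depth = 20000, multiread_rate = 0.1, seed = 1)
cohort  <- generate_cohort(catalog, design)

prof    <- prevalence_filter(build_gene_profile(cohort$samples, catalog), 0.10)
species <- aggregate_profile(prof, taxon_map(catalog, "species"), "species")

alpha <- shannon_index(prof$matrix)
median(alpha[cohort$labels == "case"])      # 5.147
median(alpha[cohort$labels == "control"])   # 5.542

perm <- permanova(bray_curtis(prof$matrix), cohort$labels,
                  n_perm = 999, seed = 1)
perm$R2                                     # 0.221
perm$p                                      # 0.001

diff <- differential_abundance(species, cohort$labels)
sum(diff$q < 0.05)                          # 38 of 80 species
sum(planted$species %in% diff$feature[diff$q < 0.05])   # 18 of 20 planted

dko <- differential_abundance(aggregate_profile(prof, ko_map(catalog), "ko"),
                              cohort$labels)
z   <- ko_zscore(setNames(dko$p, dko$feature), dko$direction)
rep <- reporter_score(z, catalog$pathways, seed = 1)
head(rep[order(-abs(rep$score)), c("pathway", "k", "score", "significant")], 1)
#  pathway  k     score significant
#  path003 16 -1.674629        TRUE
```

Reading the numbers: the planted case effects depress case alpha diversity
(5.15 vs 5.54) and separate the groups in community space (PERMANOVA
R² = 0.22 at the permutation floor P = 0.001). The species-level Wilcoxon/BH
stage recovers 18 of the 20 planted species among 38 significant calls (the
extras are compositional echoes of the planted shifts), and one pathway
crosses the |reporter score| > 1.65 line in the control direction.

The same chain runs end to end, with every output written as provenance-
headered TSV/JSON, via `run_pipeline(pipeline_config(out_dir, seed = 1))`.

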