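# Synthetic community generator: determinism, conservation, planted effects.

test_that("catalog generation covers every species, is deterministic, handles empty input", {
  empty <- generate_catalog(0, 0, seed = 1)
  expect_equal(nrow(empty$genes), 0)
  expect_length(empty$pathways, 0)

  c1 <- generate_catalog(2000, 50, seed = 1)
  c2 <- generate_catalog(2000, 50, seed = 1)
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))

  tally <- table(c1$genes$species)
  expect_length(tally, 50)             # every species owns >= 1 gene
  expect_true(all(tally >= 1))
  expect_equal(sum(tally), 2000)
  expect_true(all(c1$genes$length >= 100))
  expect_false(anyDuplicated(c1$genes$gene_id) > 0)
  # paralog families span >= 2 species
  sp <- setNames(c1$genes$species, c1$genes$gene_id)
  for (fam in c1$paralog_families) {
    expect_gte(length(unique(sp[fam])), 2)
  }
  expect_error(generate_catalog(-5, 2), "nonnegative")
  expect_error(generate_catalog(10, 20), "n_species")
})

test_that("cohort generation conserves depth and honours multiread_rate = 0", {
  cat1 <- generate_catalog(300, 30, seed = 3)
  d0 <- cohort_design(3, 3, depth = 10000, multiread_rate = 0, seed = 5)
  co0 <- generate_cohort(cat1, d0)
  expect_true(all(vapply(co0$samples, total_reads, numeric(1)) == 10000))
  expect_true(all(lengths(lapply(co0$samples, `[[`, "multi_groups")) == 0))

  d1 <- cohort_design(3, 3, depth = 10000, multiread_rate = 0.3, seed = 5)
  co1 <- generate_cohort(cat1, d1)
  expect_true(all(vapply(co1$samples, total_reads, numeric(1)) == 10000))
  expect_true(any(lengths(lapply(co1$samples, `[[`, "multi_groups")) > 0))

  # determinism, byte-wise
  co2 <- generate_cohort(cat1, d1)
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))

  # planted species must exist
  bad <- cohort_design(3, 3, planted = data.frame(species = "s__Nope",
                                                  log2_effect = 2), seed = 1)
  expect_error(generate_cohort(cat1, bad), "s__Nope")
})

test_that("null planted effects leave case and control exchangeable", {
  cat1 <- generate_catalog(200, 40, seed = 2)
  sp <- unique(cat1$genes$species)
  d <- cohort_design(50, 50,
                     planted = data.frame(species = sp[1:5], log2_effect = 0),
                     depth = 1000, seed = 11)
  sim <- simulate_species_truth(sp, d)
  for (s in sp[1:3]) {
    ks <- suppressWarnings(
      ks.test(sim$truth[sim$labels == "case", s],
              sim$truth[sim$labels == "control", s]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("planted effects are recoverable from ground truth at n = 40/40", {
  # detection fraction across seeds for planted |log2 effect| >= 1
  hits <- 0; planted_total <- 0
  for (seed in 1:20) {
    cat1 <- generate_catalog(1000, 1000, n_kos = 10, n_pathways = 0, seed = seed)
    sp <- unique(cat1$genes$species)
    planted <- default_planted(cat1, 50, seed = seed)
    d <- cohort_design(40, 40, planted = planted, depth = 1000, seed = seed)
    sim <- simulate_species_truth(sp, d)
    res <- differential_abundance(sim$truth, sim$labels)
    sig <- res$feature[res$q < 0.05]
    hits <- hits + sum(planted$species %in% sig)
    planted_total <- planted_total + nrow(planted)
  }
  expect_gte(hits / planted_total, 0.95)
})

test_that("clinical indices follow the planted coefficients", {
  cat1 <- generate_catalog(100, 20, seed = 4)
  sp <- unique(cat1$genes$species)

  # all-zero coefficients: index independent of every species
  d0 <- cohort_design(50, 50, depth = 1000, seed = 21,
                      clinical_model = list(SUA = list(intercept = 450,
                                                       coef = numeric(0),
                                                       sd = 50)))
  sim0 <- simulate_species_truth(sp, d0)
  clin0 <- generate_clinical(sim0$truth, d0, labels = sim0$labels)
  rho0 <- abs(cor(clin0$SUA, sim0$truth, method = "spearman"))
  expect_lt(max(rho0), 0.3)           # pointwise null bound at n = 100
  expect_lt(median(rho0), 0.15)

  # negative coefficient gives negative sample correlation at n = 200
  signs <- vapply(1:20, function(seed) {
    dn <- cohort_design(100, 100, depth = 1000, seed = seed,
                        clinical_model = list(SUA = list(
                          intercept = 450,
                          coef = setNames(-60, sp[1]), sd = 30)))
    simn <- simulate_species_truth(sp, dn)
    clin <- generate_clinical(simn$truth, dn, labels = simn$labels)
    cor(clin$SUA, simn$truth[, sp[1]], method = "spearman")
  }, numeric(1))
  expect_true(all(signs < 0))

  # single coefficient, noise sd -> 0: monotone transform, |rho| = 1
  eps <- cohort_design(10, 10, depth = 1000, seed = 31,
                       clinical_model = list(CRP = list(
                         intercept = 10, coef = setNames(5, sp[2]),
                         sd = 1e-12)))
  sime <- simulate_species_truth(sp, eps)
  cline <- generate_clinical(sime$truth, eps, labels = sime$labels)
  expect_equal(cor(cline$CRP, sime$truth[, sp[2]], method = "spearman"), 1)

  # model referencing an unknown species errors by name
  bad <- cohort_design(5, 5, seed = 1,
                       clinical_model = list(SUA = list(
                         intercept = 1, coef = c(s__ghost = 1), sd = 1)))
  simb <- simulate_species_truth(sp, bad)
  expect_error(generate_clinical(simb$truth, bad), "s__ghost")
})

test_that("longitudinal recovery moves cases toward controls monotonically", {
  cat1 <- generate_catalog(300, 30, seed = 6)
  planted <- default_planted(cat1, 10, seed = 6)
  d <- cohort_design(8, 8, planted = planted, depth = 2000, seed = 6)
  co <- generate_cohort(cat1, d)

  expect_error(generate_longitudinal(co, c(a = 0.5, b = 0.2)), "nondecreasing")
  expect_error(generate_longitudinal(co, c(a = -0.1)), "\\[0, 1\\]")

  # f = 1 erases planted differences in ground truth
  lt1 <- generate_longitudinal(co, c(end = 1), seed = 1)
  controls <- names(co$labels)[co$labels == "control"]
  centroid <- colMeans(log2(co$truth[controls, ]))
  ab <- 2^matrix(centroid, 1); ab <- ab / sum(ab)
  expect_equal(unname(lt1$end$truth[1, ]), as.vector(ab), tolerance = 1e-12)

  # mean Bray-Curtis from baseline increases with the recovery fraction
  mean_bc <- function(seed) {
    lt <- generate_longitudinal(co, c(t1 = 0.1, t2 = 0.3, t3 = 0.8),
                                seed = seed)
    cases <- rownames(co$truth)[co$labels[rownames(co$truth)] == "case"]
    vapply(lt, function(x) {
      mean(vapply(cases, function(s) {
        pair <- rbind(co$truth[s, ], x$truth[s, ])
        bray_curtis(pair)[1, 2]
      }, numeric(1)))
    }, numeric(1))
  }
  ok <- vapply(1:10, function(s) {
    bc <- mean_bc(s)
    bc[1] < bc[2] && bc[2] < bc[3]
  }, logical(1))
  expect_true(all(ok))
})
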