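# Richness, diversity, ordination, PERMANOVA, enterotyping.

test_that("Chao2 matches the closed forms", {
  # S_obs = 10, q1 = 4, q2 = 2: bias-corrected = 10 + 4*3/(2*3) = 12
  inc <- matrix(0, 4, 10, dimnames = list(paste0("s", 1:4), paste0("f", 1:10)))
  inc[, 1:4] <- 1                              # 4 ubiquitous
  inc[1, 5] <- 1; inc[2, 6] <- 1; inc[3, 7] <- 1; inc[4, 8] <- 1  # q1 = 4
  inc[1:2, 9] <- 1; inc[3:4, 10] <- 1          # q2 = 2
  expect_equal(chao2(inc), 12)
  expect_equal(chao2(inc, bias_corrected = FALSE), 10 + 16 / 4)

  # no singletons: estimate = S_obs
  all_in <- matrix(1, 3, 7)
  expect_equal(chao2(all_in), 7)
  expect_equal(chao2(all_in, bias_corrected = FALSE), 7)

  expect_gte(chao2(inc), 10)                   # never below observed
  expect_error(chao2(inc[1, , drop = FALSE]), ">= 2 samples")
})

test_that("rarefaction curves are deterministic and nondecreasing in k", {
  set.seed(5)
  inc <- matrix(rbinom(30 * 80, 1, 0.25), 30, 80)
  c1 <- rarefaction_curve(inc, n_resamples = 50, seed = 9)
  c2 <- rarefaction_curve(inc, n_resamples = 50, seed = 9)
  expect_identical(c1, c2)

  # flat at S_obs when every feature is ubiquitous
  ubiq <- matrix(1, 6, 12)
  cf <- rarefaction_curve(ubiq, n_resamples = 10, seed = 1)
  expect_true(all(cf$mean_richness == 12))

  # on heavy-tailed feature prevalence (the realistic gene-catalog shape)
  # the mean curve is nondecreasing up to Monte-Carlo noise (2 se) beyond
  # the k = 2 transient, where the bias-corrected estimator systematically
  # overshoots (q1 large, q2 near zero)
  for (seed in 1:5) {
    set.seed(seed)
    prev <- rbeta(400, 0.4, 2.5)
    hinc <- sapply(prev, function(p) rbinom(30, 1, p))
    cc <- rarefaction_curve(hinc, n_resamples = 60, seed = seed)
    mr <- cc$mean_richness[-(1:2)]
    se <- cc$sd_richness[-(1:2)] / sqrt(60)
    expect_true(all(diff(mr) > -2 * (se[-1] + se[-length(se)])))
  }
})

test_that("gene counts and Shannon index match closed forms", {
  expect_equal(gene_count(rep(0, 5)), 0)
  expect_equal(gene_count(c(0, 1, 0)), 1)
  row7 <- c(rep(0.1, 7), rep(0, 3))
  expect_equal(gene_count(row7), 7)

  expect_equal(shannon_index(rep(1 / 8, 8)), log(8), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.5 * log(2),
               tolerance = 1e-12)
  # maximal at the uniform row for fixed support
  set.seed(1)
  p <- runif(6); p <- p / sum(p)
  expect_lte(shannon_index(p), log(6))
  expect_error(shannon_index(c(-0.1, 1.1)), "nonnegative")
})

test_that("Bray-Curtis matches closed forms, symmetry and bounds", {
  x <- c(0.5, 0.5, 0)
  y <- c(0.5, 0, 0.5)
  dm <- bray_curtis(rbind(a = x, b = y))
  expect_equal(dm["a", "b"], 0.5, tolerance = 1e-12)
  expect_equal(dm["a", "a"], 0)
  expect_equal(dm, t(dm))

  disjoint <- rbind(c(1, 0), c(0, 1))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  identical_rows <- rbind(x, x)
  expect_equal(bray_curtis(identical_rows)[1, 2], 0)

  set.seed(2)
  m <- matrix(runif(40), 8, 5)
  dmm <- bray_curtis(m / rowSums(m))
  expect_true(all(dmm >= 0 & dmm <= 1))
  expect_error(bray_curtis(rbind(c(0, 0), c(1, 0))), "all-zero")
})

test_that("ordination orders axes by variance and separates planted clusters", {
  pg <- planted_genus_profile(n_per = 12, seed = 3)
  ord <- ordinate(pg$profile, "pca")
  expect_true(all(diff(ord$explained) <= 1e-12))
  # duplicated samples land on coincident coordinates
  dup <- rbind(pg$profile, pg$profile[1, , drop = FALSE])
  odup <- ordinate(dup, "pca")
  expect_equal(odup$coordinates[1, ], odup$coordinates[nrow(dup), ],
               tolerance = 1e-8)
  # axis 1 separates the two planted community types
  r <- abs(cor(ord$coordinates[, 1], as.numeric(pg$truth == 1)))
  expect_gt(r, 0.9)

  op <- ordinate(bray_curtis(pg$profile), "pcoa")
  expect_true(all(diff(op$explained) <= 1e-12))
  r2 <- abs(cor(op$coordinates[, 1], as.numeric(pg$truth == 1)))
  expect_gt(r2, 0.9)
})

test_that("PERMANOVA detects planted structure and respects exchangeability", {
  pg <- planted_genus_profile(n_per = 12, seed = 4)
  dm <- bray_curtis(pg$profile)
  fit <- permanova(dm, factor(pg$truth), n_perm = 999, seed = 1)
  expect_lte(fit$p, 0.001)
  expect_gt(fit$R2, 0.3)
  expect_gte(fit$p, 1 / 1000)

  # R2 invariant to relabeling within groups (R2 depends only on the split)
  perm <- c(sample(which(pg$truth == 1)), sample(which(pg$truth == 2)))
  fit2 <- permanova(dm[perm, perm], factor(pg$truth[perm]), n_perm = 99,
                    seed = 1)
  expect_equal(fit2$R2, fit$R2, tolerance = 1e-12)

  expect_error(permanova(dm, rep(1, nrow(dm))), "constant")
})

test_that("enterotyping recovers planted community types with CH-optimal k = 2", {
  for (seed in 1:3) {
    pg <- planted_genus_profile(n_per = 12, seed = seed)
    et <- enterotype(pg$profile, k_range = 2:5, seed = seed)
    expect_equal(et$k, 2)
    expect_gte(oracle_ari(et$labels, pg$truth), 0.9)
  }
  # determinism under identical seed
  pg <- planted_genus_profile(seed = 8)
  e1 <- enterotype(pg$profile, seed = 4)
  e2 <- enterotype(pg$profile, seed = 4)
  expect_identical(e1$medoids, e2$medoids)
  expect_identical(e1$labels, e2$labels)
  # bray flag and group test plumbing
  groups <- setNames(factor(rep(c("case", "control"), 15)),
                     rownames(pg$profile))
  eb <- enterotype(pg$profile, distance = "bray", groups = groups)
  expect_true(is.numeric(eb$group_test))
  expect_error(enterotype(matrix(0.5, 10, 4), k_range = 2:3), "identical")
})

test_that("within/between distance comparison behaves on planted and degenerate data", {
  pg <- planted_genus_profile(n_per = 10, seed = 5)
  dm <- bray_curtis(pg$profile)
  lab <- factor(pg$truth)
  gdc <- group_distance_comparison(dm, lab)
  expect_gt(gdc$mean_between, gdc$mean_within)
  expect_lt(gdc$p, 0.01)
  # symmetric under label swap
  gdc2 <- group_distance_comparison(dm, factor(3 - pg$truth))
  expect_equal(sort(gdc2$within), sort(gdc$within))
  expect_equal(gdc2$p, gdc$p)

  # all points identical: distances zero, P reported as 1
  dz <- matrix(0, 6, 6)
  gz <- group_distance_comparison(dz, factor(rep(1:2, 3)))
  expect_true(all(gz$within == 0) && all(gz$between == 0))
  expect_equal(gz$p, 1)
  expect_error(group_distance_comparison(dm, factor(c("a", rep("b", 19)))),
               ">= 2 samples")

  # baseline mode returns distances keyed by timepoint
  pairing <- data.frame(baseline = rownames(dm)[1:3],
                        followup = rownames(dm)[4:6],
                        timepoint = c("2W", "4W", "24W"))
  bl <- group_distance_comparison(dm, mode = "baseline", pairing = pairing)
  expect_equal(bl$distance,
               dm[cbind(pairing$baseline, pairing$followup)])
})
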