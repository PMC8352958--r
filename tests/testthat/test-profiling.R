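# Gene-abundance engine, downsampling, filters, taxonomy consensus,
# aggregation.

test_that("gene abundance matches the hand-worked two-gene example", {
  cat2 <- tiny_catalog(c(A = 100, B = 200))
  s <- read_map_sample("s1", c(A = 10, B = 40),
                       list(list(genes = c("A", "B"), count = 1)))
  g <- gene_abundance(s, cat2)
  expect_equal(unname(g$relative[c("A", "B")]), c(31 / 92, 61 / 92),
               tolerance = 1e-12)
  expect_equal(sum(g$relative), 1, tolerance = 1e-12)
})

test_that("with no multi-reads the relative abundance is normalised U/L", {
  lens <- c(a = 150, b = 300, c = 450)
  s <- read_map_sample("s1", c(a = 3, b = 6, c = 9))
  g <- gene_abundance(s, tiny_catalog(lens))
  expected <- (c(3, 6, 9) / lens) / sum(c(3, 6, 9) / lens)
  expect_equal(unname(g$relative), unname(expected), tolerance = 1e-12)
})

test_that("gene abundance agrees with the per-read enumeration oracle", {
  set.seed(99)
  for (i in 1:100) {
    inst <- random_readmap_instance(max_genes = 20)
    got <- suppressMessages(gene_abundance(inst$sample, inst$catalog))
    want <- oracle_gene_abundance(inst$sample, inst$catalog)
    expect_equal(got$relative, want, tolerance = 1e-12)
    if (sum(got$abundance) > 0) {
      expect_equal(sum(got$relative), 1, tolerance = 1e-12)
    }
  }
})

test_that("gene abundance is scale invariant and flags degenerate groups", {
  lens <- c(a = 100, b = 200, c = 400)
  s1 <- read_map_sample("s", c(a = 5, b = 10),
                        list(list(genes = c("a", "b"), count = 2)))
  s2 <- read_map_sample("s", c(a = 50, b = 100),
                        list(list(genes = c("a", "b"), count = 20)))
  cat3 <- tiny_catalog(lens)
  expect_equal(gene_abundance(s1, cat3)$relative,
               gene_abundance(s2, cat3)$relative, tolerance = 1e-12)

  # all-zero unique abundance in the candidate set: equal split, message
  s3 <- read_map_sample("s", c(c = 10),
                        list(list(genes = c("a", "b"), count = 4)))
  expect_message(g3 <- gene_abundance(s3, cat3), "split equally")
  expect_equal(unname(g3$abundance["a"] / g3$abundance["b"]), 2)  # 2/100 vs 2/200

  expect_error(gene_abundance(read_map_sample("s", c(zz = 1)), cat3),
               "not in catalog")
  expect_warning(gene_abundance(read_map_sample("s", numeric(0)), cat3),
                 "zero total")
})

test_that("downsampling conserves targets and matches hypergeometric expectation", {
  s <- read_map_sample("s", c(a = 20, b = 30),
                       list(list(genes = c("a", "b"), count = 10)))
  expect_identical(downsample_reads(s, 60), s)          # target = total
  empty <- downsample_reads(s, 0, seed = 1)
  expect_equal(total_reads(empty), 0)
  expect_error(downsample_reads(s, 61), "exceeds")

  set.seed(7)
  half <- replicate(1000, {
    d <- downsample_reads(s, 30)
    k <- d$unique_counts["a"]
    if (is.na(k)) 0 else unname(k)
  })
  # each of gene a's 20 reads is retained with frequency 1/2; over 1000
  # repeats the mean frequency sits within 3 standard errors of 0.5
  freq <- mean(half) / 20
  se <- sqrt(0.5 * 0.5 * (60 - 30) / (60 - 1) / (20 * 1000))
  expect_lt(abs(freq - 0.5), 3 * se + 0.01)
  d1 <- downsample_reads(s, 30, seed = 42)
  d2 <- downsample_reads(s, 30, seed = 42)
  expect_identical(serialize(d1, NULL), serialize(d2, NULL))
})

test_that("prevalence filter applies the ceiling threshold without renormalising", {
  mat <- matrix(0, 20, 3, dimnames = list(sprintf("s%02d", 1:20),
                                          c("ubiq", "once", "twice")))
  mat[, "ubiq"] <- 0.5
  mat[1, "once"] <- 0.1
  mat[1:2, "twice"] <- 0.1
  f <- prevalence_filter(mat, 0.10)     # needs >= 2 of 20
  expect_identical(colnames(f), c("ubiq", "twice"))
  expect_equal(f[1, "twice"], 0.1)      # no renormalisation
  expect_identical(colnames(prevalence_filter(mat, 1)), "ubiq")
  expect_error(prevalence_filter(mat, 0), "min_fraction")
})

test_that("taxonomy consensus follows the per-rank thresholds and tie rule", {
  hit <- function(gene, ph, ge, sp, id, cov = 90) {
    data.frame(gene_id = gene, phylum = ph, genus = ge, species = sp,
               identity = id, coverage = cov, stringsAsFactors = FALSE)
  }
  # unanimous high-identity hits: assigned at all ranks
  h1 <- do.call(rbind, replicate(3, hit("gA", "pX", "gX", "sX", 99),
                                 simplify = FALSE))
  r1 <- assign_taxonomy(h1)
  expect_identical(unlist(r1[1, c("phylum", "genus", "species")],
                          use.names = FALSE), c("pX", "gX", "sX"))

  # 2 vs 2 exact species tie: species unassigned
  h2 <- rbind(hit("gB", "pX", "gX", "sX", 99), hit("gB", "pX", "gX", "sX", 99),
              hit("gB", "pX", "gX", "sY", 99), hit("gB", "pX", "gX", "sY", 99))
  r2 <- assign_taxonomy(h2)
  expect_identical(r2$genus[1], "gX")
  expect_true(is.na(r2$species[1]))

  # identity 90 clears the genus (>85) but not the species (>95) threshold
  h3 <- do.call(rbind, replicate(3, hit("gC", "pX", "gX", "sX", 90),
                                 simplify = FALSE))
  r3 <- assign_taxonomy(h3)
  expect_identical(r3$genus[1], "gX")
  expect_true(is.na(r3$species[1]))

  # hits failing the global coverage filter leave the gene unassigned
  h4 <- hit("gD", "pX", "gX", "sX", 99, cov = 50)
  r4 <- assign_taxonomy(h4)
  expect_true(all(is.na(r4[1, c("phylum", "genus", "species")])))

  # child rank blanked when parent unassigned
  h5 <- rbind(hit("gE", "pX", "gX", "sX", 99), hit("gE", "pY", "gX", "sX", 99))
  r5 <- assign_taxonomy(h5)
  expect_true(is.na(r5$phylum[1]) && is.na(r5$genus[1]) && is.na(r5$species[1]))
})

test_that("aggregation sums member genes and conserves annotated mass", {
  mat <- matrix(c(0.1, 0.2, 0.3, 0.4), 1,
                dimnames = list("s1", c("g1", "g2", "g3", "g4")))
  map <- c(g1 = "spA", g2 = "spA", g3 = "spB")   # g4 unannotated
  agg <- aggregate_profile(mat, map, "species")
  expect_equal(agg$matrix[1, c("spA", "spB")], c(spA = 0.3, spB = 0.3))
  expect_lte(sum(agg$matrix), 1)

  # all genes one species: abundance 1
  all_map <- setNames(rep("spA", 4), colnames(mat))
  expect_equal(unname(aggregate_profile(mat, all_map)$matrix[1, 1]), 1)

  # disjoint KO sets conserve annotated mass
  ko <- c(g1 = "K1", g2 = "K2", g3 = "K2", g4 = "K3")
  expect_equal(sum(aggregate_profile(mat, ko, "ko")$matrix), 1)
})

test_that("B/F ratio handles the zero-denominator sample by flagging", {
  mat <- matrix(c(0.4, 0.2,
                  0.3, 0.3,
                  0.5, 0.0), 3, 2, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"),
                                c("p__Bacteroidetes", "p__Firmicutes")))
  r <- bf_ratio(mat)
  expect_equal(unname(r[1:2]), c(2, 1))
  expect_true(is.infinite(r[3]))
  expect_identical(unname(attr(r, "degenerate")), c(FALSE, FALSE, TRUE))
  expect_error(bf_ratio(mat[, 1, drop = FALSE]), "absent")
})

test_that("functional hit filter keeps the best passing hit per gene", {
  hits <- data.frame(
    gene_id = c("g1", "g1", "g2", "g3", "g4", "g5"),
    subject = c("enzA", "enzB", "enzA", "enzC", "enzD", "enzE"),
    evalue = c(1e-10, 1e-8, 1e-4, 1e-6, 1e-3, 0.5),
    identity = c(90, 95, 90, 70, 90, 99),
    coverage = c(80, 90, 80, 90, 60, 95),
    stringsAsFactors = FALSE)
  kept <- filter_function_hits(hits)
  # g1: both pass, best e-value wins; g2: e-value 1e-4 >= 1e-5 rejected;
  # g3: identity 70 not > 70 rejected; g4: coverage fails; g5: e-value fails
  expect_identical(kept, c(g1 = "enzA"))

  hits2 <- hits
  hits2$evalue[3] <- 1e-9
  expect_identical(sort(names(filter_function_hits(hits2))), c("g1", "g2"))
})
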