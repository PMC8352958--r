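# Independent oracles and tiny fixture builders shared across tests.

# Minimal hand-built catalog: gene ids, lengths, one species per gene unless
# stated otherwise.
tiny_catalog <- function(lengths, species = NULL, ko = NULL) {
  n <- length(lengths)
  ids <- names(lengths) %||% sprintf("g%02d", seq_len(n))
  structure(list(
    genes = data.frame(
      gene_id = ids, length = as.integer(lengths),
      phylum = "p__P", genus = "g__G",
      species = species %||% sprintf("s__%02d", seq_len(n)),
      ko = if (is.null(ko)) NA_character_ else ko,
      stringsAsFactors = FALSE),
    pathways = list(), paralog_families = list()),
    class = "gene_catalog")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force per-read redistribution oracle for the gene-abundance engine:
# every multi-read is handled one read at a time, each read split across its
# candidate genes by the unique-abundance coefficient. Independent of the
# vectorised implementation.
oracle_gene_abundance <- function(sample, catalog) {
  L <- setNames(as.numeric(catalog$genes$length), catalog$genes$gene_id)
  ab_u <- setNames(numeric(length(L)), names(L))
  for (g in names(sample$unique_counts)) {
    ab_u[g] <- sample$unique_counts[[g]] / L[[g]]
  }
  ab <- ab_u
  for (grp in sample$multi_groups) {
    for (r in seq_len(grp$count)) {         # read-by-read
      w <- ab_u[grp$genes]
      co <- if (sum(w) > 0) w / sum(w) else rep(1 / length(w), length(w))
      ab[grp$genes] <- ab[grp$genes] + co / L[grp$genes]
    }
  }
  if (sum(ab) > 0) ab / sum(ab) else ab
}

# Random small read-mapping instance over <= max_genes genes.
random_readmap_instance <- function(max_genes = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- sample(3:max_genes, 1)
  lens <- sample(100:2000, n, replace = TRUE)
  names(lens) <- sprintf("g%02d", seq_len(n))
  cat <- tiny_catalog(lens)
  u <- rpois(n, 10)
  # sometimes zero out some unique counts to exercise the degenerate split
  u[sample.int(n, max(1, n %/% 4))] <- 0
  names(u) <- names(lens)
  n_groups <- sample(0:4, 1)
  groups <- lapply(seq_len(n_groups), function(i) {
    size <- sample(2:min(4, n), 1)
    list(genes = sample(names(lens), size), count = sample(1:5, 1))
  })
  list(sample = read_map_sample("fuzz", u[u > 0], groups), catalog = cat)
}

# Exact two-sided Wilcoxon rank-sum P by full enumeration of all
# C(n1 + n2, n1) group assignments (tie-free inputs), using the same
# two-sided doubling convention as the exact distribution test.
oracle_wilcox_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean_w <- n1 * n2 / 2
  p <- if (w_obs > mean_w) 2 * mean(w_all >= w_obs) else 2 * mean(w_all <= w_obs)
  min(p, 1)
}

# Brute-force AUC as the concordance-pair fraction (ties count one half).
oracle_auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Adjusted Rand index between two labelings (contingency-table form).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Small planted two-cluster genus profile: two community types with distinct
# dominant genera plus noise.
planted_genus_profile <- function(n_per = 15, n_genus = 12, seed = 1) {
  set.seed(seed)
  base1 <- c(10, rep(1, n_genus - 1))
  base2 <- c(1, 10, rep(1, n_genus - 2))
  mk <- function(base, tag) {
    t(sapply(seq_len(n_per), function(i) {
      v <- base * rlnorm(n_genus, 0, 0.3)
      v / sum(v)
    }))
  }
  mat <- rbind(mk(base1), mk(base2))
  rownames(mat) <- sprintf("s%02d", seq_len(2 * n_per))
  colnames(mat) <- sprintf("g__%02d", seq_len(n_genus))
  list(profile = mat, truth = rep(1:2, each = n_per))
}
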