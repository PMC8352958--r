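# Richness, alpha/beta diversity, ordination, community-level testing and
# enterotyping.

#' Chao2 incidence-based richness estimator
#'
#' Estimates total feature richness from presence/absence across samples.
#' The bias-corrected form (default) is
#' `S_obs + q1 * (q1 - 1) / (2 * (q2 + 1))`, where `q1` and `q2` count
#' features present in exactly one and exactly two samples; it stays defined
#' when no doubletons exist. The classic form `S_obs + q1^2 / (2 * q2)` is
#' available by flag (falling back to the bias-corrected ratio when
#' `q2 = 0`).
#'
#' @param incidence samples x features matrix; any positive entry counts as
#'   presence. At least 2 samples are required.
#' @param bias_corrected use the bias-corrected form (default `TRUE`).
#' @return estimated richness (numeric scalar, >= observed richness).
#' @export
chao2 <- function(incidence, bias_corrected = TRUE) {
  mat <- as_profile_matrix(incidence) > 0
  if (nrow(mat) < 2) stop_invalid("Chao2 needs >= 2 samples")
  inc <- colSums(mat)
  s_obs <- sum(inc > 0)
  q1 <- sum(inc == 1)
  q2 <- sum(inc == 2)
  if (bias_corrected || q2 == 0) {
    s_obs + q1 * (q1 - 1) / (2 * (q2 + 1))
  } else {
    s_obs + q1^2 / (2 * q2)
  }
}

#' Rarefaction curve of estimated richness
#'
#' For each sample count `k = 1..n`, draws `k` samples with replacement from
#' the cohort `n_resamples` times and averages the Chao2 estimate (observed
#' richness at `k = 1`, where Chao2 is undefined). Per-group curves are
#' comparable point-by-point, e.g. by a paired Wilcoxon test across `k`.
#'
#' @param incidence samples x features matrix (presence = positive entry).
#' @param n_resamples resampling repeats per `k` (default 100).
#' @param seed RNG seed.
#' @param bias_corrected passed to [chao2()].
#' @return data.frame: `k`, `mean_richness`, `sd_richness`.
#' @export
rarefaction_curve <- function(incidence, n_resamples = 100, seed = 1L,
                              bias_corrected = TRUE) {
  if (n_resamples < 1) stop_invalid("n_resamples must be >= 1")
  mat <- as_profile_matrix(incidence) > 0
  n <- nrow(mat)
  set.seed(as.integer(seed))
  res <- matrix(NA_real_, n_resamples, n)
  for (k in seq_len(n)) {
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n, k, replace = TRUE)
      res[r, k] <- if (k == 1) sum(mat[idx, ]) else
        chao2(mat[idx, , drop = FALSE], bias_corrected)
    }
  }
  data.frame(k = seq_len(n),
             mean_richness = colMeans(res),
             sd_richness = apply(res, 2, stats::sd))
}

#' Observed gene count of a sample
#'
#' The number of catalog features with strictly positive abundance.
#'
#' @param x numeric vector (one profile row) or samples x features matrix.
#' @return integer scalar, or per-sample integer vector for a matrix.
#' @export
gene_count <- function(x) {
  if (is.matrix(x)) return(rowSums(x > 0))
  sum(x > 0)
}

#' Shannon diversity index
#'
#' `-sum(p * log(p))` over positive entries, natural log. Delegates to
#' [vegan::diversity()].
#'
#' @param x nonnegative numeric vector or samples x features matrix.
#' @return numeric scalar (or per-sample vector).
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop_invalid("abundances must be nonnegative")
  vegan::diversity(x, index = "shannon")
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)`, bounded in `[0, 1]` on
#' relative-abundance rows. Delegates to [vegan::vegdist()].
#'
#' @param profile `abundance_profile` or samples x features matrix with
#'   nonnegative rows.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(profile) {
  mat <- as_profile_matrix(profile)
  if (any(mat < 0)) stop_invalid("abundances must be nonnegative")
  if (any(rowSums(mat) == 0)) {
    stop_invalid("Bray-Curtis undefined for all-zero samples")
  }
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Ordinate samples by PCA or PCoA
#'
#' PCA is a centred (not scaled, by default) singular value decomposition of
#' the profile; PCoA is classical multidimensional scaling of a distance
#' matrix, with negative eigenvalues truncated to zero for the
#' explained-variance shares.
#'
#' @param x samples x features matrix/profile (PCA) or a square distance
#'   matrix (PCoA).
#' @param method `"pca"` or `"pcoa"`.
#' @param scale. scale features to unit variance before PCA.
#' @return list: `coordinates` (samples x axes), `explained` (variance
#'   shares, nonincreasing), `method`.
#' @export
ordinate <- function(x, method = c("pca", "pcoa"), scale. = FALSE) {
  method <- match.arg(method)
  if (method == "pca") {
    mat <- as_profile_matrix(x)
    if (nrow(mat) < 3) stop_invalid("ordination needs >= 3 samples")
    keep <- apply(mat, 2, stats::sd) > 0 | !scale.
    fit <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE,
                         scale. = scale.)
    ev <- fit$sdev^2
    list(coordinates = fit$x, explained = ev / sum(ev), method = "pca")
  } else {
    dm <- if (inherits(x, "dist")) as.matrix(x) else as_profile_matrix(x)
    if (nrow(dm) < 3) stop_invalid("ordination needs >= 3 samples")
    k <- nrow(dm) - 1
    # cmdscale warns and trims axes when fewer than k eigenvalues are
    # positive; the trimmed result is exactly what we want
    fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = k,
                                            eig = TRUE))
    pos <- pmax(fit$eig, 0)
    coords <- fit$points
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
    list(coordinates = coords,
         explained = (pos / sum(pos))[seq_len(ncol(coords))],
         method = "pcoa")
  }
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the distance
#' matrix's sum of squares by a single covariate and assesses the pseudo-F by
#' label permutation, `P = (1 + #permuted F >= observed) / (1 + n_perm)`.
#' Delegates to [vegan::adonis2()].
#'
#' @param dm square distance matrix (or `dist`).
#' @param covariate per-sample covariate, categorical or continuous; must not
#'   be constant.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed for the permutation stream.
#' @return list: `R2`, `p`, `F`, `n_perm`.
#' @export
permanova <- function(dm, covariate, n_perm = 9999, seed = NULL) {
  d <- if (inherits(dm, "dist")) dm else stats::as.dist(as_profile_matrix(dm))
  n <- attr(d, "Size")
  if (length(covariate) != n) {
    stop_invalid("covariate length %d != %d samples", length(covariate), n)
  }
  if (length(unique(covariate)) < 2) stop_invalid("covariate is constant")
  if (!is.null(seed)) set.seed(as.integer(seed))
  df <- data.frame(x = covariate)
  fit <- vegan::adonis2(d ~ x, data = df, permutations = n_perm)
  list(R2 = fit$R2[1], p = fit$`Pr(>F)`[1], F = fit$F[1], n_perm = n_perm)
}

# Root Jensen-Shannon divergence between relative-abundance rows — the
# canonical enterotype distance.
.root_jsd <- function(mat) {
  mat <- mat / rowSums(mat)
  n <- nrow(mat)
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  h <- rowSums(xlogx(mat))  # negative entropy per row
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- (mat[i, ] + mat[j, ]) / 2
      jsd <- 0.5 * (h[i] + h[j]) - sum(xlogx(m))
      d[i, j] <- d[j, i] <- sqrt(max(jsd, 0))
    }
  }
  d
}

# Calinski-Harabasz index computed from a distance matrix via the
# within/total sum-of-squares identity sum_{i<j in C} d_ij^2 / |C|.
.ch_index <- function(dm, labels) {
  n <- nrow(dm)
  k <- length(unique(labels))
  d2 <- dm^2
  tss <- sum(d2[upper.tri(d2)]) / n
  wss <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      wss <- wss + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  bss <- tss - wss
  (bss / (k - 1)) / (wss / (n - k))
}

#' Enterotype samples by PAM clustering of genus profiles
#'
#' Clusters samples with partitioning around medoids on a genus-level
#' distance matrix (root Jensen-Shannon divergence by default, the canonical
#' enterotype choice; Bray-Curtis by flag) for each candidate `k`, and picks
#' the `k` maximising the Calinski-Harabasz index (`k = 1` is excluded by
#' construction, the index being undefined there). When group labels are
#' supplied, the enterotype x group contingency is tested by Fisher's exact
#' test.
#'
#' @param genus_profile genus-level `abundance_profile` or matrix.
#' @param k_range candidate cluster numbers (default `2:6`).
#' @param distance `"jsd"` (root Jensen-Shannon) or `"bray"`.
#' @param groups optional named factor of case/control labels.
#' @param seed RNG seed (PAM on a fixed distance matrix is deterministic;
#'   kept for interface stability and recorded in the output).
#' @return list: `labels` (cluster per sample), `k` (CH-optimal), `ch`
#'   (index per candidate k), `medoids`, `distance`, `group_test`
#'   (Fisher P or NULL).
#' @export
enterotype <- function(genus_profile, k_range = 2:6,
                       distance = c("jsd", "bray"), groups = NULL,
                       seed = 1L) {
  distance <- match.arg(distance)
  mat <- as_profile_matrix(genus_profile)
  if (nrow(mat) < max(k_range) + 1) {
    stop_invalid("need more samples than max(k_range)")
  }
  dm <- if (distance == "jsd") .root_jsd(mat) else bray_curtis(mat)
  if (all(dm < 1e-12)) stop_invalid("all samples identical; enterotyping undefined")
  set.seed(as.integer(seed))
  fits <- lapply(k_range, function(k) {
    cluster::pam(stats::as.dist(dm), k = k, diss = TRUE)
  })
  ch <- vapply(fits, function(f) .ch_index(dm, f$clustering), numeric(1))
  names(ch) <- paste0("k", k_range)
  best <- which.max(ch)
  lab <- fits[[best]]$clustering
  names(lab) <- rownames(mat)
  gt <- NULL
  if (!is.null(groups)) {
    gt <- stats::fisher.test(table(lab, groups[names(lab)]))$p.value
  }
  list(labels = lab, k = k_range[best], ch = ch,
       medoids = fits[[best]]$medoids, distance = distance,
       group_test = gt, seed = as.integer(seed))
}

#' Within- versus between-group distance comparison
#'
#' In `"group"` mode, splits all pairwise distances into within-group and
#' between-group sets and compares them by a two-sided Wilcoxon rank-sum
#' test (community dissimilarity between cases and controls versus within
#' each group). In `"baseline"` mode, returns the distance of each sample to
#' its own baseline per timepoint — the longitudinal treatment-response view.
#'
#' @param dm square distance matrix.
#' @param labels two-level group factor (group mode), each level with >= 2
#'   samples.
#' @param mode `"group"` or `"baseline"`.
#' @param pairing for baseline mode: data.frame with columns `baseline`,
#'   `followup`, `timepoint` naming rows of `dm`.
#' @return group mode: list with `within`, `between` (distance vectors),
#'   `p` (Wilcoxon; 1 when all distances are identical), `mean_within`,
#'   `mean_between`, `median_within`, `median_between`. Baseline mode:
#'   data.frame `timepoint`, `distance`.
#' @export
group_distance_comparison <- function(dm, labels = NULL,
                                      mode = c("group", "baseline"),
                                      pairing = NULL) {
  mode <- match.arg(mode)
  dm <- if (inherits(dm, "dist")) as.matrix(dm) else as_profile_matrix(dm)
  if (mode == "baseline") {
    stopifnot(is.data.frame(pairing),
              all(c("baseline", "followup", "timepoint") %in% names(pairing)))
    return(data.frame(
      timepoint = pairing$timepoint,
      distance = dm[cbind(pairing$baseline, pairing$followup)]
    ))
  }
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_invalid("need exactly two groups")
  if (any(table(labels) < 2)) stop_invalid("each group needs >= 2 samples")
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(dm)
  within <- dm[ut & same]
  between <- dm[ut & !same]
  p <- if (stats::sd(c(within, between)) == 0) 1 else
    suppressWarnings(stats::wilcox.test(within, between)$p.value)
  list(within = within, between = between, p = p,
       mean_within = mean(within), mean_between = mean(between),
       median_within = stats::median(within),
       median_between = stats::median(between))
}
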