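# Feature-wise case-control and longitudinal testing with FDR control,
# direction calls, and discovery/validation replication.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement, via
#' [stats::p.adjust()]. Input values must lie in `[0, 1]`.
#'
#' @param p numeric vector of raw P values.
#' @return q values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_invalid("P values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# One two-sided rank-sum test; constant features get P = 1 instead of NA so
# they stay in the BH family without claiming signal.
.wilcox_p <- function(x, g1, g2) {
  if (stats::sd(x) == 0) return(1)
  suppressWarnings(stats::wilcox.test(x[g1], x[g2])$p.value)
}

#' Differential abundance between two groups
#'
#' Two-sided Wilcoxon rank-sum test per feature, BH adjustment across all
#' features at the level tested, and an enrichment direction determined by
#' the group with the higher mean rank. Constant features are recorded with
#' `P = 1` (not dropped), and features identical across groups have an
#' undefined direction.
#'
#' @param profile `abundance_profile` or samples x features matrix.
#' @param labels two-level factor; the **second** level is treated as "case"
#'   (use `factor(..., levels = c("control", "case"))`). Each group needs
#'   >= 3 samples.
#' @param fdr_cutoff significance threshold on q (stored, used by
#'   [replication_check()] and the classifier).
#' @return data.frame of class `differential_result`: `feature`, `p`, `q`,
#'   `direction` (`"case-enriched"` / `"control-enriched"` / NA),
#'   `mean_rank_case`, `mean_rank_control`, `median_case`, `median_control`,
#'   with `fdr_cutoff` as an attribute.
#' @export
differential_abundance <- function(profile, labels, fdr_cutoff = 0.05) {
  mat <- as_profile_matrix(profile)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_invalid("labels must have two levels")
  if (any(table(labels) < 3)) stop_invalid("each group needs >= 3 samples")
  case <- labels == levels(labels)[2]
  ctrl <- !case
  n_feat <- ncol(mat)
  p <- numeric(n_feat)
  mr_case <- mr_ctrl <- numeric(n_feat)
  for (j in seq_len(n_feat)) {
    x <- mat[, j]
    p[j] <- .wilcox_p(x, case, ctrl)
    r <- rank(x)
    mr_case[j] <- mean(r[case])
    mr_ctrl[j] <- mean(r[ctrl])
  }
  direction <- ifelse(mr_case > mr_ctrl, "case-enriched",
                      ifelse(mr_case < mr_ctrl, "control-enriched",
                             NA_character_))
  out <- data.frame(
    feature = colnames(mat) %||% as.character(seq_len(n_feat)),
    p = p, q = bh_adjust(p), direction = direction,
    mean_rank_case = mr_case, mean_rank_control = mr_ctrl,
    median_case = apply(mat[case, , drop = FALSE], 2, stats::median),
    median_control = apply(mat[ctrl, , drop = FALSE], 2, stats::median),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Paired (longitudinal) differential test
#'
#' Wilcoxon signed-rank test per feature between two timepoints of the same
#' subjects; direction by the sign of the median paired difference
#' (`t1 - t0`).
#'
#' @param profile_t0,profile_t1 matrices/profiles with identical features.
#' @param pairing data.frame with columns `t0`, `t1` naming sample rows; at
#'   least 5 complete pairs.
#' @return data.frame: `feature`, `p`, `q`, `direction`
#'   (`"increased"`/`"decreased"`/NA), `median_diff`.
#' @export
paired_differential <- function(profile_t0, profile_t1, pairing) {
  m0 <- as_profile_matrix(profile_t0)
  m1 <- as_profile_matrix(profile_t1)
  stopifnot(identical(colnames(m0), colnames(m1)))
  bad <- !(pairing$t0 %in% rownames(m0)) | !(pairing$t1 %in% rownames(m1))
  if (any(bad)) {
    stop_invalid("broken pairing ids: %s",
                 paste(pairing$t0[bad], pairing$t1[bad], sep = "/",
                       collapse = ", "))
  }
  if (nrow(pairing) < 5) stop_invalid("need >= 5 complete pairs")
  x0 <- m0[pairing$t0, , drop = FALSE]
  x1 <- m1[pairing$t1, , drop = FALSE]
  n_feat <- ncol(m0)
  p <- md <- numeric(n_feat)
  for (j in seq_len(n_feat)) {
    d <- x1[, j] - x0[, j]
    md[j] <- stats::median(d)
    p[j] <- if (all(d == 0)) 1 else
      suppressWarnings(stats::wilcox.test(x1[, j], x0[, j],
                                          paired = TRUE)$p.value)
  }
  data.frame(feature = colnames(m0) %||% as.character(seq_len(n_feat)),
             p = p, q = bh_adjust(p),
             direction = ifelse(md > 0, "increased",
                                ifelse(md < 0, "decreased", NA_character_)),
             median_diff = md, row.names = NULL, stringsAsFactors = FALSE)
}

#' Replication of differential features across cohorts
#'
#' A feature replicates when it is significant in the discovery cohort and
#' significant *with the same direction* in the validation cohort.
#'
#' @param discovery,validation `differential_result` data.frames.
#' @param cutoff significance threshold applied to both cohorts' q values
#'   (set `use = "p"` to threshold raw P in validation, matching reports
#'   that relax the validation criterion).
#' @param use threshold validation on `"q"` (default) or `"p"`.
#' @return character vector of replicated feature ids.
#' @export
replication_check <- function(discovery, validation, cutoff = 0.05,
                              use = c("q", "p")) {
  use <- match.arg(use)
  d_sig <- discovery[discovery$q < cutoff & !is.na(discovery$direction), ,
                     drop = FALSE]
  vcol <- validation[[use]]
  v_sig <- validation[vcol < cutoff & !is.na(validation$direction), ,
                      drop = FALSE]
  m <- merge(d_sig[, c("feature", "direction")],
             v_sig[, c("feature", "direction")],
             by = "feature", suffixes = c("_d", "_v"))
  sort(m$feature[m$direction_d == m$direction_v])
}
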