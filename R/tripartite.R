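# Three-pronged association of species x pathways x clinical indices:
# background-corrected median Spearman correlations between a species (or a
# clinical index) and a pathway's member KOs, plain and BMI-adjusted
# species-clinical correlations, all with per-family BH control.

# Spearman rho of one vector against every column of a matrix.
.spearman_vec <- function(v, mat) {
  suppressWarnings(stats::cor(rank(v), apply(mat, 2, rank)))[1, ]
}

#' Background-corrected species-pathway association
#'
#' Computes Spearman correlations between the species abundance vector and
#' every scored KO; the association with a pathway is the median correlation
#' over member KOs minus the median over all non-member KOs (the background),
#' removing global shifts such as those induced by compositionality. The two
#' correlation sets are compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param species numeric per-sample abundance vector.
#' @param ko_profile samples x KOs matrix (same sample order).
#' @param members character vector of member KO ids; needs >= 2 members with
#'   data and >= 2 non-members.
#' @return list: `corrected` (median in-pathway rho minus median background
#'   rho), `p` (Wilcoxon), `n_in`, `n_out`.
#' @export
species_pathway_score <- function(species, ko_profile, members) {
  mat <- as_profile_matrix(ko_profile)
  stopifnot(length(species) == nrow(mat))
  rho <- .spearman_vec(species, mat)
  inp <- colnames(mat) %in% members
  if (sum(inp) < 2) stop_invalid("pathway needs >= 2 member KOs with data")
  if (sum(!inp) < 2) stop_invalid("empty background: pathway covers (almost) all KOs")
  r_in <- rho[inp]
  r_out <- rho[!inp]
  p <- if (stats::sd(c(r_in, r_out)) == 0) 1 else
    suppressWarnings(stats::wilcox.test(r_in, r_out)$p.value)
  list(corrected = stats::median(r_in) - stats::median(r_out), p = p,
       n_in = sum(inp), n_out = sum(!inp))
}

#' @describeIn species_pathway_score The same machinery with a clinical index
#'   in place of the species abundance vector.
#' @param clinical numeric per-sample clinical index vector.
#' @export
pathway_clinical_score <- function(clinical, ko_profile, members) {
  species_pathway_score(clinical, ko_profile, members)
}

#' All species x pathway association cells
#'
#' Applies [species_pathway_score()] to every species / pathway combination
#' and BH-adjusts the Wilcoxon P values across all cells (one association
#' family). Pathways with fewer than `min_size` scored member KOs are
#' reported unscored (NA).
#'
#' @param species_profile samples x species matrix/profile.
#' @param ko_profile samples x KOs matrix/profile.
#' @param pathways named list of KO-id vectors.
#' @param min_size minimum member KOs for scoring (default 2).
#' @return long-form data.frame: `species`, `pathway`, `corrected`, `p`, `q`.
#' @export
species_pathway_matrix <- function(species_profile, ko_profile, pathways,
                                   min_size = 2) {
  smat <- as_profile_matrix(species_profile)
  kmat <- as_profile_matrix(ko_profile)
  rho <- suppressWarnings(stats::cor(apply(smat, 2, rank),
                                     apply(kmat, 2, rank)))
  cells <- expand.grid(species = colnames(smat), pathway = names(pathways),
                       stringsAsFactors = FALSE)
  cells$corrected <- NA_real_
  cells$p <- NA_real_
  for (pw in names(pathways)) {
    inp <- colnames(kmat) %in% pathways[[pw]]
    rows <- cells$pathway == pw
    if (sum(inp) < min_size || sum(!inp) < 2) next
    for (sp in colnames(smat)) {
      r <- rho[sp, ]
      i <- rows & cells$species == sp
      cells$corrected[i] <- stats::median(r[inp]) - stats::median(r[!inp])
      cells$p[i] <- if (stats::sd(r) == 0) 1 else
        suppressWarnings(stats::wilcox.test(r[inp], r[!inp])$p.value)
    }
  }
  cells$q <- bh_adjust(cells$p)
  cells
}

#' Spearman correlation of every feature with a clinical index
#'
#' Tie-aware Spearman correlations with a t-approximation P value, BH
#' adjusted across features (one family per clinical index). Constant
#' features or a constant index yield NA.
#'
#' @param profile samples x features matrix/profile.
#' @param index numeric clinical vector, same sample order, n >= 5.
#' @return data.frame: `feature`, `rho`, `p`, `q`.
#' @export
feature_clinical_spearman <- function(profile, index) {
  mat <- as_profile_matrix(profile)
  stopifnot(length(index) == nrow(mat))
  if (length(index) < 5) stop_invalid("need n >= 5 samples")
  n <- length(index)
  rho <- p <- rep(NA_real_, ncol(mat))
  if (stats::sd(index) > 0) {
    for (j in seq_len(ncol(mat))) {
      if (stats::sd(mat[, j]) == 0) next
      r <- suppressWarnings(stats::cor(mat[, j], index, method = "spearman"))
      rho[j] <- r
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p[j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  data.frame(feature = colnames(mat) %||% as.character(seq_len(ncol(mat))),
             rho = rho, p = p, q = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partial Spearman correlation
#'
#' First-order partial correlation of the ranks of `x` and `y` given the
#' ranks of a covariate (the BMI adjustment of species-clinical
#' correlations): Pearson on ranks,
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) (1 - r_yz^2))`, with a
#' t-approximation P value at `n - 3` degrees of freedom. A constant
#' covariate falls back to the plain Spearman correlation with a warning.
#'
#' @param x,y,covariate numeric vectors of equal length, n >= 6.
#' @return list: `rho`, `p`, `adjusted` (FALSE when the fallback fired).
#' @export
partial_spearman <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n)
  if (n < 6) stop_invalid("need n >= 6")
  if (stats::sd(covariate) == 0) {
    warning("constant covariate; returning plain Spearman correlation")
    r <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    return(list(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 2),
                adjusted = FALSE))
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- if (denom < .Machine$double.eps) 0 else (rxy - rxz * ryz) / denom
  r <- max(-1, min(1, r))
  tstat <- r * sqrt((n - 3) / max(1 - r^2, .Machine$double.eps))
  list(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 3), adjusted = TRUE)
}

#' Full three-pronged association
#'
#' Computes the three association families of the species / pathway /
#' clinical scheme — species x pathway (background-corrected median Spearman
#' + Wilcoxon), species x clinical (plain and covariate-adjusted Spearman),
#' and pathway x clinical (same background-corrected machinery with the
#' clinical vector) — each BH-adjusted within its own family.
#'
#' @param species_profile samples x species matrix/profile.
#' @param ko_profile samples x KOs matrix/profile.
#' @param pathways named list of KO-id vectors.
#' @param clinical data.frame of clinical indices (numeric columns used).
#' @param adjust_for optional column name in `clinical` (e.g. `"BMI"`) used
#'   as partial-correlation covariate for the species x clinical prong.
#' @return list of class `tripartite_result` with long-form data.frames
#'   `species_pathway`, `species_clinical`, `pathway_clinical`.
#' @export
tripartite_association <- function(species_profile, ko_profile, pathways,
                                   clinical, adjust_for = NULL) {
  smat <- as_profile_matrix(species_profile)
  kmat <- as_profile_matrix(ko_profile)
  idx_cols <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  if (!is.null(adjust_for)) {
    stopifnot(adjust_for %in% names(clinical))
    idx_cols <- setdiff(idx_cols, adjust_for)
  }

  sp_pw <- species_pathway_matrix(smat, kmat, pathways)

  sc <- list()
  for (ix in idx_cols) {
    res <- feature_clinical_spearman(smat, clinical[[ix]])
    res$index <- ix
    if (!is.null(adjust_for)) {
      adj <- t(vapply(seq_len(ncol(smat)), function(j) {
        pr <- partial_spearman(smat[, j], clinical[[ix]],
                               clinical[[adjust_for]])
        c(pr$rho, pr$p)
      }, numeric(2)))
      res$rho_adj <- adj[, 1]
      res$p_adj <- adj[, 2]
      res$q_adj <- bh_adjust(res$p_adj)
    }
    sc[[ix]] <- res
  }
  species_clinical <- do.call(rbind, sc)

  pc <- list()
  for (ix in idx_cols) {
    cells <- species_pathway_matrix(matrix(clinical[[ix]],
                                           ncol = 1,
                                           dimnames = list(rownames(smat), ix)),
                                    kmat, pathways)
    names(cells)[names(cells) == "species"] <- "index"
    pc[[ix]] <- cells
  }
  pathway_clinical <- do.call(rbind, pc)
  pathway_clinical$q <- bh_adjust(pathway_clinical$p)

  structure(list(species_pathway = sp_pw,
                 species_clinical = species_clinical,
                 pathway_clinical = pathway_clinical,
                 adjusted_for = adjust_for),
            class = "tripartite_result")
}
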