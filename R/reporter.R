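# Reporter-score pathway enrichment from KO-level statistics.
#
# Each KO's two-sided P value is converted to a signed Z score; a pathway
# aggregates its member Zs as sum(Z) / sqrt(k) and is corrected against the
# null of k KOs drawn at random from the scored universe, so |score| > 1.65
# corresponds to one-sided 95% normal confidence in either direction.

#' Signed Z score per KO from a two-sided P value
#'
#' `Z = qnorm(1 - p/2)`, given a positive sign for case-enriched KOs and a
#' negative sign for control-enriched ones, so a single score carries both
#' strength and direction. `p = 1` maps to `Z = 0`; `p = 0` is clipped to the
#' smallest positive double with a warning.
#'
#' @param p two-sided P values in `(0, 1]`.
#' @param direction character vector, `"case-enriched"` or
#'   `"control-enriched"` per KO (anything else, e.g. NA for an undefined
#'   direction, gets sign 0).
#' @return named numeric vector of signed Z scores.
#' @export
ko_zscore <- function(p, direction) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_invalid("P values must be in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("P = 0 clipped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  z <- stats::qnorm(p / 2, lower.tail = FALSE)  # stable for tiny p
  s <- ifelse(is.na(direction), 0,
              ifelse(direction == "case-enriched", 1,
                     ifelse(direction == "control-enriched", -1, 0)))
  out <- s * z
  names(out) <- names(p)
  out
}

#' Reporter scores for pathways
#'
#' For a pathway with `k` scored member KOs, the raw aggregate is
#' `Z_pathway = sum(Z_members) / sqrt(k)`. The background-corrected reporter
#' score is `(Z_pathway - mu_k) / sigma_k`, with `mu_k` and `sigma_k` the
#' mean and standard deviation of the same statistic over `n_background`
#' random size-`k` KO sets drawn (without replacement within a set) from all
#' scored KOs. Pathways are significant at `|score| > cutoff` (default 1.65,
#' the one-sided 95% normal quantile as conventionally printed).
#'
#' @param z named vector of signed KO Z scores (see [ko_zscore()]).
#' @param pathways named list of KO-id character vectors (GMT-style).
#' @param n_background random background sets per pathway size (default 1000).
#' @param seed RNG seed for the background draws.
#' @param cutoff significance threshold on `|score|`.
#' @return data.frame of class `reporter_result`: `pathway`, `k`, `z_raw`,
#'   `score`, `direction` (`"case"`/`"control"`), `significant`.
#' @export
reporter_score <- function(z, pathways, n_background = 1000, seed = 1L,
                           cutoff = 1.65) {
  z <- z[is.finite(z)]
  if (!length(z)) stop_invalid("no scored KOs")
  ks <- vapply(pathways, function(m) sum(m %in% names(z)), integer(1))
  if (any(ks < 1)) {
    stop_invalid("pathway(s) with no scored KO: %s",
                 paste(names(pathways)[ks < 1], collapse = ", "))
  }
  if (any(ks >= length(z))) {
    stop_invalid("pathway size >= KO universe (%d): %s", length(z),
                 paste(names(pathways)[ks >= length(z)], collapse = ", "))
  }
  set.seed(as.integer(seed))
  mu <- sig <- numeric(max(ks))
  for (k in sort(unique(ks))) {   # sorted: deterministic RNG consumption
    draws <- vapply(seq_len(n_background),
                    function(i) sum(sample(z, k)), numeric(1)) / sqrt(k)
    mu[k] <- mean(draws)
    sig[k] <- stats::sd(draws)
  }
  z_raw <- vapply(seq_along(pathways), function(i) {
    sum(z[pathways[[i]][pathways[[i]] %in% names(z)]]) / sqrt(ks[i])
  }, numeric(1))
  score <- ifelse(sig[ks] > 0, (z_raw - mu[ks]) / sig[ks],
                  0)  # constant background (e.g. all Z equal): no enrichment
  out <- data.frame(
    pathway = names(pathways) %||% as.character(seq_along(pathways)),
    k = ks, z_raw = z_raw, score = score,
    direction = ifelse(score >= 0, "case", "control"),
    significant = abs(score) > cutoff,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "n_background") <- n_background
  class(out) <- c("reporter_result", "data.frame")
  out
}

#' Split significant pathways by direction
#'
#' Filters reporter results at `|score| > cutoff` (strict) and splits by
#' enrichment direction.
#'
#' @param results a `reporter_result` data.frame.
#' @param cutoff score threshold (default 1.65).
#' @return list: `case` and `control` character vectors of pathway ids.
#' @export
threshold_pathways <- function(results, cutoff = 1.65) {
  sig <- results[abs(results$score) > cutoff, , drop = FALSE]
  list(case = sig$pathway[sig$score > 0],
       control = sig$pathway[sig$score < 0])
}
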