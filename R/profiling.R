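# Gene, taxon and KO relative-abundance profiles from read-mapping tables.
#
# The abundance engine splits every gene's reads into a unique part U and a
# multi-mapped part M. Unique abundance is Ab(U) = U / L (L = gene length);
# each multi-read group with count M over a candidate gene set is
# redistributed by the coefficient Co_i = Ab(U)_i / sum_{j in set} Ab(U)_j,
# contributing Ab(M)_i = M * Co_i / L_i; the relative abundance Ab(G) is the
# per-sample normalisation of Ab(U) + Ab(M).

#' Gene relative abundance for one sample
#'
#' Computes the unique-read abundance `U / L` per gene, redistributes every
#' multi-read group across its candidate genes proportional to their
#' unique-read abundance (a group whose candidates all have zero unique
#' abundance is split equally, so no reads are dropped; a message flags this),
#' and normalises to relative abundance.
#'
#' @param sample a [read_map_sample()].
#' @param catalog a `gene_catalog` supplying gene lengths.
#' @return list: `abundance` (unnormalised `Ab(U) + Ab(M)` over all catalog
#'   genes), `relative` (normalised to sum 1). A sample with zero total
#'   abundance returns an all-zero `relative` with a warning.
#' @examples
#' cat <- generate_catalog(5, 2, seed = 1)
#' s <- read_map_sample("s1", c(gene_000001 = 10, gene_000002 = 5))
#' gene_abundance(s, cat)$relative
#' @export
gene_abundance <- function(sample, catalog) {
  stopifnot(inherits(sample, "read_map_sample"),
            inherits(catalog, "gene_catalog"))
  L <- stats::setNames(as.numeric(catalog$genes$length), catalog$genes$gene_id)
  seen <- c(names(sample$unique_counts),
            unlist(lapply(sample$multi_groups, `[[`, "genes")))
  unknown <- setdiff(seen, names(L))
  if (length(unknown)) {
    stop_invalid("gene ids not in catalog: %s",
                 paste(utils::head(unknown, 5), collapse = ", "))
  }
  ab_u <- stats::setNames(numeric(length(L)), names(L))
  if (length(sample$unique_counts)) {
    ab_u[names(sample$unique_counts)] <-
      sample$unique_counts / L[names(sample$unique_counts)]
  }
  ab_m <- stats::setNames(numeric(length(L)), names(L))
  degenerate <- 0L
  for (g in sample$multi_groups) {
    s <- g$genes
    w <- ab_u[s]
    tot <- sum(w)
    co <- if (tot > 0) w / tot else {
      degenerate <- degenerate + 1L
      rep(1 / length(s), length(s))
    }
    ab_m[s] <- ab_m[s] + g$count * co / L[s]
  }
  if (degenerate > 0) {
    message(sprintf("%s: %d multi-read group(s) with all-zero unique abundance split equally",
                    sample$sample_id, degenerate))
  }
  ab <- ab_u + ab_m
  tot <- sum(ab)
  rel <- if (tot > 0) ab / tot else {
    warning(sprintf("sample %s has zero total abundance", sample$sample_id))
    ab
  }
  list(abundance = ab, relative = rel)
}

#' Build a gene-level profile from many samples
#'
#' @param samples list of `read_map_sample`s.
#' @param catalog a `gene_catalog`.
#' @return an [abundance_profile()] at gene level (samples x genes).
#' @export
build_gene_profile <- function(samples, catalog) {
  rows <- lapply(samples, function(s) gene_abundance(s, catalog)$relative)
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(samples, `[[`, character(1), "sample_id")
  abundance_profile(mat, level = "gene")
}

#' Downsample a read-mapping record to a fixed read total
#'
#' Uniform sampling without replacement over the whole read population of the
#' sample — unique reads and multi-read instances alike — matching the
#' practice of rarefying every sample to the same number of matched reads
#' before diversity analysis.
#'
#' @param sample a `read_map_sample`.
#' @param target_reads reads to keep; must not exceed the sample total.
#' @param seed optional RNG seed.
#' @return a `read_map_sample` with exactly `target_reads` reads.
#' @export
downsample_reads <- function(sample, target_reads, seed = NULL) {
  stopifnot(inherits(sample, "read_map_sample"))
  tot <- total_reads(sample)
  if (target_reads > tot) {
    stop_invalid("target %d exceeds total %d reads in sample %s",
                 target_reads, tot, sample$sample_id)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (target_reads == tot) return(sample)
  counts <- c(sample$unique_counts,
              vapply(sample$multi_groups, `[[`, numeric(1), "count"))
  n_u <- length(sample$unique_counts)
  pop <- rep.int(seq_along(counts), counts)
  keep <- tabulate(sample(pop, target_reads), nbins = length(counts))
  uniq <- keep[seq_len(n_u)]
  names(uniq) <- names(sample$unique_counts)
  groups <- list()
  for (i in seq_along(sample$multi_groups)) {
    k <- keep[n_u + i]
    if (k > 0) {
      groups[[length(groups) + 1L]] <-
        list(genes = sample$multi_groups[[i]]$genes, count = as.numeric(k))
    }
  }
  read_map_sample(sample$sample_id, uniq[uniq > 0], groups)
}

#' Prevalence filter
#'
#' Keeps features detected (strictly positive abundance) in at least
#' `ceiling(min_fraction * n_samples)` samples. Retained rows are not
#' renormalised.
#'
#' @param profile an `abundance_profile` or samples x features matrix.
#' @param min_fraction minimum detection fraction, in `(0, 1]`; default 0.10.
#' @return object of the same type with the filtered feature set.
#' @export
prevalence_filter <- function(profile, min_fraction = 0.10) {
  if (min_fraction <= 0 || min_fraction > 1) {
    stop_invalid("min_fraction must be in (0, 1]")
  }
  mat <- as_profile_matrix(profile)
  need <- ceiling(min_fraction * nrow(mat))
  keep <- colSums(mat > 0) >= need
  if (inherits(profile, "abundance_profile")) {
    meta <- profile$metadata
    if (!is.null(meta)) meta <- meta[keep, , drop = FALSE]
    abundance_profile(mat[, keep, drop = FALSE], profile$level, meta)
  } else {
    mat[, keep, drop = FALSE]
  }
}

#' Consensus taxonomy assignment from alignment hits
#'
#' Hits with gene coverage below 70% or identity below 65% are discarded. At
#' each rank only hits whose identity exceeds the rank's similarity threshold
#' (phylum > 65%, genus > 85%, species > 95%) are considered, and the rank is
#' assigned to the taxon named by at least half of those hits; an exact tie
#' between two taxa at 50% each is no consensus, so the rank stays
#' unassigned. Ranks are decided independently but emitted as a consistent
#' lineage: a child rank is blanked when its parent is unassigned.
#'
#' @param hits data.frame with columns `gene_id`, `phylum`, `genus`,
#'   `species`, `identity`, `coverage` (percentages), one row per hit.
#' @param min_coverage,min_identity global hit-retention thresholds.
#' @param rank_identity named vector of per-rank identity thresholds
#'   (strictly exceeded).
#' @return data.frame, one row per gene: `gene_id`, `phylum`, `genus`,
#'   `species` (NA where unassigned).
#' @export
assign_taxonomy <- function(hits,
                            min_coverage = 70, min_identity = 65,
                            rank_identity = c(phylum = 65, genus = 85,
                                              species = 95)) {
  stopifnot(all(c("gene_id", "phylum", "genus", "species",
                  "identity", "coverage") %in% names(hits)))
  ids <- unique(hits$gene_id)
  hits <- hits[hits$coverage >= min_coverage & hits$identity >= min_identity, ,
               drop = FALSE]
  consensus <- function(taxa) {
    taxa <- taxa[!is.na(taxa)]
    if (!length(taxa)) return(NA_character_)
    tab <- table(taxa)
    top <- max(tab)
    if (top / length(taxa) < 0.5) return(NA_character_)
    if (sum(tab == top) > 1) return(NA_character_)  # a tie is not a consensus
    names(tab)[which.max(tab)]
  }
  out <- data.frame(gene_id = ids, phylum = NA_character_,
                    genus = NA_character_, species = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    h <- hits[hits$gene_id == ids[i], , drop = FALSE]
    for (rk in c("phylum", "genus", "species")) {
      hh <- h[h$identity > rank_identity[[rk]], , drop = FALSE]
      out[[rk]][i] <- consensus(hh[[rk]])
    }
  }
  out$genus[is.na(out$phylum)] <- NA_character_
  out$species[is.na(out$genus)] <- NA_character_
  out
}

#' Feature maps from a catalog
#'
#' Named character vectors mapping gene id to its taxon at the given rank, or
#' to its KO; genes without an assignment are omitted (they contribute to no
#' aggregated group).
#'
#' @param catalog a `gene_catalog`.
#' @param rank one of `"phylum"`, `"genus"`, `"species"`.
#' @return named character vector, gene id -> group.
#' @export
taxon_map <- function(catalog, rank = c("species", "genus", "phylum")) {
  rank <- match.arg(rank)
  g <- catalog$genes
  keep <- !is.na(g[[rank]])
  stats::setNames(g[[rank]][keep], g$gene_id[keep])
}

#' @rdname taxon_map
#' @export
ko_map <- function(catalog) {
  g <- catalog$genes
  keep <- !is.na(g$ko)
  stats::setNames(g$ko[keep], g$gene_id[keep])
}

#' Aggregate a gene-level profile to taxon or KO level
#'
#' Group abundance is the sum of member-gene relative abundances; unannotated
#' genes contribute to no group, so aggregated row sums are at most 1 (the
#' remainder is the unannotated mass).
#'
#' @param profile gene-level `abundance_profile` or matrix.
#' @param map named character vector, gene id -> group (see [taxon_map()]).
#' @param level level label for the result.
#' @return an [abundance_profile()] at the requested level.
#' @export
aggregate_profile <- function(profile, map, level = "species") {
  mat <- as_profile_matrix(profile)
  map <- map[names(map) %in% colnames(mat)]
  if (!length(map)) {
    return(abundance_profile(matrix(0, nrow(mat), 0,
                                    dimnames = list(rownames(mat), NULL)),
                             level))
  }
  sub <- mat[, names(map), drop = FALSE]
  agg <- t(rowsum(t(sub), group = unname(map)))
  abundance_profile(agg[, order(colnames(agg)), drop = FALSE], level)
}

#' Bacteroidetes/Firmicutes ratio per sample
#'
#' A coarse dysbiosis indicator. A sample with zero Firmicutes abundance gets
#' `Inf`, flagged via the `degenerate` attribute so downstream tests can
#' exclude it.
#'
#' @param phylum_profile phylum-level profile containing both phyla.
#' @param bacteroidetes,firmicutes feature names of the two phyla.
#' @return named numeric vector of ratios with attribute `degenerate`
#'   (logical vector marking infinite entries).
#' @export
bf_ratio <- function(phylum_profile, bacteroidetes = "p__Bacteroidetes",
                     firmicutes = "p__Firmicutes") {
  mat <- as_profile_matrix(phylum_profile)
  missing <- setdiff(c(bacteroidetes, firmicutes), colnames(mat))
  if (length(missing)) {
    stop_invalid("phylum feature(s) absent: %s", paste(missing, collapse = ", "))
  }
  r <- mat[, bacteroidetes] / mat[, firmicutes]
  attr(r, "degenerate") <- !is.finite(r)
  r
}

#' Filter homology hits for functional gene profiling
#'
#' Best-hit filter used for enzyme (e.g. short-chain fatty acid biosynthesis)
#' profiles: keep, per gene, the hit with the lowest e-value among hits with
#' e-value < 1e-5, identity > 70% and coverage > 70% (ties broken by higher
#' identity).
#'
#' @param hits data.frame with columns `gene_id`, `subject`, `evalue`,
#'   `identity`, `coverage`.
#' @param max_evalue,min_identity,min_coverage thresholds (strict).
#' @return named character vector, gene id -> subject (enzyme).
#' @export
filter_function_hits <- function(hits, max_evalue = 1e-5, min_identity = 70,
                                 min_coverage = 70) {
  stopifnot(all(c("gene_id", "subject", "evalue", "identity", "coverage")
                %in% names(hits)))
  keep <- hits$evalue < max_evalue & hits$identity > min_identity &
    hits$coverage > min_coverage
  h <- hits[keep, , drop = FALSE]
  if (!nrow(h)) return(stats::setNames(character(0), character(0)))
  h <- h[order(h$gene_id, h$evalue, -h$identity), , drop = FALSE]
  h <- h[!duplicated(h$gene_id), , drop = FALSE]
  stats::setNames(h$subject, h$gene_id)
}
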