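# Synthetic community generator: gene catalogs, read-mapping tables and
# clinical tables with planted, known ground truth, so every downstream stage
# of the pipeline can be exercised and verified offline.

#' Generate a synthetic microbial gene catalog
#'
#' Builds a reference gene catalog in which every gene carries a length, a
#' species-level lineage (species nested in genus nested in phylum) and,
#' for a configurable fraction of genes, a KO (KEGG Ortholog) assignment.
#' A fraction of genes is grouped into paralog families shared by at least
#' two species; multi-mapped reads are later drawn only within these
#' families. KOs are grouped into pathways emitted as a GMT-style list.
#'
#' @param n_genes number of genes; every species is guaranteed at least one.
#' @param n_species number of species; species are nested into
#'   `ceiling(n_species / 3)` genera and up to 6 phyla.
#' @param n_kos size of the KO universe.
#' @param n_pathways number of KO pathways to emit.
#' @param paralog_fraction fraction of genes placed into paralog families.
#' @param paralog_family_size integer range (length-2) of family sizes.
#' @param ko_fraction fraction of genes that receive a KO assignment.
#' @param seed integer RNG seed; identical seeds give identical catalogs.
#' @return A list of class `gene_catalog` with elements `genes` (data.frame:
#'   `gene_id`, `length`, `phylum`, `genus`, `species`, `ko`), `pathways`
#'   (named list of KO character vectors) and `paralog_families` (list of
#'   gene-id character vectors, each spanning >= 2 species).
#' @export
generate_catalog <- function(n_genes, n_species, n_kos = 200, n_pathways = 20,
                             paralog_fraction = 0.10,
                             paralog_family_size = c(2L, 4L),
                             ko_fraction = 0.7, seed = 1L) {
  if (n_genes < 0 || n_species < 0 || n_kos < 0) {
    stop_invalid("counts must be nonnegative")
  }
  if (n_genes > 0 && (n_species < 1 || n_genes < n_species)) {
    stop_invalid("need 1 <= n_species <= n_genes")
  }
  set.seed(as.integer(seed))

  if (n_genes == 0) {
    genes <- data.frame(gene_id = character(), length = integer(),
                        phylum = character(), genus = character(),
                        species = character(), ko = character(),
                        stringsAsFactors = FALSE)
    return(structure(list(genes = genes, pathways = list(),
                          paralog_families = list()),
                     class = "gene_catalog"))
  }

  n_phyla <- min(6L, n_species)
  n_genera <- max(n_phyla, ceiling(n_species / 3))
  phyla <- sprintf("p__Phylum%02d", seq_len(n_phyla))
  # first two phyla mimic the dominant gut phyla so B/F ratios are computable
  if (n_phyla >= 2) phyla[1:2] <- c("p__Bacteroidetes", "p__Firmicutes")
  genus_phylum <- phyla[1 + (seq_len(n_genera) - 1L) %% n_phyla]
  genera <- sprintf("g__Genus%03d", seq_len(n_genera))
  species_genus <- 1 + (seq_len(n_species) - 1L) %% n_genera
  species <- sprintf("s__Species%04d", seq_len(n_species))

  # every species owns >= 1 gene; the rest are spread with uneven weights
  sp_of_gene <- integer(n_genes)
  sp_of_gene[seq_len(n_species)] <- seq_len(n_species)
  if (n_genes > n_species) {
    w <- rexp(n_species) + 0.1
    sp_of_gene[(n_species + 1L):n_genes] <-
      sample.int(n_species, n_genes - n_species, replace = TRUE, prob = w)
  }
  sp_of_gene <- sample(sp_of_gene)  # shuffle so gene order carries no signal

  lens <- pmax(100L, as.integer(round(rlnorm(n_genes, log(800), 0.45))))
  gene_id <- sprintf("gene_%06d", seq_len(n_genes))

  ko_pool <- sprintf("K%05d", seq_len(n_kos))
  ko <- rep(NA_character_, n_genes)
  n_annot <- round(ko_fraction * n_genes)
  if (n_annot > 0 && n_kos > 0) {
    idx <- sample.int(n_genes, n_annot)
    ko[idx] <- sample(ko_pool, n_annot, replace = TRUE)
  }

  genes <- data.frame(
    gene_id = gene_id,
    length = lens,
    phylum = genus_phylum[species_genus[sp_of_gene]],
    genus = genera[species_genus[sp_of_gene]],
    species = species[sp_of_gene],
    ko = ko,
    stringsAsFactors = FALSE
  )

  # paralog families: members drawn from distinct species
  fams <- list()
  n_paralog <- floor(paralog_fraction * n_genes)
  if (n_paralog >= 2 && n_species >= 2) {
    pool <- sample.int(n_genes, n_paralog)
    fi <- 1L
    while (length(pool) >= 2) {
      size <- sample(seq(paralog_family_size[1], paralog_family_size[2]), 1L)
      size <- min(size, length(pool))
      if (size < 2) break
      # greedily pick genes of distinct species
      picked <- integer(0)
      for (g in pool) {
        if (!(sp_of_gene[g] %in% sp_of_gene[picked])) picked <- c(picked, g)
        if (length(picked) == size) break
      }
      if (length(picked) < 2) break
      fams[[fi]] <- gene_id[picked]
      fi <- fi + 1L
      pool <- setdiff(pool, picked)
    }
  }

  pathways <- list()
  if (n_pathways > 0 && n_kos >= 2) {
    for (p in seq_len(n_pathways)) {
      size <- sample(5:min(25L, n_kos), 1L)
      pathways[[sprintf("path%03d", p)]] <- sort(sample(ko_pool, size))
    }
  }

  # population-level base log2 abundance per species: a property of the
  # simulated community, shared by every cohort drawn from this catalog
  species_mean <- stats::setNames(stats::rnorm(n_species, 0, 2),
                                  sort(species))

  structure(list(genes = genes, pathways = pathways,
                 paralog_families = fams, species_mean = species_mean),
            class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes, %d species, %d paralog families, %d pathways\n",
              nrow(x$genes), length(unique(x$genes$species)),
              length(x$paralog_families), length(x$pathways)))
  invisible(x)
}

#' Describe a synthetic case-control cohort
#'
#' Bundles all parameters of a simulated cohort: sample sizes, the planted
#' species effects (log2 fold changes applied to cases), sequencing depth,
#' multi-mapping rate and the clinical-index generative model.
#'
#' Species log2 abundances are drawn per sample as
#' `Normal(mu_species, sd = 1)` on the log2 scale, exponentiated and
#' renormalised to the simplex; planted species have the stated log2 effect
#' added in cases. The log2 scale is used throughout so that planted effect
#' sizes and between-sample noise share units.
#'
#' @param n_case,n_control per-group sample counts (each >= 2).
#' @param planted data.frame with columns `species` and `log2_effect`
#'   (positive = case-enriched), or `NULL` for no planted effects.
#' @param depth target mapped reads per sample.
#' @param multiread_rate probability that a read landing on a paralog-family
#'   gene is emitted as a multi-read group over that family (reads on
#'   non-family genes are always unique), in `[0, 1)`.
#' @param clinical_model named list, one entry per clinical index:
#'   `list(intercept =, coef = c(species = value), sd =)`. `NULL` uses
#'   [default_clinical_model()] at cohort-generation time.
#' @param seed integer RNG seed.
#' @return list of class `cohort_design`.
#' @export
cohort_design <- function(n_case, n_control, planted = NULL, depth = 20000L,
                          multiread_rate = 0.1, clinical_model = NULL,
                          seed = 1L) {
  if (n_case < 2 || n_control < 2) stop_invalid("need n_case, n_control >= 2")
  if (depth <= 0) stop_invalid("depth must be positive")
  if (multiread_rate < 0 || multiread_rate >= 1) {
    stop_invalid("multiread_rate must be in [0, 1)")
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("species", "log2_effect") %in% names(planted)))
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 planted = planted, depth = as.integer(depth),
                 multiread_rate = multiread_rate,
                 clinical_model = clinical_model, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default planted-effect table for a catalog
#'
#' Picks `n` species and assigns alternating-direction log2 effects with
#' magnitudes spread over `[1, 2.5]` — effect sizes a shotgun case-control
#' study would call moderate-to-strong and that rank tests at n of tens per
#' group can detect.
#'
#' @param catalog a `gene_catalog`.
#' @param n number of planted species.
#' @param seed RNG seed for the species draw.
#' @return data.frame with `species`, `log2_effect`.
#' @export
default_planted <- function(catalog, n = 50L, seed = 1L) {
  sp <- unique(catalog$genes$species)
  if (length(sp) < n) stop_invalid("catalog has only %d species", length(sp))
  set.seed(as.integer(seed))
  chosen <- sample(sp, n)
  mag <- seq(1, 2.5, length.out = n)
  data.frame(species = chosen,
             log2_effect = mag * rep_len(c(1, -1), n),
             stringsAsFactors = FALSE)
}

#' Simulate ground-truth species relative abundances
#'
#' The generative core shared by [generate_cohort()] and
#' [generate_longitudinal()]: per-species base means `mu ~ N(0, 2)` (log2),
#' per-sample log2 abundances `mu + N(0, 1)`, planted case effects added,
#' then `2^x` renormalised to relative abundances.
#'
#' @param species character vector of species names.
#' @param design a `cohort_design`.
#' @param mu optional named vector of base log2 means (one per species);
#'   supplied by [generate_cohort()] from the catalog so that every cohort
#'   drawn from one catalog shares the same population. When `NULL`, means
#'   are drawn under the design seed.
#' @return list with `truth` (samples x species relative-abundance matrix),
#'   `labels` (factor case/control named by sample) and `mu` (base log2 means).
#' @export
simulate_species_truth <- function(species, design, mu = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  n_sp <- length(species)
  if (!is.null(design$planted)) {
    missing <- setdiff(design$planted$species, species)
    if (length(missing)) {
      stop_invalid("planted species absent from catalog: %s",
                   paste(missing, collapse = ", "))
    }
  }
  set.seed(design$seed)
  if (is.null(mu)) {
    mu <- stats::rnorm(n_sp, 0, 2)
    names(mu) <- species
  } else {
    stopifnot(all(species %in% names(mu)))
    mu <- mu[species]
  }
  n <- design$n_case + design$n_control
  labels <- factor(rep(c("case", "control"),
                       c(design$n_case, design$n_control)),
                   levels = c("control", "case"))
  ids <- c(sprintf("case_%03d", seq_len(design$n_case)),
           sprintf("ctrl_%03d", seq_len(design$n_control)))
  names(labels) <- ids

  eff <- numeric(n_sp)
  names(eff) <- species
  if (!is.null(design$planted)) {
    eff[design$planted$species] <- design$planted$log2_effect
  }

  x <- matrix(stats::rnorm(n * n_sp, 0, 1), n, n_sp, byrow = FALSE)
  x <- sweep(x, 2, mu, `+`)
  x[labels == "case", ] <- sweep(x[labels == "case", , drop = FALSE], 2, eff, `+`)
  ab <- 2^x
  ab <- ab / rowSums(ab)
  dimnames(ab) <- list(ids, species)
  list(truth = ab, labels = labels, mu = mu)
}

#' A per-sample read-mapping record
#'
#' Holds the unique-read counts (`U` of the abundance equations) and the
#' multi-read groups: reads whose alignment was ambiguous among a set of
#' `N >= 2` candidate genes, recorded as (gene set, read count).
#'
#' @param sample_id sample identifier.
#' @param unique_counts named numeric vector, gene id -> unique read count.
#' @param multi_groups list of `list(genes = <character, length >= 2>,
#'   count = <numeric>)`.
#' @return object of class `read_map_sample`.
#' @export
read_map_sample <- function(sample_id, unique_counts,
                            multi_groups = list()) {
  if (length(unique_counts) && is.null(names(unique_counts))) {
    stop_invalid("unique_counts must be named by gene id")
  }
  if (any(unique_counts < 0)) stop_invalid("counts must be >= 0")
  for (g in multi_groups) {
    if (length(g$genes) < 2) stop_invalid("multi-read group needs >= 2 genes")
    if (g$count < 0) stop_invalid("counts must be >= 0")
  }
  structure(list(sample_id = sample_id,
                 unique_counts = unique_counts,
                 multi_groups = multi_groups),
            class = "read_map_sample")
}

#' Total mapped reads of a read-mapping record
#' @param sample a `read_map_sample`.
#' @return numeric scalar: unique reads plus multi-group reads.
#' @export
total_reads <- function(sample) {
  sum(sample$unique_counts) +
    sum(vapply(sample$multi_groups, function(g) g$count, numeric(1)))
}

# Draw one sample's reads from a species relative-abundance row.
# Gene probability = species abundance x (gene length / species length sum);
# reads on paralog-family genes become multi-read groups with prob
# multiread_rate.
.sample_reads <- function(truth_row, catalog, design, sample_id) {
  genes <- catalog$genes
  sp_len <- tapply(genes$length, genes$species, sum)
  p <- truth_row[genes$species] * genes$length / sp_len[genes$species]
  p[is.na(p)] <- 0
  counts <- as.vector(stats::rmultinom(1, design$depth, p))
  names(counts) <- genes$gene_id

  fam_of <- rep(NA_integer_, nrow(genes))
  names(fam_of) <- genes$gene_id
  for (i in seq_along(catalog$paralog_families)) {
    fam_of[catalog$paralog_families[[i]]] <- i
  }

  uniq <- counts
  groups <- list()
  if (design$multiread_rate > 0 && length(catalog$paralog_families)) {
    in_fam <- !is.na(fam_of) & counts > 0
    m <- integer(length(counts))
    m[in_fam] <- stats::rbinom(sum(in_fam), counts[in_fam],
                               design$multiread_rate)
    uniq <- counts - m
    fam_tot <- tapply(m[in_fam], fam_of[in_fam], sum)
    for (fi in names(fam_tot)) {
      if (fam_tot[[fi]] > 0) {
        groups[[length(groups) + 1L]] <-
          list(genes = catalog$paralog_families[[as.integer(fi)]],
               count = as.numeric(fam_tot[[fi]]))
      }
    }
  }
  read_map_sample(sample_id, uniq[uniq > 0], groups)
}

#' Generate a synthetic case-control cohort of read-mapping tables
#'
#' Species abundances are simulated by [simulate_species_truth()]; reads are
#' then assigned multinomially to genes proportional to species abundance
#' times within-species gene-length weight, and a `multiread_rate` fraction of
#' the reads on paralog-family genes is emitted as multi-read groups over the
#' family. The ground-truth species abundances travel with the result.
#'
#' @param catalog a `gene_catalog`.
#' @param design a `cohort_design`; planted species must exist in the catalog.
#' @return list of class `synthetic_cohort`: `samples` (list of
#'   `read_map_sample`), `labels` (named factor), `truth` (samples x species),
#'   `clinical` (data.frame, see [generate_clinical()]), `catalog`, `design`.
#' @export
generate_cohort <- function(catalog, design) {
  stopifnot(inherits(catalog, "gene_catalog"), inherits(design, "cohort_design"))
  species <- sort(unique(catalog$genes$species))
  sim <- simulate_species_truth(species, design, mu = catalog$species_mean)
  samples <- vector("list", nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    samples[[i]] <- .sample_reads(sim$truth[i, ], catalog, design,
                                  rownames(sim$truth)[i])
  }
  names(samples) <- rownames(sim$truth)
  clinical <- generate_clinical(sim$truth, design, labels = sim$labels)
  structure(list(samples = samples, labels = sim$labels, truth = sim$truth,
                 clinical = clinical, catalog = catalog, design = design),
            class = "synthetic_cohort")
}

#' Default clinical-index generative model
#'
#' Emulates the clinical panel of a gout case-control study: uric acid (SUA)
#' and inflammation (CRP, ESR) driven by planted species, renal indices and
#' age mostly noise. Intercepts and noise standard deviations are on the
#' scale of the corresponding laboratory units. The first planted
#' control-enriched species drives SUA negatively (a urate-degrading
#' commensal proxy) and the first case-enriched species drives CRP and ESR
#' positively.
#'
#' @param planted planted-effect data.frame (`species`, `log2_effect`) or NULL.
#' @return named list: index -> `list(intercept, coef, sd)`.
#' @export
default_clinical_model <- function(planted = NULL) {
  neg_sp <- pos_sp <- NULL
  if (!is.null(planted) && nrow(planted)) {
    dn <- planted$species[planted$log2_effect < 0]
    dp <- planted$species[planted$log2_effect > 0]
    if (length(dn)) neg_sp <- dn[1]
    if (length(dp)) pos_sp <- dp[1]
  }
  cf <- function(sp, v) if (is.null(sp)) numeric(0) else stats::setNames(v, sp)
  list(
    Age  = list(intercept = 40,  coef = numeric(0),    sd = 12),
    BMI  = list(intercept = 24,  coef = cf(pos_sp, 1),  sd = 2.5),
    CRP  = list(intercept = 14,  coef = cf(pos_sp, 6),  sd = 6),
    eGFR = list(intercept = 96,  coef = numeric(0),    sd = 15),
    ESR  = list(intercept = 22,  coef = cf(pos_sp, 8),  sd = 10),
    SCr  = list(intercept = 88,  coef = numeric(0),    sd = 15),
    SUA  = list(intercept = 460, coef = cf(neg_sp, -55), sd = 60),
    Urea = list(intercept = 4.9, coef = numeric(0),    sd = 1.2)
  )
}

#' Generate a clinical table from ground-truth species abundances
#'
#' Each index is `intercept + sum(coef * clog10(abundance)) + N(0, sd)`,
#' where `clog10` is `log10(abundance + 1e-6)` centred per species across the
#' cohort (so intercepts sit at the index's typical value). Values are
#' truncated below at a small positive floor so every index stays finite and
#' positive. Group means differ only through species the model's coefficients
#' touch.
#'
#' @param truth samples x species relative-abundance matrix.
#' @param design a `cohort_design`; `design$clinical_model` (or
#'   [default_clinical_model()]) names the indices.
#' @param labels optional named factor of case/control group per sample.
#' @param timepoint timepoint label stored in the table.
#' @return data.frame: `sample_id`, `group`, `timepoint`, one column per index.
#' @export
generate_clinical <- function(truth, design, labels = NULL,
                              timepoint = "0W") {
  stopifnot(inherits(design, "cohort_design"))
  model <- design$clinical_model %||% default_clinical_model(design$planted)
  for (nm in names(model)) {
    m <- model[[nm]]
    if (length(m$coef)) {
      missing <- setdiff(names(m$coef), colnames(truth))
      if (length(missing)) {
        stop_invalid("clinical model for %s references unknown species: %s",
                     nm, paste(missing, collapse = ", "))
      }
    }
    if (is.null(m$sd) || m$sd <= 0) stop_invalid("noise sd must be > 0 (%s)", nm)
  }
  # separate stream from the read sampler so cohort and clinical draws are
  # individually reproducible
  set.seed(design$seed + 10000L)
  n <- nrow(truth)
  lg <- log10(truth + 1e-6)
  lg <- scale(lg, center = TRUE, scale = FALSE)
  out <- data.frame(sample_id = rownames(truth),
                    group = if (is.null(labels)) NA_character_
                            else as.character(labels[rownames(truth)]),
                    timepoint = timepoint,
                    stringsAsFactors = FALSE)
  for (nm in names(model)) {
    m <- model[[nm]]
    v <- rep(m$intercept, n)
    if (length(m$coef)) {
      v <- v + as.vector(lg[, names(m$coef), drop = FALSE] %*% m$coef)
    }
    v <- v + stats::rnorm(n, 0, m$sd)
    out[[nm]] <- pmax(v, m$intercept / 100)
  }
  out
}

#' Generate longitudinal follow-up samples with partial recovery
#'
#' Emulates treatment follow-up: at each timepoint the case samples' log2
#' species abundances are moved a fraction `f` toward the control-group
#' centroid (mean log2 abundance over control samples) before reads are
#' regenerated. `f = 0` reproduces the baseline ground-truth distribution;
#' `f = 1` erases the planted case-control differences.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param recovery named numeric vector of recovery fractions per timepoint,
#'   values in `[0, 1]`, nondecreasing in the given order.
#' @param seed RNG seed for read regeneration.
#' @return named list per timepoint: `samples` (case `read_map_sample`s),
#'   `truth` (case samples x species), `timepoint`, `recovery`.
#' @export
generate_longitudinal <- function(cohort, recovery = c("2W" = 0.1, "4W" = 0.3,
                                                       "24W" = 0.8),
                                  seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (any(recovery < 0 | recovery > 1)) {
    stop_invalid("recovery fractions must lie in [0, 1]")
  }
  if (is.unsorted(recovery)) {
    stop_invalid("recovery fractions must be nondecreasing over time")
  }
  cases <- names(cohort$labels)[cohort$labels == "case"]
  controls <- names(cohort$labels)[cohort$labels == "control"]
  centroid <- colMeans(log2(cohort$truth[controls, , drop = FALSE]))
  out <- list()
  for (ti in seq_along(recovery)) {
    f <- recovery[[ti]]
    tp <- names(recovery)[ti] %||% sprintf("t%d", ti)
    set.seed(as.integer(seed) + ti)
    lg <- log2(cohort$truth[cases, , drop = FALSE])
    lg <- (1 - f) * lg + f * matrix(centroid, nrow(lg), ncol(lg), byrow = TRUE)
    ab <- 2^lg
    ab <- ab / rowSums(ab)
    samples <- vector("list", nrow(ab))
    for (i in seq_len(nrow(ab))) {
      samples[[i]] <- .sample_reads(ab[i, ], cohort$catalog, cohort$design,
                                    paste0(rownames(ab)[i], "_", tp))
    }
    names(samples) <- rownames(ab)
    out[[tp]] <- list(samples = samples, truth = ab, timepoint = tp,
                      recovery = f)
  }
  out
}
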