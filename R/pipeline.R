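# Configuration-driven end-to-end orchestration and the report bundle.

#' Pipeline configuration
#'
#' Collects the synthetic design, analysis thresholds and stage toggles of a
#' full run. Thresholds default to the study conventions: FDR 0.05, reporter
#' score 1.65, prevalence 0.10, 9999 PERMANOVA permutations.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param n_genes,n_species,n_kos,n_pathways catalog size.
#' @param n_case,n_control,depth,multiread_rate cohort design.
#' @param n_planted planted differential species (see [default_planted()]).
#' @param fdr,reporter_cutoff,prevalence,n_perm analysis thresholds.
#' @param top_n,ntree,n_trials,folds classifier settings.
#' @param stages character vector of stages to run, a subset of
#'   `c("synthetic", "profiling", "diversity", "differential", "reporter",
#'   "tripartite", "classifier")`. Later stages require earlier ones.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_genes = 2000, n_species = 100, n_kos = 150,
                            n_pathways = 15,
                            n_case = 20, n_control = 20, depth = 20000,
                            multiread_rate = 0.1, n_planted = 20,
                            fdr = 0.05, reporter_cutoff = 1.65,
                            prevalence = 0.10, n_perm = 9999,
                            top_n = 100, ntree = 500, n_trials = 5,
                            folds = 10,
                            stages = c("synthetic", "profiling", "diversity",
                                       "differential", "reporter",
                                       "tripartite", "classifier")) {
  stopifnot(fdr > 0, fdr < 1, reporter_cutoff > 0,
            prevalence > 0, prevalence <= 1, n_perm >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid("stage %s failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order — synthetic data,
#' profiling, diversity, differential abundance, reporter-score enrichment,
#' tripartite association, classifier — writing every output as plain-text
#' TSV/GMT/JSON under `config$out_dir` with a provenance header (seed and
#' configuration hash). The same configuration and seed reproduce a
#' byte-identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return list of class `report_bundle`: in-memory stage results, `files`
#'   (relative paths written), `bundle_hash` (MD5 over the file contents),
#'   `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # the hash identifies the scientific configuration: output location and
  # stage toggles are excluded so partial reruns leave earlier outputs intact
  cfg_for_hash <- config[setdiff(names(config), c("out_dir", "stages"))]
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA)
  cfg_tmp <- tempfile()
  writeLines(as.character(cfg_json), cfg_tmp)
  cfg_hash <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  prov <- list(seed = config$seed, config_hash = cfg_hash,
               package = as.character(utils::packageVersion("goutmeta")))
  res <- list()
  files <- character(0)
  emit <- function(writer, obj, rel) {
    writer(obj, file.path(config$out_dir, rel))
    files <<- c(files, rel)
  }
  on <- function(s) s %in% config$stages

  if (on("synthetic")) {
    res$synthetic <- .stage("synthetic", {
      catalog <- generate_catalog(config$n_genes, config$n_species,
                                  n_kos = config$n_kos,
                                  n_pathways = config$n_pathways,
                                  seed = config$seed)
      planted <- default_planted(catalog, n = config$n_planted,
                                 seed = config$seed)
      design <- cohort_design(config$n_case, config$n_control,
                              planted = planted, depth = config$depth,
                              multiread_rate = config$multiread_rate,
                              seed = config$seed)
      cohort <- generate_cohort(catalog, design)
      emit(write_catalog, catalog, "catalog.tsv")
      emit(function(x, p) write_gmt(x, p), catalog$pathways, "pathways.gmt")
      emit(write_readmap, cohort$samples, "readmap.tsv")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           cohort$clinical, "clinical.tsv")
      emit(write_manifest,
           list(seed = config$seed, config_hash = cfg_hash,
                design = list(n_case = design$n_case,
                              n_control = design$n_control,
                              depth = design$depth,
                              multiread_rate = design$multiread_rate),
                planted = planted),
           "manifest.json")
      list(catalog = catalog, cohort = cohort, planted = planted)
    })
  }

  if (on("profiling")) {
    res$profiling <- .stage("profiling", {
      syn <- res$synthetic
      if (is.null(syn)) stop("requires the synthetic stage")
      gene_prof <- build_gene_profile(syn$cohort$samples, syn$catalog)
      gene_prof <- prevalence_filter(gene_prof, config$prevalence)
      species_prof <- aggregate_profile(gene_prof,
                                        taxon_map(syn$catalog, "species"),
                                        "species")
      genus_prof <- aggregate_profile(gene_prof,
                                      taxon_map(syn$catalog, "genus"),
                                      "genus")
      phylum_prof <- aggregate_profile(gene_prof,
                                       taxon_map(syn$catalog, "phylum"),
                                       "phylum")
      ko_prof <- aggregate_profile(gene_prof, ko_map(syn$catalog), "ko")
      emit(function(x, p) write_profile(x, p, prov), gene_prof, "profile_gene.tsv")
      emit(function(x, p) write_profile(x, p, prov), species_prof, "profile_species.tsv")
      emit(function(x, p) write_profile(x, p, prov), genus_prof, "profile_genus.tsv")
      emit(function(x, p) write_profile(x, p, prov), phylum_prof, "profile_phylum.tsv")
      emit(function(x, p) write_profile(x, p, prov), ko_prof, "profile_ko.tsv")
      list(gene = gene_prof, species = species_prof, genus = genus_prof,
           phylum = phylum_prof, ko = ko_prof)
    })
  }

  if (on("diversity")) {
    res$diversity <- .stage("diversity", {
      pf <- res$profiling
      if (is.null(pf)) stop("requires the profiling stage")
      labels <- res$synthetic$cohort$labels
      gmat <- pf$gene$matrix
      alpha <- data.frame(sample_id = rownames(gmat),
                          gene_count = gene_count(gmat),
                          shannon = shannon_index(gmat))
      dm <- bray_curtis(gmat)
      perma <- permanova(dm, labels[rownames(gmat)], n_perm = config$n_perm,
                         seed = config$seed)
      gdc <- group_distance_comparison(dm, labels[rownames(gmat)])
      et <- enterotype(pf$genus, groups = labels, seed = config$seed)
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           alpha, "alpha_diversity.tsv")
      emit(function(x, p) utils::write.table(round(x, 10), p, sep = "\t",
                                             quote = FALSE),
           dm, "bray_curtis.tsv")
      emit(write_manifest,
           list(permanova = perma,
                distance_comparison = gdc[c("p", "mean_within",
                                            "mean_between", "median_within",
                                            "median_between")],
                enterotype = list(k = et$k, ch = as.list(et$ch),
                                  distance = et$distance,
                                  group_test = et$group_test)),
           "diversity_summary.json")
      list(alpha = alpha, dm = dm, permanova = perma,
           distance_comparison = gdc, enterotype = et)
    })
  }

  if (on("differential")) {
    res$differential <- .stage("differential", {
      pf <- res$profiling
      if (is.null(pf)) stop("requires the profiling stage")
      labels <- res$synthetic$cohort$labels
      out <- list()
      for (lev in c("gene", "species", "genus", "ko")) {
        d <- differential_abundance(pf[[lev]], labels[rownames(pf[[lev]]$matrix)],
                                    fdr_cutoff = config$fdr)
        emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                               row.names = FALSE),
             d, sprintf("differential_%s.tsv", lev))
        out[[lev]] <- d
      }
      out
    })
  }

  if (on("reporter")) {
    res$reporter <- .stage("reporter", {
      dl <- res$differential
      if (is.null(dl)) stop("requires the differential stage")
      dko <- dl$ko
      z <- ko_zscore(stats::setNames(dko$p, dko$feature), dko$direction)
      pws <- res$synthetic$catalog$pathways
      pws <- pws[vapply(pws, function(m) {
        k <- sum(m %in% names(z))
        k >= 1 && k < length(z)
      }, logical(1))]
      rep_res <- reporter_score(z, pws, seed = config$seed,
                                cutoff = config$reporter_cutoff)
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           rep_res, "reporter_scores.tsv")
      rep_res
    })
  }

  if (on("tripartite")) {
    res$tripartite <- .stage("tripartite", {
      pf <- res$profiling
      dl <- res$differential
      if (is.null(pf) || is.null(dl)) stop("requires profiling and differential stages")
      dsp <- dl$species
      top_sp <- dsp$feature[order(dsp$q, dsp$p)][seq_len(min(10, nrow(dsp)))]
      smat <- pf$species$matrix[, top_sp, drop = FALSE]
      clin <- res$synthetic$cohort$clinical
      clin <- clin[match(rownames(smat), clin$sample_id), , drop = FALSE]
      pws <- res$synthetic$catalog$pathways
      pws <- pws[vapply(pws, function(m)
        sum(m %in% colnames(pf$ko$matrix)) >= 2, logical(1))]
      tri <- tripartite_association(smat, pf$ko$matrix, pws,
                                    clin[, c("BMI", "CRP", "SUA")],
                                    adjust_for = "BMI")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           tri$species_pathway, "tripartite_species_pathway.tsv")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           tri$species_clinical, "tripartite_species_clinical.tsv")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           tri$pathway_clinical, "tripartite_pathway_clinical.tsv")
      tri
    })
  }

  if (on("classifier")) {
    res$classifier <- .stage("classifier", {
      pf <- res$profiling
      dl <- res$differential
      if (is.null(pf) || is.null(dl)) stop("requires profiling and differential stages")
      labels <- res$synthetic$cohort$labels
      cand <- candidate_genes(dl$gene, top_n = config$top_n)
      x <- pf$gene$matrix[, cand, drop = FALSE]
      y <- labels[rownames(x)]
      curve <- cv_error_curve(x, y, n_trials = config$n_trials,
                              folds = config$folds, seed = config$seed,
                              ntree = config$ntree)
      sel <- select_features(curve)
      model <- train_and_score(x, y, sel$genes, seed = config$seed,
                               ntree = config$ntree)
      eval_train <- roc_auc(model$scores, y)
      emit(write_manifest,
           list(candidates = cand, selected = sel$genes, m = sel$m,
                cutoff = sel$cutoff, seed = config$seed,
                ntree = config$ntree,
                curve = list(m = curve$m, mean_error = curve$mean_error,
                             sd_error = curve$sd_error),
                auc_train = eval_train$auc),
           "classifier_model.json")
      emit(function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE),
           data.frame(sample_id = names(model$scores), score = model$scores),
           "classifier_scores.tsv")
      list(candidates = cand, curve = curve, selection = sel, model = model,
           auc_train = eval_train$auc)
    })
  }

  hash <- bundle_hash(config$out_dir, files)
  structure(c(res, list(files = files, bundle_hash = hash, config = config)),
            class = "report_bundle")
}

#' Hash a report bundle
#'
#' MD5 over the per-file MD5 sums of the bundle files, taken in sorted
#' relative-path order; two runs with the same configuration and seed
#' produce the same hash.
#'
#' @param dir bundle directory.
#' @param files relative paths (default: all files under `dir`).
#' @return character MD5 hash.
#' @export
bundle_hash <- function(dir, files = NULL) {
  files <- sort(files %||% list.files(dir, recursive = TRUE))
  sums <- tools::md5sum(file.path(dir, files))
  tmp <- tempfile()
  writeLines(paste(files, unname(sums)), tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
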