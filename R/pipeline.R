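#' Run configuration
#'
#' Collects the knobs of the two analysis pipelines: iMAT settings, the
#' activity threshold (0.001), FDR rate (0.1), permutation/randomization
#' counts (1000), split count (100) and the RNG seed. All thresholds carry
#' their conventional defaults.
#'
#' @param settings [imat_settings()].
#' @param activity_threshold flux threshold for calling a reaction active.
#' @param fdr_rate FDR level for the covariate correlations.
#' @param n_perm label permutations (correlations, classification).
#' @param n_random random measurement sets (consistency p-value).
#' @param n_splits train/test splits for classification.
#' @param seed RNG seed recorded in every manifest.
#' @return List of class `run_config`.
#' @export
run_config <- function(settings = imat_settings(),
                       activity_threshold = 0.001, fdr_rate = 0.1,
                       n_perm = 1000, n_random = 1000, n_splits = 100,
                       seed = 1) {
  stopifnot(activity_threshold > 0, fdr_rate > 0, n_perm >= 0,
            n_random >= 1, n_splits >= 1)
  structure(list(settings = settings,
                 activity_threshold = activity_threshold,
                 fdr_rate = fdr_rate, n_perm = n_perm,
                 n_random = n_random, n_splits = n_splits, seed = seed),
            class = "run_config")
}

write_tsv_report <- function(df, path, command) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# generated by: ", command), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_manifest <- function(path, config, extra = list()) {
  manifest <- c(list(
    package = "hepaflux",
    version = as.character(utils::packageVersion("hepaflux")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    activity_threshold = config$activity_threshold,
    fdr_rate = config$fdr_rate,
    n_perm = config$n_perm, n_random = config$n_random,
    n_splits = config$n_splits,
    imat = unclass(config$settings),
    tolerances = tolerances()), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the expression-based functionality pipeline
#'
#' Scores every (sample, function) pair, compares the two liver-fat groups
#' per function, classifies the samples from their functionality profiles,
#' and writes a report bundle: `functionality.tsv` (wide score table),
#' `group_comparisons.tsv`, `classification.json` and `manifest.json`.
#'
#' @param model a `metabolic_model`.
#' @param catalogue a `function_catalogue`.
#' @param cohort named list of expression profiles.
#' @param groups named group labels (two levels), or `NULL` to skip the
#'   comparison and classification stages.
#' @param out_dir output directory (created if missing).
#' @param config a [run_config()].
#' @return Invisible list with `profiles`, `comparisons`, `classification`
#'   and the output paths.
#' @export
run_expression_pipeline <- function(model, catalogue, cohort, groups = NULL,
                                    out_dir, config = run_config()) {
  if (length(cohort) == 0) stop("empty cohort")
  validate_catalogue(catalogue, model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmd <- "hepaflux::run_expression_pipeline"

  profiles <- profile_functionality(model, catalogue, cohort,
                                    config$settings)
  f_path <- file.path(out_dir, "functionality.tsv")
  wide <- functionality_wide(profiles)
  write_tsv_report(cbind(sample_id = rownames(wide), as.data.frame(wide)),
                   f_path, cmd)

  comparisons <- NULL
  classification <- NULL
  if (!is.null(groups)) {
    comparisons <- compare_functionality_groups(profiles, groups)
    write_tsv_report(comparisons,
                     file.path(out_dir, "group_comparisons.tsv"), cmd)
    classification <- svm_classify(
      wide, groups[rownames(wide)], n_splits = config$n_splits,
      n_perm = config$n_perm, seed = config$seed)
    jsonlite::write_json(
      list(mean_auc = classification$mean_auc,
           split_aucs = classification$split_aucs,
           p_empirical = classification$p_empirical,
           n_splits = classification$n_splits,
           n_perm = classification$n_perm, seed = classification$seed),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA)
  }
  write_manifest(file.path(out_dir, "manifest.json"), config,
                 extra = list(stage = "expression",
                              n_samples = length(cohort),
                              n_functions = length(catalogue)))
  invisible(list(profiles = profiles, comparisons = comparisons,
                 classification = classification, out_dir = out_dir))
}

#' Run the flux-based pipeline
#'
#' For each condition: QP fit of the measurements (consistency score),
#' constrained FVA, activity classification, pathway enrichment, the
#' consistency p-value against random measurement sets, and LOOCV. Writes
#' `ranges_<condition>.tsv`, `activity_<condition>.tsv`,
#' `enrichment_<condition>.tsv`, `summary.json` and `manifest.json`.
#'
#' @param model a `metabolic_model`.
#' @param measurements a [flux_measurements()] data.frame or a named list
#'   of them (one per condition).
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return Invisible list keyed by condition with the per-stage results.
#' @export
run_flux_pipeline <- function(model, measurements, out_dir,
                              config = run_config()) {
  if (inherits(measurements, "flux_measurements")) {
    measurements <- stats::setNames(list(measurements),
                                    measurements$condition[1])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cmd <- "hepaflux::run_flux_pipeline"
  out <- list()
  summary <- list()
  for (cond in names(measurements)) {
    mm <- measurements[[cond]]
    fit <- fit_fluxes_qp(model, mm)
    ranges <- constrained_fva(model, fit)
    cls <- classify_activity(ranges, config$activity_threshold)
    enr <- pathway_enrichment(cls, model)
    cons <- consistency_pvalue(model, mm, n_random = config$n_random,
                               seed = config$seed)
    loocv <- if (nrow(mm) >= 3) loocv_fluxes(model, mm) else NULL
    write_tsv_report(ranges,
                     file.path(out_dir, paste0("ranges_", cond, ".tsv")),
                     cmd)
    write_tsv_report(cls,
                     file.path(out_dir, paste0("activity_", cond, ".tsv")),
                     cmd)
    write_tsv_report(enr,
                     file.path(out_dir, paste0("enrichment_", cond, ".tsv")),
                     cmd)
    summary[[cond]] <- list(
      consistency_score = fit$consistency_score,
      consistency_pvalue = cons$p_value,
      n_active = sum(cls$active),
      n_reactions = nrow(cls),
      loocv_rho = if (is.null(loocv)) NULL else loocv$rho,
      loocv_pvalue = if (is.null(loocv)) NULL else loocv$p_value)
    out[[cond]] <- list(fit = fit, ranges = ranges, classification = cls,
                        enrichment = enr, consistency = cons, loocv = loocv)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(file.path(out_dir, "manifest.json"), config,
                 extra = list(stage = "flux",
                              conditions = names(measurements)))
  invisible(out)
}
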