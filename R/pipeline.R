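#' Run the full context-dependency pipeline
#'
#' End-to-end orchestration of the framework on one arm of an experiment:
#' read (or accept) a concentration table, floor at the detection limit,
#' impute missing analytes, compute paired stimulus differences, exclude
#' context-restricted analytes, score context-dependency per analyte with
#' likelihood-ratio significance, run post-hoc pairwise context tests for
#' significant analytes, compute PCA stimulus-shift distances, and — when
#' two context variables are supplied — rank them with the group-lasso
#' path. Results are written as CSVs plus a JSON manifest recording the
#' seed, configuration, and a checksum per output file.
#'
#' @param input A [concentration_table()] or a path readable by
#'   [read_concentration_table()].
#' @param output_dir Directory for results (created if absent).
#' @param lod Detection limit in pg/mL (default 10).
#' @param seed Seed for the stochastic imputation (default 1).
#' @param orientation Passed to [paired_differences()].
#' @param exclude Optional explicit analyte exclusion list (overrides the
#'   detection rule).
#' @param detection_threshold Detection-rule threshold when no explicit
#'   list is given (default 0.5).
#' @param transform PCA transform (default `"zscore"`).
#' @param alpha_levels Significance thresholds (default 0.05/0.01/0.001).
#' @param group_variables Optional character vector of two or more effect
#'   table columns (e.g. `c("dc_type", "stimulus")`) for the group-lasso
#'   importance step; requires those columns derivable from `context` via
#'   `context_split` or already present.
#' @param context_split Optional function mapping the context label vector
#'   to a data frame of context variables (e.g. splitting "cDC2.LPS" into
#'   dc_type and stimulus).
#' @param dialect Optional input dialect for file input.
#' @return Invisibly, a list with the in-memory results (`design`,
#'   `effects`, `kept`, `excluded`, `scores`, `posthoc`, `shifts`,
#'   `importance`, `manifest`).
#' @export
run_pipeline <- function(input, output_dir, lod = 10, seed = 1,
                         orientation = "standard", exclude = NULL,
                         detection_threshold = 0.5, transform = "zscore",
                         alpha_levels = c(0.05, 0.01, 0.001),
                         group_variables = NULL, context_split = NULL,
                         dialect = NULL) {
  table <- if (is.character(input)) {
    read_concentration_table(input, dialect)
  } else {
    concentration_table(input)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  design <- stage("design", summarize_design(table))
  message("design: ", design$n_condition_observations,
          " condition observations, ", design$n_missing, " missing cells")

  table <- stage("lod", apply_lod_floor(table, lod))
  if (any(is.na(table$concentration))) {
    table <- stage("impute", impute_chained_equations(table, seed = seed))
    message("impute: completed table with seed ", seed)
  }

  effects <- stage("differences", paired_differences(table, orientation))
  filt <- stage("filter", filter_context_restricted_analytes(
    table, threshold = detection_threshold, lod = lod, override = exclude))
  kept_effects <- effects[effects$analyte %in% filt$kept, ]
  message("filter: ", length(filt$kept), " analytes kept, ",
          length(filt$excluded), " excluded")

  scores <- stage("score", score_all_analytes(kept_effects, alpha_levels))
  signif_analytes <- scores$analyte[scores$significance != "ns"]
  posthoc <- if (length(signif_analytes) > 0) {
    dplyr::bind_rows(lapply(signif_analytes, function(a) {
      ph <- posthoc_pairwise_tests(kept_effects, a)
      ph$analyte <- a
      ph
    }))
  } else tibble::tibble()

  profile <- stage("pca", build_profile_matrix(table, transform))
  pca <- pca_with_barycenters(profile)
  shifts <- stimulus_shift_distance(pca)

  importance <- NULL
  if (!is.null(group_variables)) {
    eff2 <- kept_effects
    if (!is.null(context_split)) {
      eff2 <- dplyr::bind_cols(eff2, context_split(eff2$context))
    }
    importance <- stage("importance", dplyr::bind_rows(
      lapply(split(eff2, eff2$analyte), function(sub) {
        r <- residualize(sub$rel_diff, sub$donor)
        des <- build_group_design(sub, group_variables)
        path <- group_lasso_path(des, r)
        verdict <- dominant_variable(path)
        tibble::tibble(analyte = sub$analyte[1],
                       dominant = verdict$dominant,
                       relative_gap = verdict$relative_gap,
                       vanish = list(verdict$vanish_lambda))
      })))
  }

  flat_scores <- scores[c("analyte", "score", "classification", "lrt_stat",
                          "df", "p_value", "significance")]
  outputs <- list(design = as.data.frame(design),
                  effects = effects, scores = flat_scores,
                  shifts = shifts)
  if (nrow(posthoc) > 0) outputs$posthoc <- posthoc
  if (!is.null(importance)) {
    outputs$importance <- importance[c("analyte", "dominant",
                                       "relative_gap")]
  }
  files <- character(0)
  for (nm in names(outputs)) {
    f <- file.path(output_dir, paste0(nm, ".csv"))
    write_results_table(outputs[[nm]], f)
    files[nm] <- f
  }
  manifest <- list(
    seed = seed, lod = lod, orientation = orientation,
    transform = transform, alpha_levels = alpha_levels,
    excluded_analytes = filt$excluded,
    package_version = as.character(utils::packageVersion("ctxdep")),
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(design = design, effects = effects, kept = filt$kept,
                 excluded = filt$excluded, scores = scores,
                 posthoc = posthoc, shifts = shifts,
                 importance = importance, manifest = manifest))
}
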