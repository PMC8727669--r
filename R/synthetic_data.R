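#' Configure a synthetic concentration experiment
#'
#' The generator assumes a lognormal measurement model: on the log10 scale
#' each concentration is a per-(analyte, context) baseline plus a donor
#' random intercept, plus a per-(analyte, context) stimulus effect when the
#' stimulus is present, plus residual noise. Exponentiation gives positive,
#' heavy-tailed pg/mL values, and an additive log-scale stimulus effect
#' \eqn{e} corresponds to a multiplicative fold change \eqn{10^{e}}, i.e. a
#' relative difference of \eqn{10^{e} - 1} — exactly the response the
#' scoring model works on.
#'
#' @param n_donors Number of donors.
#' @param contexts Character vector of context labels.
#' @param analytes Character vector of analyte labels.
#' @param baseline_log_mean Baseline log10 concentration: a single number,
#'   or an analytes x contexts matrix (dimnames required).
#' @param donor_sd Donor random-intercept SD on the log10 scale.
#' @param noise_sd Residual SD on the log10 scale (> 0).
#' @param stimulus_effect Log10 fold-change of the stimulus: a single
#'   number, or an analytes x contexts matrix.
#' @param lod Limit of detection (pg/mL) the generated assay would have;
#'   sub-LOD values are stored raw so that downstream LOD handling is
#'   exercised, not pre-applied.
#' @param missing_analytes Analytes affected by block missingness.
#' @param missing_fraction Fraction of samples (donor x context x state)
#'   whose `missing_analytes` measurements are dropped.
#' @param arm Arm label for the generated records.
#' @return A `ctx_sim_config` list.
#' @export
simulation_config <- function(n_donors, contexts, analytes,
                              baseline_log_mean = 2, donor_sd = 0.15,
                              noise_sd = 0.1, stimulus_effect = 0,
                              lod = 10, missing_analytes = character(0),
                              missing_fraction = 0, arm = "arm1") {
  if (n_donors < 1) stop("n_donors must be >= 1", call. = FALSE)
  if (donor_sd < 0 || noise_sd < 0) {
    stop("donor_sd and noise_sd must be >= 0", call. = FALSE)
  }
  if (missing_fraction < 0 || missing_fraction > 1) {
    stop("missing_fraction must be in [0, 1]", call. = FALSE)
  }
  expand <- function(x, what) {
    if (is.matrix(x)) {
      if (!setequal(rownames(x), analytes) ||
          !setequal(colnames(x), contexts)) {
        stop(what, " matrix must have analytes as rows and contexts as ",
             "columns", call. = FALSE)
      }
      x[analytes, contexts, drop = FALSE]
    } else {
      matrix(x, length(analytes), length(contexts),
             dimnames = list(analytes, contexts))
    }
  }
  structure(list(
    n_donors = as.integer(n_donors), contexts = contexts,
    analytes = analytes,
    baseline_log_mean = expand(baseline_log_mean, "baseline_log_mean"),
    donor_sd = donor_sd, noise_sd = noise_sd,
    stimulus_effect = expand(stimulus_effect, "stimulus_effect"),
    lod = lod, missing_analytes = missing_analytes,
    missing_fraction = missing_fraction, arm = arm),
    class = "ctx_sim_config")
}

#' Simulate a concentration table
#'
#' Draws a fully crossed donors x contexts x states x analytes table from
#' the lognormal generative model of [simulation_config()], applies block
#' missingness (a random fraction of samples loses the configured analyte
#' subset, emulating a late secondary assay that could not be run for some
#' supernatants), and returns both the table and the generating ground
#' truth. Sub-LOD values are kept raw.
#'
#' @param config A `ctx_sim_config`.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `table` (a [concentration_table()]) and `truth`
#'   (the config plus the drawn donor effects and the per-(analyte,
#'   context) true relative differences `10^effect - 1`).
#' @export
simulate_table <- function(config, seed = 1) {
  stopifnot(inherits(config, "ctx_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  donors <- sprintf("D%02d", seq_len(config$n_donors))
  donor_effect <- setNames(rnorm(config$n_donors, 0, config$donor_sd),
                           donors)
  grid <- tidyr::expand_grid(donor = donors, context = config$contexts,
                             stimulus_state = CTX_STATES,
                             analyte = config$analytes)
  base <- config$baseline_log_mean[cbind(grid$analyte, grid$context)]
  eff <- config$stimulus_effect[cbind(grid$analyte, grid$context)] *
    (grid$stimulus_state == "present")
  logc <- base + donor_effect[grid$donor] + eff +
    rnorm(nrow(grid), 0, config$noise_sd)
  grid$arm <- config$arm
  grid$concentration <- 10^logc

  if (config$missing_fraction > 0 && length(config$missing_analytes) > 0) {
    samples <- unique(grid[c("donor", "context", "stimulus_state")])
    n_miss <- round(config$missing_fraction * nrow(samples))
    if (n_miss > 0) {
      hit <- samples[sample.int(nrow(samples), n_miss), ]
      key <- paste(grid$donor, grid$context, grid$stimulus_state)
      drop <- key %in% paste(hit$donor, hit$context, hit$stimulus_state) &
        grid$analyte %in% config$missing_analytes
      grid$concentration[drop] <- NA_real_
    }
  }
  truth <- list(config = config, donor_effect = donor_effect,
                true_rel_diff = 10^config$stimulus_effect - 1)
  list(table = concentration_table(grid), truth = truth)
}

#' Study-design presets mirroring the framework's motivating experiments
#'
#' Three arms of a cytokine-profiling study of a costimulatory ligand:
#' \describe{
#'   \item{Th}{13 donors, 4 T-helper-polarizing contexts (Th0, Th1, Th2,
#'     Th17), 17 output cytokines, soluble-ligand stimulation. Six
#'     analytes are context-restricted (secreted essentially only in Th2
#'     or Th17), exercising the exclusion filter.}
#'   \item{cDC2}{9 donors, 6 dendritic-cell activation contexts (Zymosan,
#'     PAM3, LPS, HKSA, Curdlan, TSLP), 17 cytokines; 12 of the 108
#'     samples lose a 4-analyte late-assay block.}
#'   \item{MoDC}{9 donors, the 5 non-TSLP contexts, 17 cytokines; 10 of
#'     the 90 samples lose the same block.}
#' }
#' Defaults encode moderately context-dependent stimulus effects (a mix of
#' one-direction and sign-switching analytes) with donor SD 0.15 and noise
#' SD 0.1 on the log10 scale.
#'
#' @param arm One of `"Th"`, `"cDC2"`, `"MoDC"`.
#' @return A `ctx_sim_config`.
#' @export
make_paper_like_design <- function(arm = c("Th", "cDC2", "MoDC")) {
  arm <- match.arg(arm)
  analytes <- c("IL-2", "IL-3", "IL-4", "IL-5", "IL-6", "IL-9", "IL-10",
                "IL-13", "IL-17A", "IL-17F", "IL-21", "IL-22", "IL-31",
                "TNF-a", "TNF-b", "IFN-g", "GM-CSF")
  late_assay <- c("IL-21", "IL-22", "IL-31", "TNF-b")  # second-platform block
  cfg <- switch(arm,
    Th = {
      contexts <- c("Th0", "Th1", "Th2", "Th17")
      base <- matrix(2.2, length(analytes), length(contexts),
                     dimnames = list(analytes, contexts))
      # context-restricted analytes: high in their home context, sub-LOD
      # elsewhere (LOD 10 pg/mL = 1 on the log10 scale)
      for (a in c("IL-4", "IL-5", "IL-9", "IL-31")) base[a, ] <- 0.3
      base[c("IL-4", "IL-5", "IL-9", "IL-31"), "Th2"] <- 2.5
      for (a in c("IL-17A", "IL-17F")) base[a, ] <- 0.3
      base[c("IL-17A", "IL-17F"), "Th17"] <- 2.5
      eff <- matrix(0, length(analytes), length(contexts),
                    dimnames = list(analytes, contexts))
      eff["IL-10", ] <- c(-0.15, -0.1, -0.3, -0.12)  # one-way, graded
      eff["IL-13", ] <- c(-0.2, 0, 0, -0.2)
      eff["IL-22", ] <- c(0.1, -0.25, 0.05, 0)       # sign-switching
      eff["TNF-a", ] <- c(0.12, -0.12, 0.08, -0.05)
      eff["IL-3", ] <- c(-0.1, -0.05, -0.2, -0.08)
      simulation_config(13, contexts, analytes, base,
                        stimulus_effect = eff, arm = "Th")
    },
    cDC2 = {
      contexts <- c("Zymosan", "PAM3", "LPS", "HKSA", "Curdlan", "TSLP")
      eff <- matrix(0, length(analytes), length(contexts),
                    dimnames = list(analytes, contexts))
      eff["IL-3", ] <- -0.12
      eff["GM-CSF", ] <- c(0.08, 0.05, 0.1, 0.06, 0.04, -0.2)
      eff["IL-2", ] <- c(0.06, 0.08, 0.05, 0.07, 0.06, -0.25)
      eff["IFN-g", ] <- c(0.05, 0.04, 0.08, 0.03, 0.05, -0.22)
      simulation_config(9, contexts, analytes, 2.2,
                        stimulus_effect = eff,
                        missing_analytes = late_assay,
                        missing_fraction = 12 / 108, arm = "cDC2")
    },
    MoDC = {
      contexts <- c("Zymosan", "PAM3", "LPS", "HKSA", "Curdlan")
      eff <- matrix(0, length(analytes), length(contexts),
                    dimnames = list(analytes, contexts))
      eff["IL-31", ] <- c(0.15, 0.1, 0.25, 0.12, 0.1)
      eff["GM-CSF", ] <- c(0.1, 0.08, 0.2, 0.1, 0.09)
      eff["IL-4", ] <- c(0.15, -0.1, 0.2, -0.08, 0.05)
      eff["IL-5", ] <- c(0.12, -0.12, 0.18, -0.05, 0.04)
      simulation_config(9, contexts, analytes, 2.2,
                        stimulus_effect = eff,
                        missing_analytes = late_assay,
                        missing_fraction = 10 / 90, arm = "MoDC")
    })
  cfg
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a configured experiment, runs the scoring pipeline
#' (LOD floor, imputation if needed, paired differences, per-analyte mixed
#' model + likelihood-ratio test), and summarises how well the generating
#' parameters are recovered: bias and RMSE of the per-context effect
#' estimates against the designed relative differences, and the empirical
#' LRT rejection rate at `alpha`.
#'
#' @param config A `ctx_sim_config`.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param alpha Rejection threshold for the LRT rate (default 0.05).
#' @param analytes Analytes to track (default: all in the config).
#' @return A list with `per_analyte` (tibble of bias, rmse, rejection
#'   rate) and `n_reps`.
#' @export
recovery_experiment <- function(config, n_reps, seed = 1, alpha = 0.05,
                                analytes = NULL) {
  analytes <- analytes %||% config$analytes
  true_rd <- 10^config$stimulus_effect - 1
  acc <- list()
  for (r in seq_len(n_reps)) {
    sim <- simulate_table(config, seed = seed + r)
    tab <- apply_lod_floor(sim$table, config$lod)
    if (any(is.na(tab$concentration))) {
      tab <- impute_chained_equations(tab, seed = seed + r)
    }
    eff <- paired_differences(tab)
    eff <- eff[eff$analyte %in% analytes, ]
    scores <- score_all_analytes(eff)
    scores$rep <- r
    acc[[r]] <- scores
  }
  all_scores <- dplyr::bind_rows(acc)
  per_analyte <- dplyr::bind_rows(lapply(
    split(all_scores, all_scores$analyte), function(sub) {
      err <- do.call(rbind, lapply(sub$beta, function(b)
        b[config$contexts] - true_rd[sub$analyte[1], config$contexts]))
      tibble::tibble(analyte = sub$analyte[1],
                     bias = mean(err), rmse = sqrt(mean(err^2)),
                     rejection_rate = mean(sub$p_value <= alpha))
    }))
  list(per_analyte = per_analyte, n_reps = n_reps,
       scores = all_scores)
}
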