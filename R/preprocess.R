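#' Floor concentrations at the detection limit
#'
#' Multiplex cytokine assays cannot quantify below their limit of detection
#' (LOD). Every value strictly below `lod` is replaced by `lod / 2`
#' (10 pg/mL -> 5 pg/mL with the default), the standard substitution for
#' left-censored concentrations. Values at or above the LOD and missing
#' values pass through unchanged. The operation is idempotent.
#'
#' @param table A [concentration_table()].
#' @param lod Limit of detection in pg/mL (default 10).
#' @return The table with floored concentrations.
#' @export
apply_lod_floor <- function(table, lod = 10) {
  if (!is.numeric(lod) || length(lod) != 1 || lod <= 0) {
    stop("lod must be a single positive number", call. = FALSE)
  }
  below <- !is.na(table$concentration) & table$concentration < lod
  table$concentration[below] <- lod / 2
  table
}

#' Impute missing concentrations by chained equations
#'
#' Stochastic single imputation (one completed dataset) in the spirit of
#' multiple imputation by chained equations: within each
#' (arm, context, stimulus_state) stratum, each analyte with missing values
#' is repeatedly regressed on the current completed values of the other
#' analytes on the log10 scale, and its missing cells are replaced by the
#' regression prediction plus a stochastic normal draw at the residual
#' standard deviation. Because strata typically hold fewer samples (donors)
#' than there are predictor analytes, the normal equations carry a small
#' ridge term; this stabilises the regressions without biasing well-posed
#' cases appreciably.
#'
#' Observed cells are never altered, imputed values are strictly positive
#' (log-scale model), and a fixed seed makes the output reproducible.
#'
#' @param table A LOD-floored [concentration_table()].
#' @param n_iterations Number of passes over the incomplete analytes
#'   (default 10).
#' @param seed Integer seed for the stochastic draws.
#' @param ridge Ridge coefficient on the standardized scale (default 1e-3).
#' @return The completed table.
#' @export
impute_chained_equations <- function(table, n_iterations = 10, seed = 1,
                                     ridge = 1e-3) {
  if (!any(is.na(table$concentration))) return(table)

  # sample = one physical supernatant: donor x arm x context x state
  table$.sample <- paste(table$donor, table$arm, table$context,
                         table$stimulus_state, sep = "\r")
  by_sample <- split(is.na(table$concentration), table$.sample)
  all_missing <- names(by_sample)[vapply(by_sample, all, logical(1))]
  if (length(all_missing) > 0) {
    stop("sample(s) with all analytes missing cannot be imputed: ",
         paste(gsub("\r", "/", head(all_missing, 5)), collapse = "; "),
         call. = FALSE)
  }
  by_analyte <- split(is.na(table$concentration), table$analyte)
  dead <- names(by_analyte)[vapply(by_analyte, all, logical(1))]
  if (length(dead) > 0) {
    stop("analyte(s) missing in every sample cannot be imputed: ",
         paste(dead, collapse = ", "), call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  table$.row <- seq_len(nrow(table))
  strata <- split(table, paste(table$arm, table$context,
                               table$stimulus_state, sep = "\r"))
  for (stratum in strata) {
    wide <- tidyr::pivot_wider(stratum[c(".sample", "analyte",
                                         "concentration")],
                               names_from = "analyte",
                               values_from = "concentration")
    mat <- log10(as.matrix(wide[-1]))
    filled <- impute_stratum(mat, n_iterations, ridge)
    long <- tidyr::pivot_longer(
      cbind(wide[1], as.data.frame(10^filled)),
      cols = -1, names_to = "analyte", values_to = ".imp")
    idx <- match(paste(stratum$.sample, stratum$analyte),
                 paste(long$.sample, long$analyte))
    miss <- is.na(stratum$concentration)
    table$concentration[stratum$.row[miss]] <- long$.imp[idx][miss]
  }
  table$.sample <- NULL
  table$.row <- NULL
  table
}

# chained-equations sweep over one samples x analytes log-scale matrix
impute_stratum <- function(mat, n_iterations, ridge) {
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  col_means <- colMeans(mat, na.rm = TRUE)
  col_means[is.nan(col_means)] <- mean(mat, na.rm = TRUE)
  for (j in seq_len(ncol(mat))) mat[miss[, j], j] <- col_means[j]

  incomplete <- which(colSums(miss) > 0)
  for (iter in seq_len(n_iterations)) {
    for (j in incomplete) {
      obs <- !miss[, j]
      if (sum(obs) < 2) next  # fall back to mean + noise below
      x <- mat[, -j, drop = FALSE]
      ctr <- colMeans(x)
      scl <- apply(x, 2, sd)
      scl[scl == 0 | is.na(scl)] <- 1
      xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
      y <- mat[obs, j]
      xo <- xs[obs, , drop = FALSE]
      A <- crossprod(xo) / nrow(xo) + diag(ridge, ncol(xo))
      b <- crossprod(xo, y - mean(y)) / nrow(xo)
      beta <- solve(A, b)
      pred <- mean(y) + xs %*% beta
      res_sd <- sqrt(max(mean((y - pred[obs])^2), 1e-12))
      mat[miss[, j], j] <- pred[miss[, j]] +
        rnorm(sum(miss[, j]), 0, res_sd)
    }
    for (j in incomplete) {        # analyte observed once: mean + noise
      obs <- !miss[, j]
      if (sum(obs) >= 2) next
      spread <- sd(mat[!miss], na.rm = TRUE)
      mat[miss[, j], j] <- mean(mat[obs, j]) +
        rnorm(sum(miss[, j]), 0, max(spread, 1e-6))
    }
  }
  mat
}

#' Paired stimulus-present minus stimulus-absent differences
#'
#' For each (donor, arm, context, analyte) with both stimulus states
#' measured, computes the absolute difference (present minus absent, pg/mL)
#' and the relative difference ((present - absent) / absent). The relative
#' difference is the response modelled downstream; after LOD flooring the
#' denominator is at least LOD/2 so it is always defined.
#'
#' In antibody-blockade designs the biologically "stimulus present" arm is
#' the isotype control and "absent" is the blocking antibody;
#' `orientation = "flipped"` swaps the roles of the two recorded states
#' accordingly.
#'
#' @param table A completed, LOD-floored [concentration_table()].
#' @param orientation `"standard"` (present = `stimulus_state == "present"`)
#'   or `"flipped"`.
#' @return An effect table: one row per (donor, arm, context, analyte) with
#'   `conc_present`, `conc_absent`, `abs_diff`, `rel_diff`.
#' @export
paired_differences <- function(table, orientation = c("standard", "flipped")) {
  orientation <- match.arg(orientation)
  wide <- tidyr::pivot_wider(
    table[c("donor", "arm", "context", "analyte", "stimulus_state",
            "concentration")],
    names_from = "stimulus_state", values_from = "concentration")
  for (st in CTX_STATES) if (!st %in% names(wide)) wide[[st]] <- NA_real_
  unpaired <- is.na(wide$present) | is.na(wide$absent)
  if (any(unpaired)) {
    off <- wide[unpaired, c("donor", "context", "analyte")]
    stop("unpaired or missing records for ", sum(unpaired),
         " (donor, context, analyte) combination(s), e.g. ",
         paste(apply(head(off, 3), 1, paste, collapse = "/"),
               collapse = "; "),
         "; impute or drop before pairing", call. = FALSE)
  }
  if (orientation == "flipped") {
    tmp <- wide$present; wide$present <- wide$absent; wide$absent <- tmp
  }
  tibble::tibble(
    donor = wide$donor, arm = wide$arm, context = wide$context,
    analyte = wide$analyte,
    conc_present = wide$present, conc_absent = wide$absent,
    abs_diff = wide$present - wide$absent,
    rel_diff = (wide$present - wide$absent) / wide$absent)
}

#' Scale per-context mean absolute differences for heatmap display
#'
#' For each analyte, averages the absolute difference over donors within
#' each context, then divides by the largest absolute context mean for that
#' analyte (max-abs scaling). The result lies in [-1, 1], preserves the sign
#' of the stimulus effect, and makes analytes with very different secretion
#' ranges comparable on one colour scale. An analyte whose context means are
#' all zero maps to zeros.
#'
#' @param effects An effect table from [paired_differences()].
#' @return A tibble with one row per (arm, context, analyte):
#'   `mean_abs_diff` and `scaled_abs_diff`.
#' @export
scale_absolute_for_heatmap <- function(effects) {
  if (nrow(effects) == 0) stop("empty effect table", call. = FALSE)
  means <- dplyr::summarise(
    dplyr::group_by(effects, .data$arm, .data$analyte, .data$context),
    mean_abs_diff = mean(.data$abs_diff), .groups = "drop_last")
  dplyr::ungroup(dplyr::mutate(
    means,
    scaled_abs_diff = if (max(abs(.data$mean_abs_diff)) == 0) 0 else
      .data$mean_abs_diff / max(abs(.data$mean_abs_diff))))
}

#' Exclude analytes produced only in a restricted set of contexts
#'
#' An analyte secreted in only one or two contexts would look strongly
#' context-dependent purely because of its narrow expression pattern, so
#' such analytes are excluded before scoring. Under the default rule an
#' analyte is excluded when, in at least one context, the fraction of its
#' measurements above the LOD falls below `threshold`. An explicit
#' `override` list of analyte names bypasses the rule and is excluded
#' as-is (the judgment-call route).
#'
#' @param table A LOD-floored [concentration_table()].
#' @param threshold Minimum fraction of above-LOD measurements required in
#'   every context (default 0.5).
#' @param lod Limit of detection used for the rule (default 10).
#' @param override Optional character vector of analytes to exclude instead
#'   of applying the detection rule.
#' @return A list with `kept` and `excluded` character vectors.
#' @export
filter_context_restricted_analytes <- function(table, threshold = 0.5,
                                               lod = 10, override = NULL) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  analytes <- sort(unique(table$analyte))
  if (!is.null(override)) {
    excluded <- intersect(analytes, override)
  } else {
    frac <- dplyr::summarise(
      dplyr::group_by(table, .data$analyte, .data$arm, .data$context),
      frac_detected = mean(.data$concentration >= lod, na.rm = TRUE),
      .groups = "drop")
    worst <- dplyr::summarise(
      dplyr::group_by(frac, .data$analyte),
      worst = min(.data$frac_detected), .groups = "drop")
    excluded <- worst$analyte[worst$worst < threshold]
  }
  list(kept = setdiff(analytes, excluded), excluded = sort(excluded))
}
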