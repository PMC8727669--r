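#' Rescale per-context effects by their standard errors
#'
#' The per-context fixed-effect estimates live on the scale of the response
#' (relative differences), whose precision varies between analytes and
#' contexts. Dividing each estimate by its model-based standard error,
#' \eqn{\beta'_k = \hat\beta_k / \hat\sigma_{context\,k}}, puts all
#' contexts on a common signal-to-noise scale before scoring.
#'
#' @param fit A `ctx_lmm` fit from [fit_full_lmm()].
#' @return Named numeric vector of rescaled effects.
#' @export
rescale_effects <- function(fit) {
  if (any(fit$se_beta <= 0 | !is.finite(fit$se_beta))) {
    stop("degenerate fit: zero or non-finite standard error", call. = FALSE)
  }
  fit$beta / fit$se_beta
}

#' Context-dependency score
#'
#' The mean of the pairwise Euclidean distances between the rescaled
#' per-context effects (for scalar effects the distance is the absolute
#' difference):
#' \deqn{S = \frac{2}{K(K-1)} \sum_{j<k} |\beta'_j - \beta'_k|.}
#' The score is zero iff all rescaled effects are equal, invariant under
#' permutation and global sign flip of the contexts, and scales linearly
#' with the effects.
#'
#' @param beta_prime Numeric vector of rescaled effects, length K >= 2.
#' @return Non-negative scalar score.
#' @export
context_dependency_score <- function(beta_prime) {
  K <- length(beta_prime)
  if (K < 2) stop("score undefined for fewer than 2 contexts", call. = FALSE)
  mean(dist(matrix(beta_prime, ncol = 1)))
}

#' Classify context-dependency as quantitative or qualitative
#'
#' Quantitative: the stimulus moves the output in the same direction in all
#' contexts (only the magnitude varies). Qualitative: the effect changes
#' sign between contexts. Effects within `zero_tol` of zero carry no sign.
#'
#' @param beta Numeric vector of per-context effect estimates.
#' @param zero_tol Magnitude below which an effect is treated as zero
#'   (default 0: strict sign).
#' @return `"quantitative"` or `"qualitative"`.
#' @export
classify_dependency <- function(beta, zero_tol = 0) {
  if (length(beta) < 2) stop("need at least 2 contexts", call. = FALSE)
  if (any(beta > zero_tol) && any(beta < -zero_tol)) "qualitative"
  else "quantitative"
}

#' Post-hoc pairwise context comparisons
#'
#' For each unordered pair of contexts, refits the full (two cell means)
#' and null (single intercept) mixed models on that pair's observations
#' only and reports the 1-df likelihood-ratio p-value. Identifies which
#' specific contexts drive an overall context-dependency. Pairs in which
#' either context has fewer than 2 donors are skipped with a warning.
#'
#' @param effects An effect table from [paired_differences()].
#' @param analyte Analyte to test.
#' @param adjust If `TRUE`, adds Benjamini-Hochberg adjusted p-values
#'   (default `FALSE`; raw p-values are always returned).
#' @return Tibble with `context_a`, `context_b`, `statistic`, `p_value`
#'   (and `p_adjusted` if requested).
#' @export
posthoc_pairwise_tests <- function(effects, analyte, adjust = FALSE) {
  sub <- effects[effects$analyte == analyte, ]
  contexts <- sort(unique(sub$context))
  if (length(contexts) < 2) {
    stop("need at least 2 contexts for analyte ", analyte, call. = FALSE)
  }
  pairs <- utils::combn(contexts, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    pp <- pairs[, i]
    two <- sub[sub$context %in% pp, ]
    donors_per <- tapply(two$donor, two$context,
                         function(d) length(unique(d)))
    if (any(donors_per < 2)) {
      warning("skipping pair ", pp[1], "/", pp[2], " for ", analyte,
              ": fewer than 2 donors in a context", call. = FALSE)
      return(tibble::tibble(context_a = pp[1], context_b = pp[2],
                            statistic = NA_real_, p_value = NA_real_))
    }
    full <- fit_lmm(two$rel_diff, two$context, two$donor)
    null <- fit_null_lmm(two$rel_diff, donor = two$donor)
    lrt <- likelihood_ratio_test(full, null)
    tibble::tibble(context_a = pp[1], context_b = pp[2],
                   statistic = lrt$statistic, p_value = lrt$p_value)
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Score context-dependency for every analyte
#'
#' Runs the full scoring pipeline per analyte: fit the context cell-means
#' mixed model and its intercept-only null on the relative differences,
#' rescale the per-context effects by their standard errors, take the mean
#' pairwise distance as the score, classify the dependency as quantitative
#' or qualitative, and annotate likelihood-ratio significance.
#'
#' @param effects An effect table from [paired_differences()] with excluded
#'   analytes already removed.
#' @param alpha_levels Decreasing significance thresholds mapped to
#'   `*`, `**`, `***` (default `c(0.05, 0.01, 0.001)`).
#' @param zero_tol Passed to [classify_dependency()].
#' @return A tibble with one row per analyte: `analyte`, `score`,
#'   `classification`, `lrt_stat`, `df`, `p_value`, `significance`,
#'   `converged`, plus list-columns `beta`, `se_beta`, `beta_prime` holding
#'   the named per-context vectors. Sorted by decreasing score.
#' @export
score_all_analytes <- function(effects, alpha_levels = c(0.05, 0.01, 0.001),
                               zero_tol = 0) {
  if (any(diff(alpha_levels) >= 0)) {
    stop("alpha_levels must be strictly decreasing", call. = FALSE)
  }
  rows <- lapply(split(effects, effects$analyte), function(sub) {
    full <- fit_full_lmm(sub$rel_diff, sub$context, sub$donor)
    null <- fit_null_lmm(sub$rel_diff, donor = sub$donor)
    lrt <- likelihood_ratio_test(full, null)
    bp <- rescale_effects(full)
    tibble::tibble(
      analyte = sub$analyte[1],
      score = context_dependency_score(bp),
      classification = classify_dependency(full$beta, zero_tol),
      lrt_stat = lrt$statistic, df = lrt$df, p_value = lrt$p_value,
      significance = significance_label(lrt$p_value, alpha_levels),
      converged = full$converged && null$converged,
      beta = list(full$beta), se_beta = list(full$se_beta),
      beta_prime = list(bp))
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$score), ]
}

significance_label <- function(p, alpha_levels = c(0.05, 0.01, 0.001)) {
  stars <- c("*", "**", "***")
  hit <- which(p <= alpha_levels)
  if (length(hit) == 0) "ns" else stars[max(hit)]
}

#' Bar plot of context-dependency scores
#'
#' Scores per analyte, black bars for quantitative and grey for qualitative
#' dependency, significance stars above the bars.
#'
#' @param scores Output of [score_all_analytes()].
#' @return A ggplot object.
#' @export
plot_context_scores <- function(scores) {
  scores$analyte <- factor(scores$analyte,
                           levels = scores$analyte[order(-scores$score)])
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$analyte, y = .data$score,
                               fill = .data$classification)) +
    ggplot2::geom_col(colour = "black", linewidth = 0.2) +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(.data$significance == "ns", "",
                                  .data$significance)),
      vjust = -0.3) +
    ggplot2::scale_fill_manual(
      values = c(quantitative = "black", qualitative = "grey60")) +
    ggplot2::labs(x = NULL, y = "context-dependency score") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
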