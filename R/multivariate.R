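#' Build an observations x analytes profile matrix
#'
#' Pivots a completed concentration table into a numeric matrix with one
#' row per (donor, context, stimulus_state) sample and one column per
#' analyte, optionally transformed per analyte. Cytokine concentrations
#' span orders of magnitude, so the default z-scores each analyte column;
#' `"log10"` and `"identity"` (raw pg/mL) are also available.
#'
#' @param table A completed (no missing values) [concentration_table()] for
#'   a single arm or a coherent set of arms.
#' @param transform One of `"zscore"`, `"log10"`, `"identity"`.
#' @return A list with `matrix` (numeric), and `annotations` (tibble with
#'   `donor`, `arm`, `context`, `stimulus_state` aligned to the rows).
#' @export
build_profile_matrix <- function(table,
                                 transform = c("zscore", "log10",
                                               "identity")) {
  transform <- match.arg(transform)
  if (any(is.na(table$concentration))) {
    stop("profile matrix requires a complete table; run ",
         "impute_chained_equations() first", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(table, names_from = "analyte",
                             values_from = "concentration")
  ann_cols <- c("donor", "arm", "context", "stimulus_state")
  mat <- as.matrix(wide[setdiff(names(wide), ann_cols)])
  if (any(is.na(mat))) {
    stop("unbalanced analyte coverage across samples; impute first",
         call. = FALSE)
  }
  mat <- switch(transform,
    identity = mat,
    log10 = log10(mat),
    zscore = {
      z <- scale(mat)
      z[, attr(z, "scaled:scale") == 0] <- 0   # constant analyte -> zeros
      z
    })
  attr(mat, "scaled:center") <- NULL
  attr(mat, "scaled:scale") <- NULL
  list(matrix = mat, annotations = wide[ann_cols])
}

#' PCA of output profiles with per-condition barycenters
#'
#' Principal-component analysis (centered, unscaled — any per-analyte
#' scaling is chosen in [build_profile_matrix()]) retaining all
#' min(n - 1, p) components, plus the barycenter (arithmetic mean position)
#' of each group of rows in PC space.
#'
#' @param profile Output of [build_profile_matrix()].
#' @param group_by Annotation fields defining the groups
#'   (default `c("context", "stimulus_state")`).
#' @return A list with `scores` (tibble of annotations + PC columns),
#'   `barycenters` (tibble of group fields + PC columns), `sdev`, and
#'   `rotation`.
#' @export
pca_with_barycenters <- function(profile,
                                 group_by = c("context", "stimulus_state")) {
  pca <- prcomp(profile$matrix, center = TRUE, scale. = FALSE)
  scores <- tibble::as_tibble(as.data.frame(pca$x))
  scores <- dplyr::bind_cols(profile$annotations, scores)
  pc_cols <- colnames(pca$x)
  bary <- dplyr::summarise(
    dplyr::group_by(scores, dplyr::across(dplyr::all_of(group_by))),
    dplyr::across(dplyr::all_of(pc_cols), mean),
    n_rows = dplyr::n(),
    .groups = "drop")
  if (any(bary$n_rows == 1)) {
    warning("group(s) with a single row: barycenter equals that row",
            call. = FALSE)
  }
  list(scores = scores, barycenters = bary, sdev = pca$sdev,
       rotation = pca$rotation)
}

#' Stimulus-induced shift distance per context
#'
#' Euclidean distance between the stimulus-present and stimulus-absent
#' barycenters of a context, computed over all retained principal
#' components. Because all components are kept, the PCA is a rotation and
#' the distance equals the barycenter distance in the (transformed)
#' analyte space.
#'
#' @param pca Output of [pca_with_barycenters()] grouped by
#'   `c("context", "stimulus_state")` (an extra leading group field such as
#'   `arm` is allowed).
#' @param context Context whose shift is measured. If omitted, all contexts
#'   are returned.
#' @return Tibble with `context`, `distance`, `n_components_used`.
#' @export
stimulus_shift_distance <- function(pca, context = NULL) {
  bary <- pca$barycenters
  contexts <- if (is.null(context)) unique(bary$context) else context
  pc_cols <- grep("^PC[0-9]+$", names(bary), value = TRUE)
  rows <- lapply(contexts, function(ctx) {
    sub <- bary[bary$context == ctx, ]
    a <- sub[sub$stimulus_state == "present", pc_cols]
    b <- sub[sub$stimulus_state == "absent", pc_cols]
    if (nrow(a) != 1 || nrow(b) != 1) {
      stop("context ", ctx, " lacks a barycenter for one stimulus state",
           call. = FALSE)
    }
    tibble::tibble(context = ctx,
                   distance = sqrt(sum((as.numeric(a) - as.numeric(b))^2)),
                   n_components_used = length(pc_cols))
  })
  dplyr::bind_rows(rows)
}

#' Paired Wilcoxon signed-rank tests per context and analyte
#'
#' Two-sided paired Wilcoxon tests of the stimulus effect: within each
#' (arm, context, analyte), the donor-paired stimulus-present and
#' stimulus-absent values are compared. Zero differences are dropped
#' before testing (standard signed-rank convention); if all differences
#' are zero the p-value is 1. The exact null distribution is used for
#' n <= 25 informative pairs without ties, the normal approximation
#' otherwise. With fewer than 2 informative pairs the p-value is `NA` with
#' a warning.
#'
#' @param effects An effect table from [paired_differences()].
#' @param value Which paired difference to test: `"abs_diff"` (raw
#'   concentrations present vs absent) is the default.
#' @return Tibble with `arm`, `context`, `analyte`, `n_pairs`,
#'   `n_informative`, `p_value`.
#' @export
paired_wilcoxon_by_context <- function(effects, value = "abs_diff") {
  groups <- split(effects,
                  paste(effects$arm, effects$context, effects$analyte,
                        sep = "\r"))
  rows <- lapply(groups, function(g) {
    d <- g[[value]]
    informative <- d[d != 0]
    p <- if (length(informative) == 0) {
      1
    } else if (length(informative) < 2) {
      warning("fewer than 2 informative pairs for ", g$analyte[1], " in ",
              g$context[1], call. = FALSE)
      NA_real_
    } else {
      exact <- length(informative) <= 25 &&
        !any(duplicated(abs(informative)))
      suppressWarnings(
        wilcox.test(informative, exact = exact, correct = TRUE)$p.value)
    }
    tibble::tibble(arm = g$arm[1], context = g$context[1],
                   analyte = g$analyte[1], n_pairs = length(d),
                   n_informative = length(informative), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$arm, out$context, out$analyte), ]
}
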