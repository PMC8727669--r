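#' Remove donor structure from a response
#'
#' Fits the intercept-only random-intercept model (grand mean fixed effect,
#' donor random intercept) and returns the residuals
#' \eqn{y - \hat\mu - \hat\alpha_{donor}}, where \eqn{\hat\alpha} are the
#' best linear unbiased predictors (BLUPs) of the donor intercepts. This
#' strips intra-donor correlation before the group-lasso step so that the
#' penalized regression sees (approximately) exchangeable errors.
#'
#' @param y Numeric response vector.
#' @param donor Donor label per observation.
#' @return Numeric residual vector (sums to ~0).
#' @export
residualize <- function(y, donor) {
  fit <- fit_null_lmm(y, donor = donor)
  unname(y - fit$beta[[1]] - fit$blup[as.character(donor)])
}

#' Build a grouped one-hot design for competing context variables
#'
#' Encodes each context variable (e.g. cell type, activating stimulus) as
#' reference-dropped one-hot indicator columns, centers every column, and
#' records the grouping: all columns of one variable form one group, so the
#' group lasso selects or drops a whole variable at once.
#'
#' @param data A data frame holding the variables.
#' @param variables Character vector of column names, one group per name.
#' @return A list of class `ctx_group_design`: `X` (centered design
#'   matrix), `groups` (integer group index per column), `group_names`,
#'   `group_sizes`.
#' @export
build_group_design <- function(data, variables) {
  cols <- list(); grp <- integer(0)
  for (g in seq_along(variables)) {
    v <- variables[g]
    if (!v %in% names(data)) stop("variable not found: ", v, call. = FALSE)
    levels_v <- sort(unique(as.character(data[[v]])))
    if (length(levels_v) < 2) {
      stop("degenerate group: variable '", v, "' has a single level",
           call. = FALSE)
    }
    for (lv in levels_v[-1]) {           # reference level dropped
      col <- as.numeric(data[[v]] == lv)
      if (var(col) == 0) {
        stop("degenerate group: level '", lv, "' of '", v,
             "' is constant or collinear", call. = FALSE)
      }
      cols[[paste(v, lv, sep = ".")]] <- col - mean(col)
      grp <- c(grp, g)
    }
  }
  X <- do.call(cbind, cols)
  structure(list(X = X, groups = grp, group_names = variables,
                 group_sizes = as.integer(table(grp))),
            class = "ctx_group_design")
}

#' Group-lasso regularization path
#'
#' Solves, over a decreasing penalty grid,
#' \deqn{\min_\beta \frac{1}{2n}\|r - X\beta\|_2^2 +
#'   \lambda \sum_g \sqrt{p_g}\,\|\beta_g\|_2}
#' by block-coordinate descent with exact group updates: a whole group is
#' zeroed when \eqn{\|X_g' r_g\|_2 / n \le \lambda\sqrt{p_g}} (the KKT
#' threshold), otherwise its coefficients solve the block stationarity
#' equation via an eigendecomposition of \eqn{X_g'X_g/n} and scalar
#' root-finding on the coefficient norm. The grid is log-spaced from
#' `lambda_max` (the smallest penalty with an all-zero solution, available
#' in closed form) down to `lambda_max / 1000`, with warm starts.
#'
#' @param design A `ctx_group_design`.
#' @param r Residual (response) vector; centered internally.
#' @param n_lambda Grid size (default 100).
#' @param tol Convergence tolerance on the max coefficient change
#'   (default 1e-8).
#' @param max_iter Iteration cap per grid point (default 10000).
#' @param lambda Optional explicit penalty grid (decreasing); overrides
#'   `n_lambda`.
#' @return A list of class `ctx_grouplasso_path`: `lambda` (grid),
#'   `coef_norms` (groups x lambda matrix of per-group L2 norms), `coefs`
#'   (coefficients x lambda matrix), `lambda_max`, `vanish_lambda` (largest
#'   grid lambda at which each group is nonzero; 0 if never), and
#'   `group_names`.
#' @export
group_lasso_path <- function(design, r, n_lambda = 100, tol = 1e-8,
                             max_iter = 10000, lambda = NULL) {
  X <- design$X
  n <- nrow(X)
  stopifnot(length(r) == n)
  r <- r - mean(r)
  grp <- design$groups
  G <- max(grp)
  w <- sqrt(design$group_sizes)

  # per-group cached pieces
  idx <- split(seq_along(grp), grp)
  Ag <- lapply(idx, function(i) crossprod(X[, i, drop = FALSE]) / n)
  eig <- lapply(Ag, eigen, symmetric = TRUE)

  lambda_max <- max(vapply(seq_len(G), function(g) {
    sqrt(sum((crossprod(X[, idx[[g]], drop = FALSE], r) / n)^2)) / w[g]
  }, numeric(1)))
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max / 1000),
                      length.out = n_lambda))
  } else {
    if (is.unsorted(rev(lambda))) {
      stop("lambda grid must be decreasing", call. = FALSE)
    }
    n_lambda <- length(lambda)
  }

  p <- ncol(X)
  beta <- numeric(p)
  coefs <- matrix(0, p, n_lambda,
                  dimnames = list(colnames(X), NULL))
  norms <- matrix(0, G, n_lambda,
                  dimnames = list(design$group_names, NULL))
  fitted <- numeric(n)
  for (l in seq_len(n_lambda)) {
    lam <- lambda[l]
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (g in seq_len(G)) {
        i <- idx[[g]]
        old <- beta[i]
        partial <- r - fitted + X[, i, drop = FALSE] %*% old
        z <- crossprod(X[, i, drop = FALSE], partial)[, 1] / n
        new <- group_prox(z, eig[[g]], lam * w[g])
        if (any(new != old)) {
          fitted <- fitted + X[, i, drop = FALSE] %*% (new - old)
          delta <- max(delta, max(abs(new - old)))
          beta[i] <- new
        }
      }
      if (delta < tol) break
    }
    if (iter == max_iter && delta >= tol) {
      stop("group-lasso did not converge at lambda = ", signif(lam, 4),
           " (max change ", signif(delta, 3), ")", call. = FALSE)
    }
    coefs[, l] <- beta
    norms[, l] <- vapply(idx, function(i) sqrt(sum(beta[i]^2)), numeric(1))
  }

  vanish <- apply(norms > 1e-10, 1, function(nz)
    if (any(nz)) max(lambda[nz]) else 0)
  structure(list(lambda = lambda, coef_norms = norms, coefs = coefs,
                 lambda_max = lambda_max, vanish_lambda = vanish,
                 group_names = design$group_names),
            class = "ctx_grouplasso_path")
}

# exact minimizer of (1/2) b' A b - z' b + pen * ||b||_2 given eigen(A)
group_prox <- function(z, eig, pen) {
  if (sqrt(sum(z^2)) <= pen) return(numeric(length(z)))
  zt <- crossprod(eig$vectors, z)[, 1]
  d <- pmax(eig$values, 0)
  # solve t = ||(A + pen/t I)^{-1} z|| for the coefficient norm t
  f <- function(t) sqrt(sum((zt * t / (d * t + pen))^2)) - t
  upper <- sqrt(sum(z^2)) / max(min(d[d > 0], na.rm = TRUE), 1e-12)
  if (!is.finite(upper) || upper <= 0) upper <- 1e8
  root <- stats::uniroot(f, lower = 1e-14, upper = upper * (1 + 1e-6),
                         tol = 1e-14, extendInt = "downX")$root
  b <- eig$vectors %*% (zt / (d + pen / root))
  b[, 1]
}

#' Which context variable dominates the path?
#'
#' The dominant variable is the one whose coefficient group is the last to
#' vanish as the penalty grows (largest vanish lambda). When the top two
#' vanish penalties are within `tie_tol` (relative), the verdict is
#' `"tie"` — the ranking should then be interpreted with caution. If no
#' group ever enters the path the verdict is `"none"`.
#'
#' @param path A `ctx_grouplasso_path`.
#' @param tie_tol Relative tie tolerance (default 0.05).
#' @return A list with `dominant` (group name, `"tie"`, or `"none"`),
#'   `vanish_lambda` (named vector), and `relative_gap`.
#' @export
dominant_variable <- function(path, tie_tol = 0.05) {
  v <- path$vanish_lambda
  if (all(v == 0)) {
    return(list(dominant = "none", vanish_lambda = v, relative_gap = NA))
  }
  ord <- order(v, decreasing = TRUE)
  gap <- if (length(v) > 1 && v[ord[1]] > 0) {
    unname((v[ord[1]] - v[ord[2]]) / v[ord[1]])
  } else 1
  dominant <- if (gap < tie_tol) "tie" else path$group_names[ord[1]]
  list(dominant = dominant, vanish_lambda = v, relative_gap = gap)
}

#' Plot a group-lasso coefficient path
#'
#' Per-group coefficient norms against the penalty (log x axis); the last
#' curve to reach zero marks the dominant variable.
#'
#' @param path A `ctx_grouplasso_path`.
#' @return A ggplot object.
#' @export
plot_group_lasso_path <- function(path) {
  df <- tibble::tibble(
    lambda = rep(path$lambda, each = nrow(path$coef_norms)),
    group = rep(rownames(path$coef_norms), ncol(path$coef_norms)),
    norm = as.numeric(path$coef_norms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$norm,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty (lambda)", y = "group coefficient norm") +
    ggplot2::theme_classic()
}
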