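#' Random-intercept linear mixed model by profiled maximum likelihood
#'
#' Fits the cell-means mixed model
#' \deqn{Y_{ij} = \beta_{k(ij)} + \alpha_i + \varepsilon_{ij},\qquad
#'   \alpha_i \sim N(0, \nu^2),\ \varepsilon_{ij} \sim N(0, \sigma^2)}
#' where each observation carries one context label \eqn{k} (one fixed
#' effect per context, no global intercept) and one donor label \eqn{i}
#' (random intercept). Estimation is full maximum likelihood — not REML —
#' so log-likelihoods are comparable across fixed-effect structures and the
#' likelihood-ratio test of the context effect is valid.
#'
#' For a fixed variance ratio \eqn{\lambda = \nu^2/\sigma^2} the per-donor
#' covariance is compound symmetric, GLS gives \eqn{\hat\beta(\lambda)} and
#' \eqn{\hat\sigma^2(\lambda)} in closed form (via the Woodbury identity on
#' per-donor blocks), and the profile log-likelihood is maximized over
#' \eqn{\lambda \in [0, 10^6]} by bounded scalar search. \eqn{\hat\nu^2}
#' may sit on the 0 boundary. Standard errors come from the inverse
#' expected information at the optimum,
#' \eqn{\hat\sigma^2 (X'V^{-1}X)^{-1}}.
#'
#' @param y Numeric response vector (typically stimulus-induced relative
#'   differences for one analyte).
#' @param context Context label per observation (coerced to character).
#'   Pass a single constant label (or use [fit_null_lmm()]) for the
#'   intercept-only null model.
#' @param donor Donor label per observation.
#' @param lambda_max_bound Upper bound of the variance-ratio search
#'   (default 1e6).
#' @return An object of class `ctx_lmm`: a list with `beta` (named
#'   per-context estimates), `se_beta`, `nu2`, `sigma2`, `loglik`,
#'   `n_params`, `converged`, `n_obs`, `lambda` (fitted variance ratio),
#'   `contexts`, and `blup` (named per-donor random-intercept predictions).
#' @export
fit_lmm <- function(y, context, donor, lambda_max_bound = 1e6) {
  ss <- lmm_suffstats(y, context, donor)
  if (ss$D < 2) stop("design error: need at least 2 donors", call. = FALSE)

  obj <- function(lambda) lmm_profile(lambda, ss)$loglik
  opt <- tryCatch(
    optimize(obj, interval = c(0, lambda_max_bound), maximum = TRUE,
             tol = 1e-10),
    error = function(e) NULL)
  converged <- !is.null(opt)
  lambda_hat <- if (converged) opt$maximum else 0
  # the interior search cannot land exactly on the boundary; test it
  if (!converged || obj(0) >= opt$objective) lambda_hat <- 0

  fit <- lmm_profile(lambda_hat, ss)
  se <- sqrt(pmax(diag(fit$sigma2 * solve(fit$A)), 0))
  blup <- lmm_blup(lambda_hat, ss, fit$beta)
  structure(list(
    beta = setNames(fit$beta, ss$contexts),
    se_beta = setNames(se, ss$contexts),
    nu2 = lambda_hat * fit$sigma2,
    sigma2 = fit$sigma2,
    loglik = fit$loglik,
    n_params = ss$K + 2,
    converged = converged && all(is.finite(fit$beta)),
    n_obs = ss$n,
    lambda = lambda_hat,
    contexts = ss$contexts,
    blup = setNames(blup, ss$donors)), class = "ctx_lmm")
}

#' @rdname fit_lmm
#' @export
fit_full_lmm <- function(y, context, donor, lambda_max_bound = 1e6) {
  context <- as.character(context)
  per_ctx <- tapply(as.character(donor), context,
                    function(d) length(unique(d)))
  if (any(per_ctx < 2)) {
    stop("design error: context(s) observed for fewer than 2 donors: ",
         paste(names(per_ctx)[per_ctx < 2], collapse = ", "), call. = FALSE)
  }
  fit_lmm(y, context, donor, lambda_max_bound)
}

#' @rdname fit_lmm
#' @export
fit_null_lmm <- function(y, context = NULL, donor, lambda_max_bound = 1e6) {
  fit_lmm(y, rep("(intercept)", length(y)), donor, lambda_max_bound)
}

# sufficient statistics: everything the profile likelihood needs, O(n) once
lmm_suffstats <- function(y, context, donor) {
  stopifnot(length(y) == length(context), length(y) == length(donor))
  if (any(!is.finite(y))) stop("non-finite response values", call. = FALSE)
  context <- as.character(context)
  donor <- as.character(donor)
  contexts <- sort(unique(context))
  donors <- sort(unique(donor))
  ci <- match(context, contexts)
  di <- match(donor, donors)
  K <- length(contexts); D <- length(donors); n <- length(y)
  M <- matrix(0, D, K)                       # donor x context counts
  for (r in seq_len(n)) M[di[r], ci[r]] <- M[di[r], ci[r]] + 1
  list(contexts = contexts, donors = donors, K = K, D = D, n = n,
       M = M, nd = rowsum_vec(rep(1, n), di, D),
       sdon = rowsum_vec(y, di, D),           # per-donor sums
       ctx_counts = rowsum_vec(rep(1, n), ci, K),
       Xty = rowsum_vec(y, ci, K),
       yy = sum(y * y))
}

rowsum_vec <- function(v, idx, m) {
  out <- numeric(m)
  agg <- rowsum(v, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

# profile log-likelihood (and GLS pieces) at a fixed variance ratio lambda
lmm_profile <- function(lambda, ss) {
  cd <- lambda / (1 + lambda * ss$nd)        # Woodbury weights per donor
  A <- diag(ss$ctx_counts, ss$K) - crossprod(ss$M, ss$M * cd)
  b <- ss$Xty - crossprod(ss$M, ss$sdon * cd)[, 1]
  beta <- solve(A, b)
  yVy <- ss$yy - sum(cd * ss$sdon^2)
  rss_v <- max(yVy - sum(beta * b), 0)
  sigma2 <- max(rss_v / ss$n, 1e-12)
  loglik <- -0.5 * ss$n * (log(2 * pi * sigma2) + 1) -
    0.5 * sum(log1p(lambda * ss$nd))
  list(beta = beta, A = A, sigma2 = sigma2, loglik = loglik)
}

# best linear unbiased predictors of the donor intercepts
lmm_blup <- function(lambda, ss, beta) {
  resid_sum <- ss$sdon - as.numeric(ss$M %*% beta)
  (lambda / (1 + lambda * ss$nd)) * resid_sum
}

#' @export
print.ctx_lmm <- function(x, ...) {
  cat("Random-intercept LMM (ML), ", x$n_obs, " obs, ",
      length(x$beta), " context(s)\n", sep = "")
  print(round(rbind(beta = x$beta, se = x$se_beta), 4))
  cat("nu^2 =", signif(x$nu2, 4), " sigma^2 =", signif(x$sigma2, 4),
      " logLik =", round(x$loglik, 3), "\n")
  invisible(x)
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' Compares the context-aware cell-means fit to the intercept-only null fit
#' on the same data: the statistic is \eqn{2(\ell_{full} - \ell_{null})}
#' clipped at zero, referred to a chi-square distribution with
#' \eqn{K - 1} degrees of freedom, where \eqn{K} is the number of contexts
#' in the full model.
#'
#' @param full,null `ctx_lmm` fits on identical observations.
#' @return A list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, null) {
  if (full$n_obs != null$n_obs) {
    stop("full and null fits use different numbers of observations",
         call. = FALSE)
  }
  df <- length(full$beta) - length(null$beta)
  statistic <- max(0, 2 * (full$loglik - null$loglik))
  list(statistic = statistic, df = df,
       p_value = pchisq(statistic, df = df, lower.tail = FALSE))
}
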