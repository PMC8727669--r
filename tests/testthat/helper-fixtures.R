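# Fixture builders and independent oracles shared across the suite.

# minimal tidy table: 1 donor, 1 context, 3 analytes, 2 states
toy_table <- function() {
  concentration_table(tibble::tibble(
    donor = "D01", arm = "Th", context = "Th0",
    stimulus_state = rep(c("present", "absent"), each = 3),
    analyte = rep(c("IL-2", "IL-6", "IL-10"), 2),
    concentration = c(150, 80, 40, 100, 90, 60)))
}

# balanced donors x contexts long data at the response level
balanced_y <- function(n_donors, contexts, donor_sd, noise_sd,
                       beta = NULL) {
  beta <- beta %||% rep(0, length(contexts))
  donors <- sprintf("d%03d", seq_len(n_donors))
  grid <- expand.grid(donor = donors, context = contexts,
                      stringsAsFactors = FALSE)
  alpha <- stats::rnorm(n_donors, 0, donor_sd)
  grid$y <- beta[match(grid$context, contexts)] +
    alpha[match(grid$donor, donors)] +
    stats::rnorm(nrow(grid), 0, noise_sd)
  grid
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direct multivariate-normal log-density of y under the random-intercept
# model: Sigma = sigma2 * I + nu2 * ZZ' built explicitly, no Woodbury
loglik_oracle <- function(y, context, donor, beta_by_context, nu2, sigma2) {
  mu <- beta_by_context[as.character(context)]
  Z <- outer(donor, unique(donor), "==") * 1
  Sigma <- diag(sigma2, length(y)) + nu2 * tcrossprod(Z)
  r <- y - mu
  -0.5 * (length(y) * log(2 * pi) +
            determinant(Sigma, logarithm = TRUE)$modulus[1] +
            sum(r * solve(Sigma, r)))
}

# brute-force mean pairwise distance (double loop)
brute_mean_pairwise <- function(v) {
  K <- length(v)
  tot <- 0
  for (j in seq_len(K - 1)) for (k in (j + 1):K) tot <- tot + abs(v[j] - v[k])
  tot / (K * (K - 1) / 2)
}

# group-lasso objective and KKT residual at one lambda
gl_objective <- function(X, grp, r, beta, lambda) {
  w <- sqrt(as.numeric(table(grp)))
  pen <- sum(vapply(unique(grp), function(g)
    w[g] * sqrt(sum(beta[grp == g]^2)), numeric(1)))
  sum((r - X %*% beta)^2) / (2 * nrow(X)) + lambda * pen
}

gl_kkt_residual <- function(X, grp, r, beta, lambda) {
  n <- nrow(X)
  grad <- crossprod(X, X %*% beta - r)[, 1] / n
  w <- sqrt(as.numeric(table(grp)))
  max(vapply(unique(grp), function(g) {
    i <- grp == g
    ng <- sqrt(sum(beta[i]^2))
    if (ng > 0) {
      max(abs(grad[i] + lambda * w[g] * beta[i] / ng))
    } else {
      max(0, sqrt(sum(grad[i]^2)) - lambda * w[g])
    }
  }, numeric(1)))
}

# proximal-gradient oracle for the group lasso (independent of the
# block-coordinate-descent implementation)
gl_proxgrad_oracle <- function(X, grp, r, lambda, max_iter = 200000,
                               tol = 1e-12) {
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  w <- sqrt(as.numeric(table(grp)))
  beta <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    grad <- crossprod(X, X %*% beta - r)[, 1] / n
    u <- beta - grad / L
    new <- beta
    for (g in unique(grp)) {
      i <- grp == g
      ng <- sqrt(sum(u[i]^2))
      thr <- lambda * w[g] / L
      new[i] <- if (ng <= thr) 0 else (1 - thr / ng) * u[i]
    }
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  beta
}

# exact two-sided signed-rank p-value by enumeration of all sign patterns
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% rk
  p_le <- mean(v_all <= v_obs)
  p_ge <- mean(v_all >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}
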