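test_that("residualization removes the grand mean and donor BLUPs", {
  # constant response: nothing left
  expect_equal(residualize(rep(2.5, 12), rep(c("a", "b", "c"), each = 4)),
               rep(0, 12))

  # no donor variance: reduces to centering
  set.seed(40)
  y <- rnorm(12)
  donor <- rep(c("a", "b", "c"), each = 4)
  fit <- fit_null_lmm(y, donor = donor)
  if (fit$nu2 == 0) {
    expect_equal(residualize(y, donor), y - mean(y), tolerance = 1e-8)
  }

  # pure donor-offset data: BLUP shrinkage factor m*lambda/(1+m*lambda)
  # approaches 1 with replication, so residuals shrink toward zero
  offsets <- c(-1, 0.2, 1.3, -0.6)
  res_small <- residualize(rep(offsets, each = 2),
                           rep(paste0("d", 1:4), each = 2))
  res_large <- residualize(rep(offsets, each = 20),
                           rep(paste0("d", 1:4), each = 20))
  expect_lt(max(abs(res_large)), max(abs(res_small)) + 1e-10)
  expect_lt(max(abs(res_large)),
            0.1 * max(abs(offsets - mean(offsets))))
  expect_equal(sum(res_large), 0, tolerance = 1e-8)
})

test_that("group design encodes variables as centered one-hot groups", {
  df <- expand.grid(dc_type = c("cDC2", "MoDC"),
                    stimulus = c("Zym", "PAM3", "LPS", "HKSA", "Curd"),
                    rep = 1:9, stringsAsFactors = FALSE)
  des <- build_group_design(df, c("dc_type", "stimulus"))
  expect_equal(ncol(des$X), 1 + 4)
  expect_equal(des$group_sizes, c(1L, 4L))
  expect_equal(unname(colSums(des$X)), rep(0, 5), tolerance = 1e-12)

  expect_error(build_group_design(df["dc_type"], "missing"), "not found")
  df$onelevel <- "same"
  expect_error(build_group_design(df, c("dc_type", "onelevel")),
               "single level")
})

test_that("path is all-zero at and above the closed-form lambda_max", {
  set.seed(41)
  df <- data.frame(a = rep(c("x", "y"), 20),
                   b = rep(c("p", "q", "r", "s"), 10))
  des <- build_group_design(df, c("a", "b"))
  r <- rnorm(40); r <- r - mean(r)
  path <- group_lasso_path(des, r)

  w <- sqrt(des$group_sizes)
  lam_expected <- max(vapply(1:2, function(g) {
    i <- des$groups == g
    sqrt(sum((crossprod(des$X[, i, drop = FALSE], r) / 40)^2)) / w[g]
  }, numeric(1)))
  expect_equal(path$lambda_max, lam_expected)
  expect_equal(unname(path$coef_norms[, 1]), c(0, 0))

  above <- group_lasso_path(des, r, lambda = c(2, 1.5, 1) * lam_expected)
  expect_true(all(above$coef_norms == 0))
})

test_that("single-column soft-threshold solution is reproduced exactly", {
  X <- matrix(c(1, -1, 1, -1), dimnames = list(NULL, "x"))
  des <- structure(list(X = X, groups = 1L, group_names = "x",
                        group_sizes = 1L), class = "ctx_group_design")
  r <- c(2, -2, 2, -2)
  # z = x'r/n = 2; beta(lambda) = (1 - lambda/|z|)+ * z
  path <- group_lasso_path(des, r, lambda = c(2, 1, 0.5, 0.25))
  expect_equal(unname(path$coefs["x", ]), c(0, 1, 1.5, 1.75),
               tolerance = 1e-8)
  expect_equal(path$lambda_max, 2)
})

test_that("a group orthogonal to the response never enters", {
  # a balanced crossed design makes the two groups orthogonal; signal
  # purely on variable a leaves group b at zero for every lambda
  df <- expand.grid(a = c("x", "y"), b = c("p", "q", "r"), rep = 1:6,
                    stringsAsFactors = FALSE)
  des <- build_group_design(df, c("a", "b"))
  r <- 2 * (df$a == "y"); r <- r - mean(r)
  path <- group_lasso_path(des, r)
  expect_true(all(path$coef_norms["b", ] < 1e-10))
  expect_true(any(path$coef_norms["a", ] > 0.5))
})

test_that("KKT conditions hold along the path", {
  set.seed(42)
  df <- data.frame(a = sample(c("x", "y"), 60, replace = TRUE),
                   b = sample(c("p", "q", "r", "s", "t"), 60,
                              replace = TRUE))
  des <- build_group_design(df, c("a", "b"))
  r <- 0.8 * (df$a == "y") + 0.5 * (df$b == "q") + rnorm(60, 0, 0.3)
  r <- r - mean(r)
  path <- group_lasso_path(des, r)
  for (l in seq(1, length(path$lambda), by = 7)) {
    expect_lt(gl_kkt_residual(des$X, des$groups, r, path$coefs[, l],
                              path$lambda[l]), 1e-6)
  }
})

test_that("solver matches a projected-gradient oracle", {
  set.seed(43)
  df <- data.frame(a = sample(c("x", "y"), 50, replace = TRUE),
                   b = sample(c("p", "q", "r", "s", "t"), 50,
                              replace = TRUE))
  des <- build_group_design(df, c("a", "b"))
  r <- rnorm(50, 0, 1) + 1.2 * (df$b == "r"); r <- r - mean(r)
  for (frac in c(0.5, 0.1, 0.02)) {
    lam <- frac * 1  # absolute penalties in the active range
    path <- group_lasso_path(des, r, lambda = c(lam * 2, lam))
    oracle <- gl_proxgrad_oracle(des$X, des$groups, r, lam)
    expect_equal(unname(path$coefs[, 2]), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("path norms are homogeneous and continuous in lambda", {
  set.seed(44)
  df <- data.frame(a = rep(c("x", "y"), 25),
                   b = sample(c("p", "q", "r"), 50, replace = TRUE))
  des <- build_group_design(df, c("a", "b"))
  r <- 0.7 * (df$a == "y") + rnorm(50, 0, 0.4); r <- r - mean(r)
  path <- group_lasso_path(des, r)
  scaled <- group_lasso_path(des, 3 * r)
  expect_equal(scaled$lambda_max, 3 * path$lambda_max, tolerance = 1e-10)
  expect_equal(unname(scaled$coef_norms), unname(3 * path$coef_norms),
               tolerance = 1e-6)
  expect_equal(scaled$vanish_lambda, 3 * path$vanish_lambda,
               tolerance = 1e-8)

  jumps <- abs(diff(t(path$coef_norms)))
  expect_lt(max(jumps), 0.2 * max(path$coef_norms))
})

test_that("dominant-variable verdicts: clear winner, tie, and none", {
  set.seed(45)
  df <- expand.grid(dc_type = c("cDC2", "MoDC"),
                    stimulus = c("p", "q", "r", "s", "t"),
                    donor = sprintf("d%02d", 1:9),
                    stringsAsFactors = FALSE)
  y <- 0.6 * (df$dc_type == "MoDC") + rnorm(nrow(df), 0, 0.2)
  r <- residualize(y, df$donor)
  des <- build_group_design(df, c("dc_type", "stimulus"))
  path <- group_lasso_path(des, r)
  verdict <- dominant_variable(path)
  expect_equal(verdict$dominant, "dc_type")

  tie_path <- path
  tie_path$vanish_lambda <- c(dc_type = 1, stimulus = 0.995)
  expect_equal(dominant_variable(tie_path)$dominant, "tie")

  none_path <- path
  none_path$vanish_lambda <- c(dc_type = 0, stimulus = 0)
  expect_equal(dominant_variable(none_path)$dominant, "none")
})
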