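test_that("effect rescaling divides estimates by their standard errors", {
  fit <- structure(list(beta = c(a = 2, b = -1),
                        se_beta = c(a = 0.5, b = 0.5)),
                   class = "ctx_lmm")
  expect_equal(unname(rescale_effects(fit)), c(4, -2))

  fit$beta[] <- 0
  expect_equal(unname(rescale_effects(fit)), c(0, 0))

  fit$se_beta[1] <- 0
  expect_error(rescale_effects(fit), "degenerate")
})

test_that("score equals mean pairwise distance, with known values", {
  expect_equal(context_dependency_score(c(1, 2, 4, 7)), 20 / 6)
  expect_equal(context_dependency_score(rep(3.2, 5)), 0)
  expect_equal(context_dependency_score(c(-1.3, 2.1)), 3.4)
  expect_error(context_dependency_score(1.5), "fewer than 2")

  set.seed(20)
  for (rep in 1:10) {
    v <- rnorm(sample(2:10, 1), 0, 2)
    s <- context_dependency_score(v)
    expect_equal(s, brute_mean_pairwise(v))
    # invariances: permutation, global sign flip, linear scaling
    expect_equal(context_dependency_score(sample(v)), s)
    expect_equal(context_dependency_score(-v), s)
    expect_equal(context_dependency_score(2.5 * v), 2.5 * s)
  }
})

test_that("dependency classification follows the sign pattern", {
  expect_equal(classify_dependency(c(-0.2, -0.5, -0.1, -0.3)),
               "quantitative")
  expect_equal(classify_dependency(c(0.2, -0.5, 0.1, -0.3)), "qualitative")
  expect_equal(classify_dependency(c(0, 0, 0, -0.5), zero_tol = 1e-9),
               "quantitative")
  expect_error(classify_dependency(0.3), "at least 2")
})

test_that("post-hoc pairwise tests localize the differing context", {
  set.seed(21)
  contexts <- paste0("c", 1:4)
  donors <- sprintf("d%02d", 1:13)
  eff <- expand.grid(donor = donors, context = contexts,
                     stringsAsFactors = FALSE)
  eff$arm <- "A"; eff$analyte <- "IL-X"
  alpha <- rnorm(13, 0, 0.15)
  eff$rel_diff <- alpha[match(eff$donor, donors)] +
    rnorm(nrow(eff), 0, 0.1) + 0.8 * (eff$context == "c1")

  ph <- posthoc_pairwise_tests(eff, "IL-X")
  expect_equal(nrow(ph), choose(4, 2))
  with_a <- ph$context_a == "c1" | ph$context_b == "c1"
  expect_lt(max(ph$p_value[with_a]), min(ph$p_value[!with_a]))

  # identical contexts: no evidence of a difference
  eff2 <- eff[eff$context %in% c("c2", "c3"), ]
  eff2$rel_diff <- rep(alpha, 2)
  ph2 <- posthoc_pairwise_tests(eff2, "IL-X")
  expect_gt(ph2$p_value, 0.95)

  # BH adjustment adds a column without touching raw p
  ph3 <- posthoc_pairwise_tests(eff, "IL-X", adjust = TRUE)
  expect_equal(ph3$p_value, ph$p_value)
  expect_true(all(ph3$p_adjusted >= ph3$p_value - 1e-12))
})

test_that("pairs with too few donors are skipped with a warning", {
  eff <- expand.grid(donor = c("d1", "d2", "d3"), context = c("a", "b"),
                     stringsAsFactors = FALSE)
  eff$arm <- "A"; eff$analyte <- "x"
  eff$rel_diff <- rnorm(6)
  eff <- eff[!(eff$context == "b" & eff$donor != "d1"), ]
  expect_warning(ph <- posthoc_pairwise_tests(eff, "x"), "fewer than 2")
  expect_true(is.na(ph$p_value))
})

test_that("score_all_analytes ranks, classifies and stars analytes", {
  set.seed(22)
  contexts <- paste0("c", 1:4)
  donors <- sprintf("d%02d", 1:13)
  base <- expand.grid(donor = donors, context = contexts,
                      stringsAsFactors = FALSE)
  base$arm <- "A"
  mk <- function(analyte, beta) {
    d <- base
    d$analyte <- analyte
    d$rel_diff <- beta[match(d$context, contexts)] +
      rnorm(13, 0, 0.1)[match(d$donor, donors)] + rnorm(nrow(d), 0, 0.1)
    d
  }
  eff <- rbind(mk("strong", c(0.8, -0.6, 0.2, 0)),
               mk("weak", c(0.05, 0, 0.02, 0.03)),
               mk("null", c(0, 0, 0, 0)))
  res <- score_all_analytes(eff)
  expect_equal(res$analyte[1], "strong")
  expect_equal(res$classification[res$analyte == "strong"], "qualitative")
  expect_equal(res$significance[res$analyte == "strong"], "***")
  expect_equal(res$df, rep(3L, 3))
  expect_true(all(res$score >= 0))
  expect_error(score_all_analytes(eff, alpha_levels = c(0.01, 0.05)),
               "decreasing")
})

test_that("null data yield the nominal number of false positives", {
  set.seed(23)
  counts <- replicate(5, {
    eff <- do.call(rbind, lapply(sprintf("a%02d", 1:20), function(a) {
      d <- expand.grid(donor = sprintf("d%02d", 1:13),
                       context = paste0("c", 1:4),
                       stringsAsFactors = FALSE)
      d$arm <- "A"; d$analyte <- a
      d$rel_diff <- rnorm(13, 0, 0.15)[match(d$donor, unique(d$donor))] +
        rnorm(nrow(d), 0, 0.1)
      d
    }))
    sum(score_all_analytes(eff)$p_value <= 0.05)
  })
  # 20 analytes at alpha 0.05: about one rejection expected per run
  expect_gte(mean(counts), 0.1)
  expect_lte(mean(counts), 3.5)
})

test_that("score ranking tracks the true standardized effect spread", {
  set.seed(24)
  contexts <- paste0("c", 1:4)
  donors <- sprintf("d%02d", 1:50)
  spreads <- seq(0, 1.4, length.out = 8)
  true_beta <- lapply(spreads, function(s) s * c(-0.5, 0, 0.25, 0.5))
  eff <- do.call(rbind, lapply(seq_along(spreads), function(i) {
    d <- expand.grid(donor = donors, context = contexts,
                     stringsAsFactors = FALSE)
    d$arm <- "A"; d$analyte <- sprintf("a%02d", i)
    d$rel_diff <- true_beta[[i]][match(d$context, contexts)] +
      rnorm(50, 0, 0.15)[match(d$donor, donors)] + rnorm(nrow(d), 0, 0.15)
    d
  }))
  res <- score_all_analytes(eff)
  truth <- vapply(true_beta, brute_mean_pairwise, numeric(1))
  names(truth) <- sprintf("a%02d", seq_along(spreads))
  rho <- cor(res$score, truth[res$analyte], method = "spearman")
  expect_gte(rho, 0.9)
})
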