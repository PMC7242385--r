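test_that("design matrices are standardized with the right columns", {
  S <- rep(c(0, 0.45, 0.75, 0.85), each = 7)
  D <- rep(2:8, 4)
  expect_equal(dim(build_design("S", S, D)), c(28, 2))
  expect_equal(dim(build_design("S+D", S, D)), c(28, 3))
  X <- build_design("S+D+SxD", S, D)
  expect_equal(dim(X), c(28, 4))
  expect_equal(unname(colMeans(X[, c("S", "D")])), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(X[, c("S", "D")], 2, sd)), c(1, 1),
               tolerance = 1e-12)
  expect_equal(unname(X[, "SxD"]), unname(X[, "S"] * X[, "D"]))
  # training scaling is reusable for new data
  sc <- attr(X, "scaling")
  X2 <- build_design("S+D+SxD", c(0.45, 0.85), c(2, 8), scaling = sc)
  expect_equal(unname(X2[, "S"]), unname((c(0.45, 0.85) - sc$center["S"]) /
                                           sc$scale["S"]))
  expect_error(build_design("S", rep(1, 12), 1:12), "zero-variance")
})

test_that("WAIC matches a hand-computed oracle and is additive", {
  # 3 draws x 2 observations, worked by hand from the definition
  ll <- matrix(c(-1.0, -1.5, -2.0,
                 -0.5, -0.7, -0.6), nrow = 3)
  lppd_hand <- log(mean(exp(c(-1, -1.5, -2)))) +
    log(mean(exp(c(-0.5, -0.7, -0.6))))
  p_hand <- var(c(-1, -1.5, -2)) + var(c(-0.5, -0.7, -0.6))
  w <- waic(ll)
  expect_equal(w$lppd, lppd_hand, tolerance = 1e-12)
  expect_equal(w$p_waic, p_hand, tolerance = 1e-12)
  expect_equal(w$waic, -2 * (lppd_hand - p_hand), tolerance = 1e-12)
  # degenerate posterior: all draws identical
  ll0 <- matrix(rep(c(-1.3, -0.4), each = 4), nrow = 4)
  w0 <- waic(ll0)
  expect_equal(w0$p_waic, 0)
  expect_equal(w0$waic, -2 * (-1.3 - 0.4))
  # duplicating observations doubles both components
  w2 <- waic(cbind(ll, ll))
  expect_equal(w2$lppd, 2 * w$lppd)
  expect_equal(w2$p_waic, 2 * w$p_waic)
  expect_error(waic(matrix(c(1, NA), 1)), "non-finite")
})

test_that("split R-hat detects convergence and its failure", {
  set.seed(10)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(abs(rhat(good) - 1), 0.01)
  bad <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(rhat(bad), 1.5)
  # a within-chain trend is caught by splitting
  trend <- matrix(rep(seq(0, 5, length.out = 500), 4), ncol = 4)
  expect_gt(rhat(trend), 1.05)
  perm <- good[, c(3, 1, 4, 2)]
  expect_equal(rhat(perm), rhat(good), tolerance = 1e-12)
  expect_error(rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("the Gibbs sampler recovers a strong linear signal", {
  set.seed(2)
  S <- rep(c(0, 0.45, 0.75, 0.85), each = 35)
  D <- rep(rep(2:8, each = 5), 4)
  X <- build_design("S", S, D)
  y <- 2 + 1 * X[, "S"] + rnorm(length(S), 0, 0.01)
  fit <- fit_bayes_lm(y, X, seed = 31)
  cs <- coef_summary(fit)
  expect_lt(abs(cs$mean[cs$coef == "S"] - 1), 3 * cs$sd[cs$coef == "S"])
  expect_lt(abs(cs$mean[cs$coef == "(Intercept)"] - 2),
            3 * cs$sd[cs$coef == "(Intercept)"])
  expect_true(all(fit$rhat < 1.05))
  # posterior matches the exact conjugate solution at fixed prior scale
  tau2 <- fit$prior_scale^2
  s2 <- mean(fit$sigma^2)
  V <- solve(crossprod(X) / s2 + diag(1 / tau2, 2))
  expect_equal(unname(colMeans(fit$beta)),
               unname(as.numeric(V %*% crossprod(X, y) / s2)),
               tolerance = 1e-3)
  # a vanishing prior scale pins the posterior at the prior mean
  fit0 <- fit_bayes_lm(y, X, prior_scale = 1e-6, seed = 31)
  expect_lt(max(abs(colMeans(fit0$beta))), 1e-4)
  # determinism
  fit2 <- fit_bayes_lm(y, X, seed = 31)
  expect_identical(fit$beta, fit2$beta)
  expect_identical(fit$sigma, fit2$sigma)
})

test_that("model comparison weights are coherent and favour the truth", {
  d <- suppressMessages(generate_synthetic_rii(
    c("(Intercept)" = -0.1, S = 0.1, D = -0.15, SxD = 0.2),
    noise = 0.05, seed = 21))
  cmp <- compare_models(d, seed = 22)
  expect_equal(sum(cmp$table$weight), 1)
  expect_true(all(cmp$table$weight >= 0))
  expect_equal(cmp$table$delta[1], 0)
  expect_equal(cmp$best, "S+D+SxD")
  expect_true(all(cmp$table$max_rhat < 1.05))
  # with no density effect, the stress-only model is competitive
  d2 <- suppressMessages(generate_synthetic_rii(
    c("(Intercept)" = -0.1, S = 0.2), noise = 0.05, seed = 23))
  cmp2 <- compare_models(d2, models = c("S", "S+D"), seed = 24)
  expect_lt(cmp2$table$waic[cmp2$table$model == "S"] -
              min(cmp2$table$waic), 2)
})

test_that("model averaging tracks the best model with wider intervals", {
  d <- suppressMessages(generate_synthetic_rii(noise = 0.05, seed = 31))
  cmp <- compare_models(d, seed = 32)
  grid <- expand.grid(stress = c(0, 0.85), density = c(2, 8))
  set.seed(1)
  avg <- model_average(cmp, grid)
  best <- cmp$fits[[cmp$best]]
  eta <- zoifacil:::predict_eta(best, cmp$best, grid$stress, grid$density)
  expect_equal(avg$estimate, colMeans(eta), tolerance = 0.02)
  expect_true(all(avg$upper > avg$lower))
  # predictive intervals are wider than mean intervals
  set.seed(1)
  pred <- model_average(cmp, grid, type = "predictive")
  expect_true(all(pred$upper - pred$lower > avg$upper - avg$lower))
})
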