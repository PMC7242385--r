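#' Candidate model ids
#'
#' The four candidate linear models of RII: stress only (`"S"`, classical
#' stress-gradient reasoning), density only (`"D"`, classical competition
#' theory), additive (`"S+D"`, the curve merely moves upward with stress)
#' and the full interaction model (`"S+D+SxD"`, density-dependence of the
#' stress response).
#'
#' @return Character vector of model ids.
#' @export
candidate_models <- function() c("S", "D", "S+D", "S+D+SxD")

#' Build a design matrix for a candidate model
#'
#' Predictors are centred and scaled to unit standard deviation before
#' the product term is formed; the intercept is always included.
#'
#' @param model One of [candidate_models()].
#' @param stress,density Equal-length predictor vectors.
#' @param scaling Optional list with `center` and `scale` (each named
#'   `S`, `D`) from a previous call, to place new data on the training
#'   scale.
#' @return Numeric matrix with an attribute `scaling`.
#' @export
build_design <- function(model, stress, density, scaling = NULL) {
  model <- match.arg(model, candidate_models())
  if (length(stress) != length(density))
    stop("stress and density must have equal length")
  if (is.null(scaling)) {
    scaling <- list(center = c(S = mean(stress), D = mean(density)),
                    scale = c(S = sd(stress), D = sd(density)))
  }
  if (any(scaling$scale == 0) || any(is.na(scaling$scale)))
    stop("zero-variance predictor")
  sS <- (stress - scaling$center["S"]) / scaling$scale["S"]
  sD <- (density - scaling$center["D"]) / scaling$scale["D"]
  X <- switch(model,
    "S" = cbind("(Intercept)" = 1, S = sS),
    "D" = cbind("(Intercept)" = 1, D = sD),
    "S+D" = cbind("(Intercept)" = 1, S = sS, D = sD),
    "S+D+SxD" = cbind("(Intercept)" = 1, S = sS, D = sD, SxD = sS * sD))
  rownames(X) <- NULL
  attr(X, "scaling") <- scaling
  X
}

#' Fit a Bayesian Gaussian linear model by Gibbs sampling
#'
#' Gaussian likelihood with weakly informative priors: coefficients
#' `N(0, prior_scale^2)` (weak on the RII scale once predictors are
#' standardized) and a half-Gaussian prior of scale `sigma_prior_scale`
#' on the residual standard deviation. Coefficients are updated from
#' their exact conjugate conditional; the residual scale by slice
#' sampling. Draws are deterministic under `seed`.
#'
#' @param y Response vector.
#' @param X Design matrix (from [build_design()]).
#' @param prior_scale Prior SD of the coefficients.
#' @param sigma_prior_scale Scale of the half-Gaussian prior on sigma.
#' @param chains Number of chains (default 4).
#' @param iter Post-warmup draws per chain (default 5000, i.e. 20000
#'   total); warmup of the same length is discarded.
#' @param seed Integer seed.
#' @return Object of class `zoi_fit`: `beta` (total draws x k), `sigma`,
#'   `chain` index, `rhat` per parameter, pointwise `loglik`
#'   (draws x observations), the inputs and prior settings.
#' @export
fit_bayes_lm <- function(y, X, prior_scale = 10, sigma_prior_scale = 10,
                         chains = 4L, iter = 5000L, seed = 1L) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (length(y) < 10) stop("need at least 10 observations")
  if (prior_scale <= 0 || sigma_prior_scale <= 0) stop("prior scales must be > 0")
  if (chains < 1L || iter < 2L) stop("invalid MCMC settings")
  n <- length(y); k <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  ols <- tryCatch(solve(XtX, Xty), error = function(e) matrix(0, k, 1))
  sd0 <- max(sd(y - X %*% ols), 1e-3)

  set.seed(seed)
  sam <- gibbs_lm_cpp(XtX, as.numeric(Xty), yty, n, prior_scale,
                      sigma_prior_scale, chains, iter,
                      as.numeric(ols), log(sd0))
  beta_all <- sam$beta
  colnames(beta_all) <- colnames(X)
  sigma_all <- as.numeric(sam$sigma)
  chain_id <- rep(seq_len(chains), each = iter)
  draws <- cbind(beta_all, sigma = sigma_all)
  rh <- apply(draws, 2, function(v)
    rhat(matrix(v, nrow = iter, ncol = chains)))
  # pointwise log-likelihood, draws x observations
  eta <- beta_all %*% t(X)
  ll <- -log(sigma_all) - 0.5 * log(2 * pi) -
    (sweep(-eta, 2, y, "+"))^2 / (2 * sigma_all^2)
  structure(list(beta = beta_all, sigma = sigma_all, chain = chain_id,
                 rhat = rh, loglik = ll, y = y, X = X,
                 scaling = attr(X, "scaling"),
                 prior_scale = prior_scale,
                 sigma_prior_scale = sigma_prior_scale,
                 chains = chains, iter = iter, seed = seed),
            class = "zoi_fit")
}

#' @export
print.zoi_fit <- function(x, ...) {
  cat(sprintf("<zoi_fit> %d coefficients, %d draws (%d chains), max R-hat %.3f\n",
              ncol(x$beta), nrow(x$beta), x$chains, max(x$rhat)))
  print(coef_summary(x))
  invisible(x)
}

#' Posterior coefficient summary
#'
#' @param fit A [fit_bayes_lm()] result.
#' @param prob Credible-interval mass (default 0.95).
#' @return Data frame `coef`, `mean`, `sd`, `lower`, `upper`, `rhat`.
#' @export
coef_summary <- function(fit, prob = 0.95) {
  a <- (1 - prob) / 2
  d <- cbind(fit$beta, sigma = fit$sigma)
  data.frame(coef = colnames(d),
             mean = colMeans(d),
             sd = apply(d, 2, sd),
             lower = apply(d, 2, quantile, probs = a),
             upper = apply(d, 2, quantile, probs = 1 - a),
             rhat = fit$rhat, row.names = NULL)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half, between- and within-chain variances are
#' pooled, and `sqrt(var_plus / W)` returned. Values near 1 indicate
#' convergence; the analysis threshold is 1.05.
#'
#' @param draws Matrix of posterior draws, iterations x chains.
#' @return Scalar R-hat.
#' @export
rhat <- function(draws) {
  stopifnot(is.matrix(draws))
  if (ncol(draws) < 2) stop("need at least 2 chains")
  if (nrow(draws) < 4) stop("need at least 4 draws per chain")
  half <- floor(nrow(draws) / 2)
  split_mat <- cbind(draws[seq_len(half), , drop = FALSE],
                     draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(split_mat); n <- nrow(split_mat)
  mu <- colMeans(split_mat)
  W <- mean(apply(split_mat, 2, var))
  B <- n * var(mu)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Watanabe-Akaike information criterion
#'
#' `lppd = sum_i log mean_d exp(loglik[d, i])`,
#' `p_waic = sum_i var_d(loglik[d, i])`, `waic = -2 (lppd - p_waic)`.
#' Smaller WAIC indicates better expected predictive fit.
#'
#' @param loglik Pointwise log-likelihood matrix, draws x observations.
#' @return List `lppd`, `p_waic`, `waic`.
#' @export
waic <- function(loglik) {
  stopifnot(is.matrix(loglik))
  if (!all(is.finite(loglik))) stop("non-finite log-likelihood entries")
  mx <- apply(loglik, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2, mx)))))
  p_waic <- sum(apply(loglik, 2, var))
  list(lppd = lppd, p_waic = p_waic, waic = -2 * (lppd - p_waic))
}

#' Fit and compare the four candidate models by WAIC
#'
#' Fits every candidate on the same RII records, computes WAIC, delta
#' WAIC and Akaike-type weights `w_k = exp(-delta_k / 2)` (normalised).
#' Comparison proceeds even if a fit has R-hat >= 1.05, with a prominent
#' warning.
#'
#' @param records Data frame with columns `RII`, `stress`, `density`
#'   (rows with missing RII are dropped).
#' @param models Model ids (default all four candidates).
#' @param seed Integer seed (one per-model seed is derived from it).
#' @param ... Passed to [fit_bayes_lm()].
#' @return Object of class `zoi_model_comparison`: `table` (model, waic,
#'   lppd, p_waic, delta, weight, max_rhat), `fits`, `best`.
#' @export
compare_models <- function(records, models = candidate_models(), seed = 1L,
                           ...) {
  keep <- !is.na(records$RII)
  records <- records[keep, , drop = FALSE]
  y <- records$RII
  fits <- lapply(seq_along(models), function(i) {
    X <- build_design(models[i], records$stress, records$density)
    fit_bayes_lm(y, X, seed = derive_seed(seed, 900 + i), ...)
  })
  names(fits) <- models
  w <- lapply(fits, function(f) waic(f$loglik))
  tab <- data.frame(model = models,
                    waic = vapply(w, `[[`, numeric(1), "waic"),
                    lppd = vapply(w, `[[`, numeric(1), "lppd"),
                    p_waic = vapply(w, `[[`, numeric(1), "p_waic"),
                    max_rhat = vapply(fits, function(f) max(f$rhat),
                                      numeric(1)))
  tab$delta <- tab$waic - min(tab$waic)
  wt <- exp(-tab$delta / 2)
  tab$weight <- wt / sum(wt)
  tab <- tab[order(tab$waic), , drop = FALSE]
  rownames(tab) <- NULL
  if (any(tab$max_rhat >= 1.05))
    warning("one or more fits did not converge (R-hat >= 1.05); ",
            "interpret the comparison with caution")
  structure(list(table = tab, fits = fits, best = tab$model[1],
                 records = records),
            class = "zoi_model_comparison")
}

#' @export
print.zoi_model_comparison <- function(x, ...) {
  cat("<zoi_model_comparison> best model:", x$best, "\n")
  print(x$table[, c("model", "waic", "delta", "weight", "max_rhat")],
        digits = 4)
  invisible(x)
}

# Linear predictor draws for new data on the training scale.
predict_eta <- function(fit, model, stress, density) {
  X <- build_design(model, stress, density, scaling = fit$scaling)
  fit$beta %*% t(X)
}

#' Model-averaged predictions with credible sets
#'
#' Mixes posterior draws of the linear predictor across candidate models
#' in proportion to their WAIC weights and summarises the mixture. The
#' averaged estimate tracks the best model but its credible sets are
#' wider, reflecting model-selection uncertainty.
#'
#' @param comparison A [compare_models()] result.
#' @param newdata Data frame with `stress` and `density`; defaults to the
#'   grid of values seen in the records.
#' @param prob Credible mass (default 0.95).
#' @param type `"mean"` for the posterior of the regression surface,
#'   `"predictive"` to add residual noise.
#' @return `newdata` with `estimate`, `lower`, `upper` columns.
#' @export
model_average <- function(comparison, newdata = NULL, prob = 0.95,
                          type = c("mean", "predictive")) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    r <- comparison$records
    newdata <- expand.grid(stress = sort(unique(r$stress)),
                           density = sort(unique(r$density)))
  }
  a <- (1 - prob) / 2
  tab <- comparison$table
  est <- matrix(0, nrow(newdata), 3)
  # draws from each model, weighted by stacking the weighted subsample
  mixed <- NULL
  for (i in seq_len(nrow(tab))) {
    fit <- comparison$fits[[tab$model[i]]]
    n_take <- round(tab$weight[i] * nrow(fit$beta))
    if (n_take < 1) next
    idx <- unique(round(seq(1, nrow(fit$beta), length.out = n_take)))
    eta <- predict_eta(fit, tab$model[i], newdata$stress,
                       newdata$density)[idx, , drop = FALSE]
    if (type == "predictive")
      eta <- eta + rnorm(length(eta), 0, rep(fit$sigma[idx], ncol(eta)))
    mixed <- rbind(mixed, eta)
  }
  newdata$estimate <- colMeans(mixed)
  newdata$lower <- apply(mixed, 2, quantile, probs = a)
  newdata$upper <- apply(mixed, 2, quantile, probs = 1 - a)
  newdata
}
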