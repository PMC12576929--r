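test_that("beta GLMM recovers generating subset means", {
  errs <- sapply(1:2, function(seed) {
    d <- sim_beta_glmm(seed)
    f <- fit_beta_glmm(d)
    expect_true(f$converged)
    m <- setNames(f$subset_means$estimate, f$subset_means$subset)
    abs(m[c("sample", "resting", "foraging", "transiting")] -
          c(0.86, 0.9, 0.9, 0.4))
  })
  expect_true(all(errs < 0.03))
})

test_that("beta GLMM agrees with an independent mixed-model fit", {
  d <- sim_beta_glmm(7)
  f <- fit_beta_glmm(d)
  g <- glmmTMB::glmmTMB(
    x_transformed ~ stats::relevel(factor(subset), "sample") +
      (1 | colony_id),
    data = d, family = glmmTMB::beta_family())
  expect_equal(unname(glmmTMB::fixef(g)$cond), f$coefficients$estimate,
               tolerance = 1e-3)
  expect_equal(unname(stats::sigma(g)), f$phi, tolerance = 1e-3)
})

test_that("zero-variance groups reduce to a fixed-effects-only beta
           regression", {
  # balanced groups, no group effect in the generating process
  d <- sim_beta_glmm(3, n_col = 6, n_ind = 12, sd_col = 0)
  f <- fit_beta_glmm(d)
  # independent oracle: fixed-effects-only beta ML fit written here
  y <- d$x_transformed
  X <- model.matrix(~stats::relevel(factor(d$subset), "sample"))
  nll <- function(th) {
    mu <- pmin(pmax(plogis(drop(X %*% th[1:4])), 1e-12), 1 - 1e-12)
    phi <- exp(th[5])
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
  }
  o <- optim(c(qlogis(mean(y)), 0, 0, 0, log(10)), nll, method = "BFGS",
             control = list(maxit = 500, reltol = 1e-12))
  expect_equal(f$coefficients$estimate, o$par[1:4], tolerance = 1e-3)
  expect_lt(f$sigma_group, 0.05)
})

test_that("logit link maps coefficients to means as expected", {
  d <- sim_beta_glmm(9, n_col = 4, n_ind = 8)
  f <- fit_beta_glmm(d)
  b <- f$coefficients$estimate
  ref_mean <- f$subset_means$estimate[f$subset_means$subset == "sample"]
  expect_equal(ref_mean, plogis(b[1]), tolerance = 1e-12)
})

test_that("quadrature is converged at the default node count", {
  d <- sim_beta_glmm(11, n_col = 8, n_ind = 6)
  f9 <- fit_beta_glmm(d, n_nodes = 9)
  f31 <- fit_beta_glmm(d, n_nodes = 31)
  expect_lt(max(abs(f9$coefficients$estimate -
                      f31$coefficients$estimate)), 1e-3)
})

test_that("LMM recovers generating offsets and matches lme4", {
  errs <- sapply(1:10, function(seed) {
    d <- sim_lmm(seed)
    f <- fit_lmm(d)
    est <- setNames(f$coefficients$estimate, f$coefficients$term)
    abs(est[c("resting", "foraging", "transiting", "sample")] -
          c(-0.48, -0.16, 0.28, -0.02))
  })
  expect_true(all(errs < 0.25))          # per-seed sampling error
  expect_true(all(rowMeans(errs) < 0.08))  # estimator is unbiased

  d <- sim_lmm(21)
  f <- fit_lmm(d)
  g <- lme4::lmer(log10_area ~ stats::relevel(factor(subset), "all") +
                    (1 | colony_id), data = d, REML = FALSE)
  expect_equal(unname(lme4::fixef(g)), f$coefficients$estimate,
               tolerance = 1e-5)
  expect_equal(unname(stats::sigma(g)), f$sigma_resid, tolerance = 1e-4)
})

test_that("degenerate LMM equals ordinary least squares and the R2
           identities hold", {
  # responses with no colony structure at all
  set.seed(31)
  d <- sim_lmm(31, sd_col = 0)
  f0 <- fit_lmm(d, lambda_fixed = 0)
  X <- model.matrix(~stats::relevel(factor(d$subset), "all"))
  ols <- solve(crossprod(X), crossprod(X, d$log10_area))
  expect_equal(f0$coefficients$estimate, as.numeric(ols),
               tolerance = 1e-8)
  # the freely profiled fit lands in the same place on such data
  f <- fit_lmm(d)
  expect_equal(f$coefficients$estimate, as.numeric(ols),
               tolerance = 1e-4)

  # the fitted object's variance components satisfy the Nakagawa
  # R2 identities (marginal = var_f / total, conditional adds var_b)
  fitted_fixed <- drop(X %*% f$coefficients$estimate)
  vf <- mean((fitted_fixed - mean(fitted_fixed))^2)
  den <- vf + f$sigma_group^2 + f$sigma_resid^2
  expect_equal(f$r2_marginal, vf / den, tolerance = 1e-10)
  expect_equal(f$r2_conditional, (vf + f$sigma_group^2) / den,
               tolerance = 1e-10)
  expect_gte(f$r2_conditional, f$r2_marginal)
})

test_that("LMM fixed effects are shift-equivariant only through the
           intercept", {
  d <- sim_lmm(41)
  f0 <- fit_lmm(d)
  d2 <- d; d2$log10_area <- d2$log10_area + 3
  f1 <- fit_lmm(d2)
  expect_equal(f1$coefficients$estimate[1],
               f0$coefficients$estimate[1] + 3, tolerance = 1e-8)
  expect_equal(f1$coefficients$estimate[-1],
               f0$coefficients$estimate[-1], tolerance = 1e-8)
})
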