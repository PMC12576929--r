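#' Mixed-effects beta regression on capture proportions
#'
#' Beta likelihood with a logit link for the mean and a common precision
#' phi, a Gaussian random intercept per group (colony), maximum
#' likelihood with the random effect integrated out by adaptive
#' Gauss-Hermite quadrature. Written for transformed capture
#' proportions strictly inside (0, 1) (see [transform_proportion()]).
#'
#' @param data `data.frame` with the response and predictors.
#' @param response Name of the (0,1) response column (default
#'   `"x_transformed"`).
#' @param subset_col Name of the behaviour-subset factor column.
#' @param group_col Name of the random-intercept grouping column
#'   (default `"colony_id"`).
#' @param reference Reference level of the subset factor (default
#'   `"sample"`, so behaviours are contrasted against the subsample
#'   control).
#' @param n_nodes Gauss-Hermite nodes (default 15, minimum 9).
#' @param mean_type Report subset means conditional on a zero random
#'   effect (default) or marginal / population-averaged.
#' @return List of class `bk_beta_glmm`: `coefficients` (logit scale,
#'   with SE and Wald 95% CI), `phi`, `sigma_group`, `subset_means`
#'   (response scale with CI), `loglik`, `converged`.
#' @export
fit_beta_glmm <- function(data, response = "x_transformed",
                          subset_col = "subset", group_col = "colony_id",
                          reference = "sample", n_nodes = 15,
                          mean_type = c("conditional", "marginal")) {
  mean_type <- match.arg(mean_type)
  stopifnot(n_nodes >= 9)
  y <- data[[response]]
  if (any(y <= 0 | y >= 1)) {
    stop("response must be strictly inside (0, 1); ",
         "apply transform_proportion() first", call. = FALSE)
  }
  f <- factor(data[[subset_col]])
  if (reference %in% levels(f)) f <- stats::relevel(f, ref = reference)
  X <- model.matrix(~f)
  colnames(X) <- sub("^f", "", colnames(X))
  g <- factor(data[[group_col]])
  if (nlevels(g) < 2) stop("need >= 2 groups for the random effect",
                           call. = FALSE)
  groups <- split(seq_along(y), g)
  gh <- pracma::gaussHermite(n_nodes)
  p <- ncol(X)

  cond_ll <- function(yy, eta) {
    # beta log density written out so extreme linear predictors explored
    # by the optimiser degrade gracefully instead of producing NaN
    mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    a <- mu * exp_phi; b <- (1 - mu) * exp_phi
    lgamma(a + b) - lgamma(a) - lgamma(b) +
      (a - 1) * log(yy) + (b - 1) * log1p(-yy)
  }
  exp_phi <- NA  # bound inside negll for speed

  negll <- function(theta) {
    beta <- theta[1:p]
    exp_phi <<- exp(theta[p + 1])
    sigma <- exp(theta[p + 2])
    eta0 <- drop(X %*% beta)
    total <- 0
    for (idx in groups) {
      yy <- y[idx]; e0 <- eta0[idx]
      fb <- function(b) {
        sum(cond_ll(yy, e0 + b)) + stats::dnorm(b, 0, sigma, log = TRUE)
      }
      opt <- optimize(function(b) -fb(b), c(-8, 8))
      bhat <- opt$minimum
      hstep <- 1e-4
      d2 <- (fb(bhat + hstep) - 2 * fb(bhat) + fb(bhat - hstep)) / hstep^2
      shat <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else sigma
      nodes <- bhat + sqrt(2) * shat * gh$x
      lv <- vapply(nodes, fb, numeric(1)) + gh$x^2 + log(gh$w)
      m <- max(lv)
      total <- total + m + log(sum(exp(lv - m))) + log(sqrt(2) * shat)
    }
    if (!is.finite(total)) 1e10 else -total
  }

  # starting values from a naive logit-scale linear model
  beta0 <- stats::coef(stats::lm(qlogis(y) ~ X - 1))
  theta0 <- c(beta0, log(10), log(0.3))
  opt <- optim(theta0, negll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  opt$par <- unname(opt$par)
  se <- rep(NA_real_, length(opt$par))
  vc <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(vc, "try-error") && all(diag(vc) > 0)) se <- sqrt(diag(vc))
  beta <- opt$par[1:p]
  coefs <- data.frame(
    term = colnames(X), estimate = beta, se = se[1:p],
    ci_lo = beta - 1.96 * se[1:p], ci_hi = beta + 1.96 * se[1:p],
    stringsAsFactors = FALSE)
  sigma <- exp(opt$par[p + 2])

  # per-subset means on the response scale
  lev <- levels(f)
  Xs <- model.matrix(~factor(lev, levels = lev))
  eta_s <- drop(Xs %*% beta)
  if (!inherits(vc, "try-error")) {
    v_eta <- diag(Xs %*% vc[1:p, 1:p, drop = FALSE] %*% t(Xs))
  } else v_eta <- rep(NA_real_, length(eta_s))
  to_mean <- function(e) {
    if (mean_type == "conditional") return(plogis(e))
    # marginal: average the inverse link over the random-effect law
    nodes <- sqrt(2) * sigma * gh$x
    vapply(e, function(ei) sum(gh$w * plogis(ei + nodes)) / sqrt(pi),
           numeric(1))
  }
  subset_means <- data.frame(
    subset = lev,
    estimate = to_mean(eta_s),
    ci_lo = to_mean(eta_s - 1.96 * sqrt(v_eta)),
    ci_hi = to_mean(eta_s + 1.96 * sqrt(v_eta)),
    stringsAsFactors = FALSE)

  out <- list(coefficients = coefs, phi = exp(opt$par[p + 1]),
              sigma_group = sigma, subset_means = subset_means,
              loglik = -opt$value, converged = opt$convergence == 0,
              mean_type = mean_type, n_nodes = n_nodes,
              reference = reference, n = length(y))
  if (sigma < 1e-4) out$note <- "random-intercept sd is essentially zero"
  class(out) <- "bk_beta_glmm"
  out
}

#' Linear mixed model on log10 key-area sizes
#'
#' Gaussian linear mixed model with behaviour subset as the fixed
#' effect (baseline: all-behaviour) and a colony random intercept,
#' fitted by maximum likelihood with the variance ratio profiled out by
#' one-dimensional optimisation. Reports Wald 95% CIs and Nakagawa
#' marginal/conditional R-squared.
#'
#' @param data `data.frame` with the response and predictors.
#' @param response Response column name (default `"log10_area"`).
#' @param subset_col Fixed-effect factor column (default `"subset"`).
#' @param group_col Random-intercept grouping column (default
#'   `"colony_id"`).
#' @param reference Baseline level (default `"all"`).
#' @param lambda_fixed Optionally fix the variance ratio
#'   sigma_b^2 / sigma_e^2 instead of profiling it (0 forces a
#'   no-random-effect fit, which reduces to ordinary least squares).
#' @return List of class `bk_lmm`: `coefficients`, `sigma_group`,
#'   `sigma_resid`, `r2_marginal`, `r2_conditional`, `loglik`.
#' @export
fit_lmm <- function(data, response = "log10_area", subset_col = "subset",
                    group_col = "colony_id", reference = "all",
                    lambda_fixed = NULL) {
  y <- data[[response]]
  f <- factor(data[[subset_col]])
  if (reference %in% levels(f)) f <- stats::relevel(f, ref = reference)
  X <- model.matrix(~f)
  colnames(X) <- sub("^f", "", colnames(X))
  g <- factor(data[[group_col]])
  if (nlevels(g) < 2) stop("need >= 2 colonies", call. = FALSE)
  groups <- split(seq_along(y), g)
  n <- length(y); p <- ncol(X)

  # profiled ML: for variance ratio lambda = sigma_b^2 / sigma_e^2,
  # V_g = I + lambda J; V^-1 and log|V| are closed-form per block
  profile_fit <- function(log_lambda) {
    lambda <- exp(log_lambda)
    XtVX <- matrix(0, p, p); XtVy <- numeric(p)
    logdet <- 0
    for (idx in groups) {
      ng <- length(idx)
      Xg <- X[idx, , drop = FALSE]; yg <- y[idx]
      cshr <- lambda / (1 + lambda * ng)
      sx <- colSums(Xg); sy <- sum(yg)
      XtVX <- XtVX + crossprod(Xg) - cshr * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xg, yg) - cshr * sx * sy
      logdet <- logdet + log(1 + lambda * ng)
    }
    beta <- solve(XtVX, XtVy)
    # weighted RSS r' V^-1 r
    rss <- 0
    for (idx in groups) {
      rg <- y[idx] - drop(X[idx, , drop = FALSE] %*% beta)
      cshr <- lambda / (1 + lambda * length(idx))
      rss <- rss + sum(rg^2) - cshr * sum(rg)^2
    }
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
    list(ll = ll, beta = beta, sigma2 = sigma2, lambda = lambda,
         XtVX = XtVX)
  }
  if (is.null(lambda_fixed)) {
    opt <- optimize(function(l) -profile_fit(l)$ll, c(-12, 12))
    fit <- profile_fit(opt$minimum)
  } else {
    fit <- profile_fit(log(max(lambda_fixed, 0) + 1e-300))
    if (lambda_fixed == 0) fit$lambda <- 0
  }
  vc <- solve(fit$XtVX) * fit$sigma2
  se <- sqrt(diag(vc))
  coefs <- data.frame(
    term = colnames(X), estimate = as.numeric(fit$beta), se = se,
    ci_lo = as.numeric(fit$beta) - 1.96 * se,
    ci_hi = as.numeric(fit$beta) + 1.96 * se,
    stringsAsFactors = FALSE)
  var_rand <- fit$lambda * fit$sigma2
  var_resid <- fit$sigma2
  fitted_fixed <- drop(X %*% fit$beta)
  var_fixed <- mean((fitted_fixed - mean(fitted_fixed))^2)
  denom <- var_fixed + var_rand + var_resid
  out <- list(coefficients = coefs,
              sigma_group = sqrt(var_rand), sigma_resid = sqrt(var_resid),
              r2_marginal = var_fixed / denom,
              r2_conditional = (var_fixed + var_rand) / denom,
              loglik = fit$ll, reference = reference, n = n)
  class(out) <- "bk_lmm"
  out
}
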