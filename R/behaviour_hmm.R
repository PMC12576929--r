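#' Construct a 3-state step/turn HMM parameter set
#'
#' States are ordered by ascending step mean and named resting,
#' foraging, transiting. Step lengths follow a gamma distribution
#' parameterised by mean and sd (km); turning angles follow a von Mises
#' distribution with mean direction mu (radians) and concentration
#' kappa. An optional per-state zero mass handles exactly-zero steps
#' from stationary GPS fixes, which have no density under a gamma.
#'
#' @param step_mean,step_sd,turn_mu,turn_kappa Numeric length-3 vectors.
#' @param Gamma 3x3 row-stochastic transition matrix.
#' @param delta Initial state distribution (default: stationary
#'   distribution of `Gamma`).
#' @param zero_mass Optional length-3 vector of P(step == 0) per state.
#' @return A list of class `bk_hmm_params`.
#' @export
hmm_params <- function(step_mean, step_sd, turn_mu, turn_kappa,
                       Gamma, delta = NULL, zero_mass = NULL) {
  stopifnot(length(step_mean) == 3, length(step_sd) == 3,
            length(turn_mu) == 3, length(turn_kappa) == 3,
            all(step_mean > 0), all(step_sd > 0), all(turn_kappa >= 0),
            is.matrix(Gamma), all(dim(Gamma) == 3),
            max(abs(rowSums(Gamma) - 1)) < 1e-8)
  if (is.null(delta)) delta <- stationary_distribution(Gamma)
  stopifnot(abs(sum(delta) - 1) < 1e-8)
  p <- list(step_mean = step_mean, step_sd = step_sd,
            turn_mu = wrap_angle(turn_mu), turn_kappa = turn_kappa,
            Gamma = Gamma, delta = as.numeric(delta),
            zero_mass = zero_mass)
  class(p) <- "bk_hmm_params"
  p
}

#' Default HMM parameters
#'
#' The colony-weighted grand-mean estimates for breeding kittiwakes
#' (resting / foraging / transiting), used both as the synthetic
#' generator's truth and as default fitting initial values. These can
#' and should be overridden for other species.
#' @export
default_hmm_params <- function() {
  pi0 <- c(0.23, 0.48, 0.29)
  hmm_params(
    step_mean = c(0.07, 0.23, 0.98),
    step_sd = c(0.04, 0.26, 0.32),
    turn_mu = c(0.00, 0.03, 0.00),
    turn_kappa = c(10.77, 0.34, 9.84),
    Gamma = build_transition_matrix(pi0, 0.1),
    delta = pi0
  )
}

#' Steps and turning angles of a projected track
#'
#' Step t is the planar distance from fix t to t+1 (km); turn t is the
#' signed heading change at fix t+1, wrapped to (-pi, pi]. The first
#' step has no defined turn (NA).
#'
#' @param trip `data.frame` with projected `x`, `y` columns (>= 3 rows).
#' @return List with `steps` (length T-1) and `turns` (length T-1, first
#'   element NA), aligned so observation i = (steps[i], turns[i]).
#' @export
steps_and_turns <- function(trip) {
  if (nrow(trip) < 3) stop("need >= 3 fixes for steps and turns",
                           call. = FALSE)
  dx <- diff(trip$x); dy <- diff(trip$y)
  steps <- sqrt(dx^2 + dy^2)
  headings <- atan2(dy, dx)
  turns <- c(NA_real_, wrap_angle(diff(headings)))
  list(steps = steps, turns = turns)
}

#' Build step/turn series from a fix stream, splitting on gaps
#'
#' Temporal gaps larger than `gap_factor` times the nominal sampling
#' interval break the stream into independent series so a long gap is
#' never treated as one 100-s step.
#'
#' @param fixes Projected fixes with `x`, `y`, `timestamp`.
#' @param interval_s Nominal interval; default the median time diff.
#' @param gap_factor Gap threshold multiplier (default 3); `Inf`
#'   disables splitting.
#' @return List of step/turn series (each as in [steps_and_turns()]).
#' @export
series_from_fixes <- function(fixes, interval_s = NULL, gap_factor = 3) {
  dt <- diff(as.numeric(fixes$timestamp))
  if (is.null(interval_s)) interval_s <- median(dt)
  brk <- which(dt > gap_factor * interval_s)
  starts <- c(1, brk + 1)
  ends <- c(brk, nrow(fixes))
  out <- list()
  for (k in seq_along(starts)) {
    if (ends[k] - starts[k] + 1 >= 3) {
      out[[length(out) + 1]] <-
        steps_and_turns(fixes[starts[k]:ends[k], , drop = FALSE])
    }
  }
  out
}

#' State emission density
#'
#' Product of the gamma step-length density (mean/sd converted to
#' shape = (mean/sd)^2, rate = mean/sd^2) and the von Mises
#' turning-angle density. A missing turn contributes the gamma factor
#' only. If the parameter set carries a zero mass, a zero step
#' contributes that mass instead of the (undefined) gamma density.
#'
#' @param params `bk_hmm_params`.
#' @param state State index 1..3 or name.
#' @param step Step length(s), km.
#' @param turn Turning angle(s), radians, may be NA.
#' @param log Return log density?
#' @export
emission_density <- function(params, state, step, turn = NA, log = FALSE) {
  if (is.character(state)) state <- match(state, .state_names)
  if (any(step < 0)) stop("negative step length", call. = FALSE)
  shape <- (params$step_mean[state] / params$step_sd[state])^2
  rate <- params$step_mean[state] / params$step_sd[state]^2
  z <- if (is.null(params$zero_mass)) 0 else params$zero_mass[state]
  ld <- ifelse(step == 0 & z > 0, log(z),
               log1p(-z) + dgamma(step, shape = shape, rate = rate,
                                  log = TRUE))
  lt <- ifelse(is.na(turn), 0,
               dvonmises(ifelse(is.na(turn), 0, turn),
                         params$turn_mu[state], params$turn_kappa[state],
                         log = TRUE))
  out <- ld + lt
  if (log) out else exp(out)
}

# T x 3 matrix of log emission densities for one series
.log_emission_matrix <- function(params, series) {
  n <- length(series$steps)
  m <- matrix(0, n, 3)
  for (s in 1:3) {
    m[, s] <- emission_density(params, s, series$steps, series$turns,
                               log = TRUE)
  }
  m
}

#' HMM log-likelihood
#'
#' Scaled forward algorithm summed over independent series.
#'
#' @param params `bk_hmm_params`.
#' @param series_list List of step/turn series.
#' @export
hmm_loglik <- function(params, series_list) {
  if (!length(series_list)) stop("no series supplied", call. = FALSE)
  ll <- 0
  for (k in seq_along(series_list)) {
    ser <- series_list[[k]]
    if (any(!is.finite(ser$steps))) {
      stop("non-finite step in series ", k, " at index ",
           which(!is.finite(ser$steps))[1], call. = FALSE)
    }
    ll <- ll + .forward_loglik_cpp(.log_emission_matrix(params, ser),
                                   params$Gamma, params$delta)
  }
  ll
}

# ---- working-scale packing ------------------------------------------------

.pack_params <- function(p) {
  eta_G <- numeric(6)
  k <- 1
  for (i in 1:3) for (j in 1:3) if (i != j) {
    eta_G[k] <- log(p$Gamma[i, j] / p$Gamma[i, i]); k <- k + 1
  }
  eta_d <- log(p$delta[2:3] / p$delta[1])
  w <- c(log(p$step_mean), log(p$step_sd), p$turn_mu, log(p$turn_kappa),
         eta_G, eta_d)
  if (!is.null(p$zero_mass)) w <- c(w, qlogis(pmax(p$zero_mass, 1e-8)))
  w
}

.unpack_params <- function(w, zero_inflated = FALSE) {
  step_mean <- exp(w[1:3]); step_sd <- exp(w[4:6])
  turn_mu <- wrap_angle(w[7:9]); turn_kappa <- exp(w[10:12])
  G <- diag(3)
  k <- 13
  for (i in 1:3) {
    e <- numeric(3); e[i] <- 0
    for (j in 1:3) if (i != j) { e[j] <- w[k]; k <- k + 1 }
    row <- exp(e - max(e)); G[i, ] <- row / sum(row)
  }
  ed <- c(0, w[19:20])
  delta <- exp(ed - max(ed)); delta <- delta / sum(delta)
  zm <- if (zero_inflated) plogis(w[21:23]) else NULL
  hmm_params(step_mean, step_sd, turn_mu, turn_kappa, G, delta, zm)
}

#' Fit the 3-state HMM by direct numerical maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation of the forward log-likelihood on a
#' working scale (log for positive parameters, multinomial logit for the
#' transition rows and initial distribution). Several seeded restarts
#' from jittered initial values guard against local optima; the best
#' log-likelihood wins. Fitted states are relabelled by ascending step
#' mean so resting < foraging < transiting.
#'
#' @param series_list List of step/turn series.
#' @param init Initial `bk_hmm_params` (default [default_hmm_params()]).
#' @param n_restarts Number of starts (default 5; the first is `init`
#'   unjittered).
#' @param seed Seed for the restart jitter.
#' @param maxit Maximum BFGS iterations per start.
#' @return The fitted `bk_hmm_params` with a `fit` element: `loglik`,
#'   `convergence` (0 = converged), `n_obs`, `restart_logliks`.
#' @export
fit_hmm <- function(series_list, init = default_hmm_params(),
                    n_restarts = 5, seed = NULL, maxit = 300) {
  if (!is.null(seed)) set.seed(seed)
  n_obs <- sum(vapply(series_list, function(s) length(s$steps), numeric(1)))
  zero_infl <- any(vapply(series_list,
                          function(s) any(s$steps == 0), logical(1)))
  if (zero_infl && is.null(init$zero_mass)) {
    init$zero_mass <- rep(0.05, 3)
  }
  n_par <- 20 + if (zero_infl) 3 else 0
  if (n_obs < 50 * n_par) {
    warning("only ", n_obs, " observations for ", n_par,
            " free parameters; estimates may be unstable")
  }
  # concatenate the series once; per-evaluation work then happens in C++
  steps <- unlist(lapply(series_list, `[[`, "steps"))
  turns <- unlist(lapply(series_list, `[[`, "turns"))
  lens <- vapply(series_list, function(s) length(s$steps), integer(1))
  starts <- as.integer(cumsum(c(0, lens[-length(lens)])))
  turn_na <- is.na(turns)
  cos_t <- ifelse(turn_na, 0, cos(turns))
  sin_t <- ifelse(turn_na, 0, sin(turns))
  log_steps <- ifelse(steps > 0, log(steps), 0)
  negll <- function(w) {
    p <- try(.unpack_params(w, zero_infl), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    zm <- if (zero_infl) p$zero_mass else rep(-1, 3)
    .hmm_negll_cpp(steps, log_steps, cos_t, sin_t, turn_na,
                   starts, as.integer(lens),
                   (p$step_mean / p$step_sd)^2,
                   p$step_mean / p$step_sd^2,
                   p$turn_mu, p$turn_kappa, zm, p$Gamma, p$delta)
  }
  best <- NULL
  restart_ll <- numeric(n_restarts)
  w0 <- .pack_params(init)
  for (r in seq_len(n_restarts)) {
    w_start <- if (r == 1) w0 else {
      jit <- w0
      jit[c(1:6, 10:12)] <- jit[c(1:6, 10:12)] + log(runif(9, 0.7, 1.3))
      jit[7:9] <- jit[7:9] + runif(3, -0.3, 0.3)
      jit[13:20] <- jit[13:20] + rnorm(8, 0, 0.3)
      if (zero_infl) jit[21:23] <- jit[21:23] + rnorm(3, 0, 0.3)
      jit
    }
    ans <- optim(w_start, negll, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-10))
    restart_ll[r] <- -ans$value
    if (is.null(best) || ans$value < best$value) best <- ans
  }
  p <- .unpack_params(best$par, zero_infl)
  # canonical relabelling by ascending step mean
  o <- order(p$step_mean)
  p <- hmm_params(p$step_mean[o], p$step_sd[o], p$turn_mu[o],
                  p$turn_kappa[o], p$Gamma[o, o, drop = FALSE],
                  p$delta[o], if (!is.null(p$zero_mass)) p$zero_mass[o])
  p$fit <- list(loglik = -best$value, convergence = best$convergence,
                converged = best$convergence == 0, n_obs = n_obs,
                restart_logliks = restart_ll,
                counts = best$counts)
  if (best$convergence != 0) {
    warning("fit_hmm: optimiser did not report convergence (code ",
            best$convergence, "); best-found parameters returned")
  }
  p
}

#' Viterbi decoding
#'
#' Most probable state sequence given observations and parameters,
#' computed by the log-space Viterbi recursion (ties broken toward the
#' lowest state index).
#'
#' @param params `bk_hmm_params`.
#' @param series One step/turn series.
#' @return Character vector of state labels, one per observation (step).
#' @export
viterbi_decode <- function(params, series) {
  path <- .viterbi_cpp(.log_emission_matrix(params, series),
                       params$Gamma, params$delta)
  .state_names[path]
}

#' Behavioural state proportions with colony-weighted grand mean
#'
#' Per-colony proportions are the fraction of decoded fixes in each
#' state; the grand mean weights colonies by their number of tracked
#' individuals (accounting for differences in colony sample size).
#'
#' @param decoded `data.frame` with columns `colony_id`,
#'   `individual_id`, `state`.
#' @return List with `per_colony` (data.frame) and `grand` (named
#'   weighted-mean proportions summing to 1).
#' @export
state_proportions <- function(decoded) {
  cols <- unique(decoded$colony_id)
  per <- do.call(rbind, lapply(cols, function(cid) {
    sub <- decoded[decoded$colony_id == cid, ]
    tab <- table(factor(sub$state, levels = .state_names))
    prop <- as.numeric(tab) / sum(tab)
    data.frame(colony_id = cid,
               n_individuals = length(unique(sub$individual_id)),
               resting = prop[1], foraging = prop[2], transiting = prop[3],
               stringsAsFactors = FALSE)
  }))
  w <- per$n_individuals / sum(per$n_individuals)
  grand <- c(resting = sum(w * per$resting),
             foraging = sum(w * per$foraging),
             transiting = sum(w * per$transiting))
  stopifnot(abs(sum(grand) - 1) < 1e-12)
  list(per_colony = per, grand = grand)
}
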