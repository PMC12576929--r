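test_that("steps and turns follow the path geometry", {
  straight <- data.frame(x = c(0, 1, 2, 3), y = c(0, 0, 0, 0))
  st <- steps_and_turns(straight)
  expect_equal(st$steps, rep(1, 3))
  expect_equal(st$turns[-1], c(0, 0))
  expect_true(is.na(st$turns[1]))

  right_angle <- data.frame(x = c(0, 1, 1), y = c(0, 0, 1))
  expect_equal(steps_and_turns(right_angle)$turns[2], pi / 2)
  left_angle <- data.frame(x = c(0, 1, 1), y = c(0, 0, -1))
  expect_equal(steps_and_turns(left_angle)$turns[2], -pi / 2)

  reversal <- data.frame(x = c(0, 1, 0), y = c(0, 0, 0))
  expect_equal(steps_and_turns(reversal)$turns[2], pi)  # wrapped into (-pi, pi]

  expect_error(steps_and_turns(straight[1:2, ]), ">= 3")
})

test_that("gap splitting breaks series without inventing long steps", {
  t0 <- as.POSIXct("2012-06-01 06:00:00", tz = "UTC")
  fx <- data.frame(x = c(0:4, 50 + 0:4), y = rep(0, 10),
                   timestamp = t0 + c(0:4 * 100, 3600 + 0:4 * 100))
  ser <- series_from_fixes(fx, interval_s = 100, gap_factor = 3)
  expect_length(ser, 2)
  expect_true(all(unlist(lapply(ser, `[[`, "steps")) <= 1))
  whole <- series_from_fixes(fx, interval_s = 100, gap_factor = Inf)
  expect_length(whole, 1)
})

test_that("emission density combines gamma and von Mises correctly", {
  p <- default_hmm_params()
  # moment-matched gamma parameters for the transiting state
  shape <- (0.98 / 0.32)^2; rate <- 0.98 / 0.32^2
  expect_equal(shape, 9.3789, tolerance = 1e-4)
  expect_equal(rate, 9.5703, tolerance = 1e-4)
  expect_equal(emission_density(p, 3, 0.5, NA),
               dgamma(0.5, shape, rate), tolerance = 1e-12)
  # kappa = 0 turn factor is the circular uniform
  p0 <- hmm_params(p$step_mean, p$step_sd, p$turn_mu, c(0, 0, 0), p$Gamma)
  expect_equal(emission_density(p0, 1, 0.07, 2.1) /
                 emission_density(p0, 1, 0.07, NA), 1 / (2 * pi))
  # unimodality: density at the mean beats the far tail for shape > 1
  expect_gt(emission_density(p, 3, 0.98, NA),
            emission_density(p, 3, 0.98 + 3 * 0.32, NA))
  expect_error(emission_density(p, 1, -0.1, NA), "negative")
})

test_that("forward likelihood matches direct evaluation on degenerate
           cases and exhaustive enumeration", {
  p <- default_hmm_params()
  obs <- list(steps = 0.4, turns = NA_real_)
  # delta concentrated on one state
  p1 <- hmm_params(p$step_mean, p$step_sd, p$turn_mu, p$turn_kappa,
                   p$Gamma, delta = c(1, 0, 0))
  expect_equal(hmm_loglik(p1, list(obs)),
               emission_density(p1, 1, 0.4, NA, log = TRUE))
  # general delta
  mix <- sum(vapply(1:3, function(s)
    p$delta[s] * emission_density(p, s, 0.4, NA), numeric(1)))
  expect_equal(hmm_loglik(p, list(obs)), log(mix))
  # T = 6 exhaustive path sum
  ser <- random_series(6, seed = 31)
  expect_equal(hmm_loglik(p, list(ser)), brute_force_loglik(p, ser),
               tolerance = 1e-12)
  expect_error(hmm_loglik(p, list(list(steps = c(0.1, NaN),
                                       turns = c(NA, 0)))), "non-finite")
})

test_that("likelihood is invariant to permuting state labels", {
  p <- default_hmm_params()
  o <- c(2, 3, 1)
  pp <- hmm_params(p$step_mean[o], p$step_sd[o], p$turn_mu[o],
                   p$turn_kappa[o], p$Gamma[o, o], p$delta[o])
  ser <- random_series(40, seed = 32)
  expect_equal(hmm_loglik(p, list(ser)), hmm_loglik(pp, list(ser)),
               tolerance = 1e-9)
})

test_that("Viterbi equals the exhaustive argmax and handles constructed
           chains", {
  p <- default_hmm_params()
  for (seed in 33:35) {
    ser <- random_series(7, seed = seed)
    dec <- viterbi_decode(p, ser)
    expect_identical(match(dec, c("resting", "foraging", "transiting")),
                     unname(brute_force_viterbi(p, ser)))
  }
  # near-deterministic emissions recover the truth
  sharp <- hmm_params(c(0.05, 0.5, 5), c(0.01, 0.05, 0.2),
                      c(0, 0, 0), c(50, 50, 50),
                      build_transition_matrix(rep(1 / 3, 3), 0.3))
  cfg <- default_config()
  cfg$state_params$step_mean <- sharp$step_mean
  cfg$state_params$step_sd <- sharp$step_sd
  cfg$state_params$turn_kappa <- sharp$turn_kappa
  cfg$transition_matrix <- sharp$Gamma
  cfg$initial_distribution <- sharp$delta
  tr <- simulate_hmm_series(cfg, 400, seed = 36)
  dec <- viterbi_decode(sharp, steps_and_turns(tr))
  truth <- tr$true_state[seq_along(dec)]
  expect_gt(mean(dec == truth), 0.98)

  # diagonal-dominant chain started in transiting stays there on a
  # short series whose observations do not overwhelm the chain
  sticky <- hmm_params(p$step_mean, p$step_sd, p$turn_mu, p$turn_kappa,
                       diag(3) * 0.999 + 0.0005 * (1 - diag(3)),
                       delta = c(1e-9, 1e-9, 1 - 2e-9))
  set.seed(37)
  ser <- list(steps = runif(5, 0.4, 0.9),
              turns = c(NA, runif(4, -0.2, 0.2)))
  expect_true(all(viterbi_decode(sticky, ser) == "transiting"))
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  cfg <- default_config()
  set.seed(41)
  series <- lapply(1:12, function(i)
    steps_and_turns(simulate_hmm_series(cfg, 400)))
  p0 <- default_hmm_params()
  fit <- suppressWarnings(fit_hmm(series, n_restarts = 2, seed = 42,
                                  maxit = 200))
  expect_true(all(abs(fit$step_mean - p0$step_mean) / p0$step_mean < 0.05))
  expect_lt(abs(fit$turn_kappa[2] - 0.34) / 0.34, 0.2)
  # MLE dominance over the generating parameters on the same data
  expect_gte(fit$fit$loglik, hmm_loglik(p0, series) - 1e-6)
  # canonical ordering
  expect_true(all(diff(fit$step_mean) > 0))
})

test_that("state proportions are counted and colony-weighted", {
  d1 <- data.frame(colony_id = "A", individual_id = "a1",
                   state = c("resting", "resting", "foraging", "transiting"))
  sp <- state_proportions(d1)
  expect_equal(unname(sp$grand), c(0.5, 0.25, 0.25))
  # two colonies with weights 3 and 1 individuals
  d2 <- rbind(
    data.frame(colony_id = "A",
               individual_id = rep(c("a1", "a2", "a3"), each = 4),
               state = rep(c("resting", "foraging", "foraging",
                             "transiting"), 3)),
    data.frame(colony_id = "B", individual_id = "b1",
               state = c("resting", "resting", "resting", "foraging")))
  sp2 <- state_proportions(d2)
  pA <- c(0.25, 0.5, 0.25); pB <- c(0.75, 0.25, 0)
  expect_equal(unname(sp2$grand), (3 * pA + pB) / 4)
  expect_equal(sum(sp2$grand), 1, tolerance = 1e-12)
})
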