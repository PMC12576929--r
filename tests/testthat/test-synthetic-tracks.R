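test_that("transition-matrix construction hits the target stationary law", {
  G <- build_transition_matrix(c(0.23, 0.48, 0.29), 0.1)
  expect_equal(rowSums(G), rep(1, 3), tolerance = 1e-14)
  expect_equal(stationary_distribution(G), c(0.23, 0.48, 0.29),
               tolerance = 1e-12)
  cfg <- default_config()
  expect_equal(cfg$state_params$step_mean[3], 0.98)
  expect_equal(cfg$state_params$turn_kappa, c(10.77, 0.34, 9.84))
})

test_that("stationary_distribution solves pi G = pi and rejects
           reducible chains", {
  expect_equal(stationary_distribution(matrix(1 / 3, 3, 3)),
               rep(1 / 3, 3))
  expect_error(stationary_distribution(diag(3)), "reducible")
  set.seed(4)
  for (i in 1:5) {
    G <- matrix(rexp(9), 3, 3); G <- G / rowSums(G)
    p <- stationary_distribution(G)
    expect_lt(max(abs(p %*% G - p)), 1e-10)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("von Mises sampler and density are consistent", {
  # density integrates to 1
  for (kap in c(0, 0.34, 9.84)) {
    v <- integrate(dvonmises, -pi, pi, mu = 0.3, kappa = kap)$value
    expect_equal(v, 1, tolerance = 1e-6)
  }
  expect_equal(dvonmises(1.234, 0, 0), 1 / (2 * pi))
  # mean resultant length matches I1(k)/I0(k)
  set.seed(5)
  x <- rvonmises(20000, 0.5, 2)
  rbar <- sqrt(mean(cos(x))^2 + mean(sin(x))^2)
  expect_equal(rbar, besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
  expect_equal(atan2(mean(sin(x)), mean(cos(x))), 0.5, tolerance = 0.03)
})

test_that("free-running simulation is seed-deterministic and converges to
           the generating moments", {
  cfg <- default_config()
  a <- simulate_hmm_series(cfg, 500, seed = 11)
  b <- simulate_hmm_series(cfg, 500, seed = 11)
  expect_identical(a, b)

  tr <- simulate_hmm_series(cfg, 100000, seed = 13)
  n <- nrow(tr) - 1
  freq <- prop.table(table(factor(tr$true_state[1:n],
                                  levels = c("resting", "foraging",
                                             "transiting"))))
  expect_lt(max(abs(as.numeric(freq) - c(0.23, 0.48, 0.29))), 0.01)

  steps <- attr(tr, "steps")
  st <- tr$true_state[1:n]
  m_tr <- mean(steps[st == "transiting"])
  # within 2 Monte-Carlo standard errors of the generating mean
  se <- 0.32 / sqrt(sum(st == "transiting"))
  expect_lt(abs(m_tr - 0.98), max(2 * se, 0.01))
  m_rest <- mean(steps[st == "resting"])
  expect_lt(abs(m_rest - 0.07), 0.01)
})

test_that("colony trips start and end at the colony and are counted
           correctly", {
  cfg <- default_config(n_individuals_per_colony = 5,
                        trips_per_individual = 3,
                        trip_length = c(60, 120))
  tracks <- simulate_colony_trips(cfg, seed = 21)
  expect_setequal(unique(tracks$colony_id), cfg$colony_sites$colony_id[1:2])
  n_trips <- 0
  for (ind in unique(tracks$individual_id)) {
    sub <- tracks[tracks$individual_id == ind, ]
    colony <- cfg$colony_sites[cfg$colony_sites$colony_id ==
                                 sub$colony_id[1], ]
    for (k in setdiff(unique(sub$trip_truth), 0)) {
      tt <- sub[sub$trip_truth == k, ]
      d_first <- great_circle_km(tt$lon[1], tt$lat[1],
                                 colony$lon, colony$lat)
      d_last <- great_circle_km(tt$lon[nrow(tt)], tt$lat[nrow(tt)],
                                colony$lon, colony$lat)
      expect_lt(d_first, 0.5)
      expect_lt(d_last, 0.5)
      n_trips <- n_trips + 1
    }
  }
  expect_equal(n_trips, 2 * 5 * 3)
})

test_that("trip range grows with trip length", {
  maxd <- vapply(seq(40, 400, length.out = 25), function(L) {
    cfg <- default_config(n_colonies = 1, n_individuals_per_colony = 1,
                          trips_per_individual = 1,
                          trip_length = round(L))
    tracks <- simulate_colony_trips(cfg, seed = round(L))
    colony <- cfg$colony_sites[1, ]
    max(great_circle_km(tracks$lon, tracks$lat, colony$lon, colony$lat))
  }, numeric(1))
  expect_gt(cor(seq_len(25), maxd, method = "spearman"), 0)
})

test_that("generator config survives a YAML round trip", {
  cfg <- default_config()
  f <- tempfile(fileext = ".yml")
  write_generator_config(cfg, f)
  back <- read_generator_config(f)
  expect_equal(back$transition_matrix, cfg$transition_matrix,
               tolerance = 1e-12)
  expect_equal(back$state_params, cfg$state_params, tolerance = 1e-12)
  expect_equal(back$origin_time, cfg$origin_time)
})
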