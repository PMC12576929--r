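# shared fixtures, all built in code

test_colony <- function() list(colony_id = "testcol", lon = -1.2, lat = 54.5)

# fixes on a straight line due north of the colony at given distances (km),
# one fix per interval_s seconds
line_fixes <- function(dist_km, colony = test_colony(), interval_s = 100,
                       t0 = as.POSIXct("2012-06-01 06:00:00", tz = "UTC")) {
  ll <- unproject_local(data.frame(x = 0, y = dist_km), colony)
  data.frame(individual_id = "b1", colony_id = colony$colony_id,
             timestamp = t0 + interval_s * (seq_along(dist_km) - 1),
             lon = ll$lon, lat = ll$lat, stringsAsFactors = FALSE)
}

# brute-force forward likelihood by summing over all 3^T state paths
brute_force_loglik <- function(params, series) {
  T_ <- length(series$steps)
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    pa <- paths[r, ]
    pr <- params$delta[pa[1]]
    if (T_ > 1) for (t in 2:T_) pr <- pr * params$Gamma[pa[t - 1], pa[t]]
    em <- 1
    for (t in seq_len(T_)) {
      em <- em * emission_density(params, pa[t], series$steps[t],
                                  series$turns[t])
    }
    tot <- tot + pr * em
  }
  log(tot)
}

# brute-force Viterbi by maximising over all 3^T state paths
brute_force_viterbi <- function(params, series) {
  T_ <- length(series$steps)
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  best <- NULL; bv <- -Inf
  for (r in seq_len(nrow(paths))) {
    pa <- paths[r, ]
    lp <- log(params$delta[pa[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(params$Gamma[pa[t - 1], pa[t]])
    for (t in seq_len(T_)) {
      lp <- lp + emission_density(params, pa[t], series$steps[t],
                                  series$turns[t], log = TRUE)
    }
    if (lp > bv) { bv <- lp; best <- pa }
  }
  best
}

random_series <- function(T_, seed) {
  set.seed(seed)
  list(steps = rgamma(T_, shape = 2, rate = 4),
       turns = c(NA, runif(T_ - 1, -pi, pi)))
}

# a small isopleth-like object on a shared grid from an explicit mask
mask_iso <- function(mask, cell = 1) {
  nx <- nrow(mask); ny <- ncol(mask)
  structure(list(level = 0.5, mask = mask,
                 area_km2 = sum(mask) * cell^2,
                 rings = list(),
                 x = seq_len(nx) * cell, y = seq_len(ny) * cell,
                 cell = cell),
            class = "bk_isopleth")
}

tiny_run_config <- function(seed = 7, out_dir = tempfile("bkrun")) {
  gen <- default_config(n_individuals_per_colony = 3,
                        trips_per_individual = 2,
                        trip_length = c(60, 90))
  cfg <- default_run_config(out_dir = out_dir, seed = seed,
                            generator = gen)
  cfg$params$min_fixes_subset <- 5
  cfg$params$min_individuals_site <- 3
  cfg$params$rep_iterations <- 10
  cfg$params$hmm_restarts <- 1
  cfg$params$hmm_maxit <- 60
  cfg
}

# simulate from the beta GLMM: colony random intercepts on the logit
# scale, common precision
sim_beta_glmm <- function(seed, n_col = 14, n_ind = 10,
                          mus = c(sample = 0.86, resting = 0.9,
                                  foraging = 0.9, transiting = 0.4),
                          phi = 20, sd_col = 0.3) {
  set.seed(seed)
  eta0 <- qlogis(mus)
  recs <- list()
  for (ci in seq_len(n_col)) {
    b <- rnorm(1, 0, sd_col)
    for (ii in seq_len(n_ind)) {
      for (ss in names(mus)) {
        mu <- plogis(eta0[[ss]] + b)
        y <- rbeta(1, mu * phi, (1 - mu) * phi)
        recs[[length(recs) + 1]] <- data.frame(
          colony_id = paste0("c", ci), subset = ss,
          x_transformed = min(max(y, 1e-6), 1 - 1e-6),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
}

sim_lmm <- function(seed, n_col = 14, sd_col = 0.4, sd_res = 0.2,
                    off = c(all = 0, sample = -0.02, foraging = -0.16,
                            resting = -0.48, transiting = 0.28)) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_col), function(ci) {
    b <- rnorm(1, 0, sd_col)
    data.frame(colony_id = paste0("c", ci), subset = names(off),
               log10_area = 2.5 + off + b + rnorm(length(off), 0, sd_res),
               stringsAsFactors = FALSE)
  }))
}

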