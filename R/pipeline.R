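#' Default end-to-end run configuration
#'
#' Bundles the synthetic-generator settings, stage toggles, stage
#' parameters and seeds for [run_pipeline()]. Every stochastic stage has
#' an explicit seed derived from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; stage seeds are fixed offsets from it.
#' @param generator A `bk_config` (default [default_config()]).
#' @export
default_run_config <- function(out_dir = tempfile("bk_run_"), seed = 1,
                               generator = default_config()) {
  cfg <- list(
    out_dir = out_dir,
    generator = generator,
    stages = c(simulate = TRUE, segment = TRUE, classify = TRUE,
               ud = TRUE, overlap = TRUE, keyareas = TRUE, stats = TRUE),
    seeds = list(simulate = seed, classify = seed + 101,
                 ud = seed + 202, keyareas = seed + 303),
    params = list(
      inner_buffer_km = 0.5, return_buffer_km = 1.0, min_return_min = 14,
      min_trip_fixes = 5,
      levels = c(0.5, 0.75, 0.95),
      stats_level = 0.5,
      min_fixes_subset = 10,
      h_override = NULL, h_min = 0.5, ud_cell_divisor = 8,
      threshold_pct = 10, rep_iterations = 50, rep_threshold = 70,
      min_individuals_site = 8,
      hmm_restarts = 3, hmm_maxit = 200,
      beta_reference = "sample", lmm_reference = "all"
    )
  )
  class(cfg) <- "bk_run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks invariants (levels inside (0,1), positive buffers, seeds
#' present for stochastic stages, stage dependencies satisfied) and
#' returns a data.frame of issues; zero rows means the config is valid.
#'
#' @param config A `bk_run_config`.
#' @export
validate_config <- function(config) {
  issues <- character(0)
  p <- config$params
  if (any(p$levels <= 0 | p$levels >= 1)) {
    issues <- c(issues, "isopleth levels must lie strictly in (0, 1)")
  }
  for (nm in c("inner_buffer_km", "return_buffer_km", "min_return_min",
               "threshold_pct", "rep_iterations")) {
    if (is.null(p[[nm]]) || p[[nm]] <= 0) {
      issues <- c(issues, paste0(nm, " must be positive"))
    }
  }
  if (p$inner_buffer_km >= p$return_buffer_km) {
    issues <- c(issues, "inner buffer must be smaller than return buffer")
  }
  st <- config$stages
  stoch <- c(simulate = "simulate", classify = "classify", ud = "ud",
             keyareas = "keyareas")
  for (nm in names(stoch)) {
    if (isTRUE(st[[nm]]) && is.null(config$seeds[[stoch[[nm]]]])) {
      issues <- c(issues, paste0("stochastic stage '", nm,
                                 "' has no seed"))
    }
  }
  deps <- list(segment = "simulate", classify = "segment", ud = "classify",
               overlap = "ud", keyareas = "ud",
               stats = c("overlap", "keyareas"))
  for (nm in names(deps)) {
    if (isTRUE(st[[nm]])) {
      missing <- deps[[nm]][!st[deps[[nm]]]]
      if (length(missing)) {
        issues <- c(issues, paste0("stage '", nm, "' requires disabled ",
                                   "stage(s): ",
                                   paste(missing, collapse = ", ")))
      }
    }
  }
  data.frame(issue = issues, stringsAsFactors = FALSE)
}

.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.write_table <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order
#' (simulate, segment, classify, ud, overlap, keyareas, stats), writing
#' each stage's tables under `config$out_dir` and a `manifest.json`
#' recording per-stage content hashes, output files with md5 checksums,
#' and wall-clock times. On a rerun with an unchanged configuration,
#' stages whose content hash matches the previous manifest and whose
#' outputs are intact are reused rather than recomputed.
#'
#' @param config A `bk_run_config`.
#' @return The manifest (invisibly a list; also written as JSON).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (nrow(issues)) {
    stop("invalid configuration:\n  ",
         paste(issues$issue, collapse = "\n  "), call. = FALSE)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    try(jsonlite::read_json(manifest_path), silent = TRUE)
  } else NULL
  if (inherits(old_manifest, "try-error")) old_manifest <- NULL

  stage_names <- c("simulate", "segment", "classify", "ud", "overlap",
                   "keyareas", "stats")
  enabled <- stage_names[vapply(stage_names,
                                function(s) isTRUE(config$stages[[s]]),
                                logical(1))]
  # content hashes chain each stage to everything upstream of it
  hashes <- list(); up <- ""
  for (s in enabled) {
    key <- switch(s,
      simulate = list(config$generator, config$seeds$simulate),
      segment = list(p$inner_buffer_km, p$return_buffer_km,
                     p$min_return_min, p$min_trip_fixes),
      classify = list(p$hmm_restarts, p$hmm_maxit, config$seeds$classify),
      ud = list(p$levels, p$min_fixes_subset, p$h_override, p$h_min,
                p$ud_cell_divisor, config$seeds$ud),
      overlap = list(p$levels),
      keyareas = list(p$threshold_pct, p$rep_iterations, p$rep_threshold,
                      p$min_individuals_site, config$seeds$keyareas),
      stats = list(p$stats_level, p$beta_reference, p$lmm_reference))
    up <- .hash_obj(list(up, s, key))
    hashes[[s]] <- up
  }
  cached_ok <- function(s) {
    if (is.null(old_manifest$stages[[s]])) return(FALSE)
    rec <- old_manifest$stages[[s]]
    if (!identical(rec$hash, hashes[[s]])) return(FALSE)
    files <- unlist(rec$outputs)
    length(files) > 0 && all(file.exists(file.path(out, files)))
  }
  # a stage can only be skipped outright if every enabled stage after it
  # is also current (later stages need its in-memory state to recompute)
  current <- vapply(enabled, cached_ok, logical(1))
  skip <- rev(cumprod(rev(current))) == 1

  manifest <- list(package_version =
                     as.character(utils::packageVersion("behavKBA")),
                   created = format(Sys.time(), tz = "UTC"),
                   stages = list())
  state <- new.env(parent = emptyenv())
  for (si in seq_along(enabled)) {
    s <- enabled[si]
    t0 <- proc.time()[["elapsed"]]
    outputs <- character(0)
    status <- "ok"
    if (skip[si]) {
      status <- "cached"
      outputs <- unlist(old_manifest$stages[[s]]$outputs)
    } else if (current[si] && s %in% c("simulate", "segment", "classify")) {
      # outputs on disk are current; reload them as state for the
      # downstream stages that do need recomputing
      status <- "cached"
      outputs <- unlist(old_manifest$stages[[s]]$outputs)
      .load_stage(s, state, config)
    } else {
      res <- tryCatch(
        .run_stage(s, state, config),
        error = function(e) e)
      if (inherits(res, "error")) {
        manifest$stages[[s]] <- list(hash = hashes[[s]], status = "failed",
                                     error = conditionMessage(res))
        message("run_pipeline: stage '", s, "' failed: ",
                conditionMessage(res), "; downstream stages skipped")
        break
      }
      outputs <- res
    }
    files_abs <- file.path(out, outputs)
    manifest$stages[[s]] <- list(
      hash = hashes[[s]], status = status, outputs = as.list(outputs),
      md5 = as.list(unname(tools::md5sum(files_abs))),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

# rebuild a reloadable stage's in-memory state from its cached outputs
.load_stage <- function(s, state, config) {
  out <- config$out_dir
  rebuild_trips <- function(df) {
    df$timestamp <- parse_utc(df$timestamp)
    lapply(split(df, df$trip_id), function(tr) {
      tr <- tr[order(tr$timestamp), , drop = FALSE]
      attr(tr, "trip_id") <- tr$trip_id[1]
      attr(tr, "complete") <- isTRUE(tr$complete[1])
      attr(tr, "colony_id") <- tr$colony_id[1]
      rownames(tr) <- NULL
      tr
    })
  }
  if (s == "simulate") {
    tracks <- read.csv(file.path(out, "tracks.csv"),
                       stringsAsFactors = FALSE)
    truth <- read.csv(file.path(out, "truth.csv"),
                      stringsAsFactors = FALSE)
    tracks$timestamp <- parse_utc(tracks$timestamp)
    tracks$true_state <- truth$true_state
    tracks$trip_truth <- truth$trip_truth
    state$tracks <- tracks
  } else if (s == "segment") {
    df <- read.csv(file.path(out, "trips.csv"), stringsAsFactors = FALSE)
    state$trips <- unname(rebuild_trips(df))
    state$trip_metrics <- read.csv(file.path(out, "trip_metrics.csv"),
                                   stringsAsFactors = FALSE)
  } else if (s == "classify") {
    df <- read.csv(file.path(out, "decoded.csv"),
                   stringsAsFactors = FALSE)
    df$complete <- TRUE  # only complete trips reach the classify stage
    state$decoded_trips <- unname(rebuild_trips(df))
  }
  invisible(state)
}

# execute one stage; returns relative output file names
.run_stage <- function(s, state, config) {
  out <- config$out_dir
  p <- config$params
  switch(s,
    simulate = {
      tracks <- simulate_colony_trips(config$generator,
                                      seed = config$seeds$simulate)
      state$tracks <- tracks
      df <- tracks
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
      .write_table(df[, c("individual_id", "colony_id", "timestamp",
                          "lon", "lat")], file.path(out, "tracks.csv"))
      .write_table(df[, c("individual_id", "true_state", "trip_truth")],
                   file.path(out, "truth.csv"))
      c("tracks.csv", "truth.csv")
    },
    segment = {
      tracks <- state$tracks
      sites <- config$generator$colony_sites
      all_trips <- list(); metrics <- list()
      for (ind in unique(tracks$individual_id)) {
        fx <- tracks[tracks$individual_id == ind, , drop = FALSE]
        colony <- sites[sites$colony_id == fx$colony_id[1], ]
        fx <- project_local(fx, colony)
        trips <- filter_complete(split_trips(
          fx, colony, p$inner_buffer_km, p$return_buffer_km,
          p$min_return_min, p$min_trip_fixes))
        for (tr in trips) {
          metrics[[length(metrics) + 1]] <- trip_metrics(tr, colony)
          all_trips[[length(all_trips) + 1]] <- tr
        }
      }
      state$trips <- all_trips
      state$trip_metrics <- do.call(rbind, metrics)
      tf <- trips_to_frame(all_trips)
      tf$timestamp <- format(tf$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
      drop_cols <- intersect(c("true_state", "trip_truth"), names(tf))
      .write_table(tf[, setdiff(names(tf), drop_cols)],
                   file.path(out, "trips.csv"))
      .write_table(state$trip_metrics, file.path(out, "trip_metrics.csv"))
      c("trips.csv", "trip_metrics.csv")
    },
    classify = {
      trips <- state$trips
      colony_of_trip <- vapply(trips, function(tr) attr(tr, "colony_id"),
                               character(1))
      fits <- list(); decoded <- list()
      for (cid in unique(colony_of_trip)) {
        ctrips <- trips[colony_of_trip == cid]
        series <- lapply(ctrips, steps_and_turns)
        fit <- fit_hmm(series, n_restarts = p$hmm_restarts,
                       seed = config$seeds$classify,
                       maxit = p$hmm_maxit)
        fits[[cid]] <- fit
        for (k in seq_along(ctrips)) {
          lab <- viterbi_decode(fit, series[[k]])
          tr <- ctrips[[k]]
          tr$state <- c(lab, lab[length(lab)])  # last fix repeats
          decoded[[length(decoded) + 1]] <- tr
        }
      }
      state$decoded_trips <- decoded
      state$hmm_fits <- fits
      dd <- trips_to_frame(decoded)
      dd$timestamp <- format(dd$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
      .write_table(dd[, c("individual_id", "colony_id", "timestamp",
                          "lon", "lat", "x", "y", "trip_id", "state")],
                   file.path(out, "decoded.csv"))
      pj <- lapply(fits, function(f) {
        list(step_mean = f$step_mean, step_sd = f$step_sd,
             turn_mu = f$turn_mu, turn_kappa = f$turn_kappa,
             Gamma = f$Gamma, delta = f$delta,
             loglik = f$fit$loglik, converged = f$fit$converged,
             n_obs = f$fit$n_obs, seed = config$seeds$classify)
      })
      jsonlite::write_json(pj, file.path(out, "hmm_params.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
      c("decoded.csv", "hmm_params.json")
    },
    ud = {
      decoded <- state$decoded_trips
      tm <- state$trip_metrics
      colony_of_trip <- vapply(decoded, function(tr) attr(tr, "colony_id"),
                               character(1))
      ud_sets <- list(); colony_of <- character(0)
      areas <- list(); grids <- list(); h_by_colony <- list()
      for (cid in unique(colony_of_trip)) {
        ctrips <- decoded[colony_of_trip == cid]
        h <- if (!is.null(p$h_override)) p$h_override else {
          bandwidth_mag(tm$max_distance_km[tm$colony_id == cid],
                        h_min = p$h_min)
        }
        h_by_colony[[cid]] <- h
        fixes <- trips_to_frame(ctrips)
        grid <- make_ud_grid(fixes, h, cell_size = h / p$ud_cell_divisor)
        grids[[cid]] <- grid
        for (ind in unique(fixes$individual_id)) {
          fx <- fixes[fixes$individual_id == ind, , drop = FALSE]
          us <- behaviour_ud_set(fx, h, levels = p$levels,
                                 min_fixes = p$min_fixes_subset,
                                 grid = grid,
                                 seed = config$seeds$ud +
                                   match(ind, unique(fixes$individual_id)))
          ud_sets[[ind]] <- us
          colony_of[ind] <- cid
          for (ss in names(us$isopleths)) {
            for (lv in names(us$isopleths[[ss]])) {
              areas[[length(areas) + 1]] <- data.frame(
                individual_id = ind, colony_id = cid, subset = ss,
                level = as.numeric(lv),
                area_km2 = us$isopleths[[ss]][[lv]]$area_km2,
                h_km = h, stringsAsFactors = FALSE)
            }
          }
        }
      }
      state$ud_sets <- ud_sets
      state$colony_of <- colony_of
      state$grids <- grids
      state$h_by_colony <- h_by_colony
      .write_table(do.call(rbind, areas),
                   file.path(out, "individual_ud_areas.csv"))
      c("individual_ud_areas.csv")
    },
    overlap = {
      tabs <- lapply(p$levels, function(l) {
        overlap_table(state$ud_sets, l, state$colony_of)
      })
      state$overlap <- do.call(rbind, tabs)
      .write_table(state$overlap, file.path(out, "overlap.csv"))
      c("overlap.csv")
    },
    keyareas = {
      subsets <- c("all", "resting", "foraging", "transiting", "sample")
      est <- list()
      for (cid in names(state$grids)) {
        inds <- names(state$colony_of)[state$colony_of == cid]
        for (ss in subsets) {
          sets <- lapply(inds, function(ind) {
            us <- state$ud_sets[[ind]]
            if (is.null(us$uds[[ss]])) return(NULL)
            list(iso = us$isopleths[[ss]], ud = us$uds[[ss]])
          })
          names(sets) <- inds
          sets <- sets[!vapply(sets, is.null, logical(1))]
          if (length(sets) < 3) next
          # representativeness resamples the subset's own locations
          fixes <- trips_to_frame(
            state$decoded_trips[vapply(state$decoded_trips, function(tr)
              attr(tr, "colony_id") == cid, logical(1))])
          loc_sets <- lapply(names(sets), function(ind) {
            fx <- fixes[fixes$individual_id == ind, , drop = FALSE]
            if (ss != "all" && ss != "sample") {
              fx <- fx[fx$state == ss, , drop = FALSE]
            }
            fx[, c("x", "y")]
          })
          names(loc_sets) <- names(sets)
          rr <- assess_representativeness(
            loc_sets, state$h_by_colony[[cid]], level = 0.5,
            n_iterations = p$rep_iterations,
            seed = config$seeds$keyareas, grid = state$grids[[cid]])
          rp <- if (rr$usable) rr$representativeness else NA_real_
          for (lv in as.character(p$levels)) {
            isos <- lapply(sets, function(z) z$iso[[lv]])
            area <- if (!is.na(rp) &&
                        length(isos) >= p$min_individuals_site) {
              find_site(isos, rp, p$threshold_pct,
                        min_individuals = p$min_individuals_site)$area_km2
            } else NA_real_
            est[[length(est) + 1]] <- data.frame(
              colony_id = cid, subset = ss, level = as.numeric(lv),
              area_km2 = area,
              representativeness = if (is.na(rp)) 0 else rp,
              n_individuals = length(sets), stringsAsFactors = FALSE)
          }
        }
      }
      est <- do.call(rbind, est)
      est_ok <- est[!is.na(est$area_km2), , drop = FALSE]
      state$key_areas <- compare_key_area_sizes(est_ok, p$rep_threshold)
      .write_table(est, file.path(out, "key_areas.csv"))
      .write_table(attr(state$key_areas, "exclusions"),
                   file.path(out, "key_area_exclusions.csv"))
      c("key_areas.csv", "key_area_exclusions.csv")
    },
    stats = {
      res <- list()
      ov <- state$overlap[state$overlap$level == p$stats_level, ,
                          drop = FALSE]
      if (length(unique(ov$colony_id)) >= 2) {
        bf <- fit_beta_glmm(ov, reference = p$beta_reference)
        res$beta_glmm <- list(
          coefficients = bf$coefficients, phi = bf$phi,
          sigma_group = bf$sigma_group, subset_means = bf$subset_means,
          loglik = bf$loglik, converged = bf$converged,
          data_hash = .hash_obj(ov))
      } else res$beta_glmm <- list(skipped = "fewer than 2 colonies")
      ka <- state$key_areas
      ka <- ka[ka$level == p$stats_level, , drop = FALSE]
      if (length(unique(ka$colony_id)) >= 2) {
        lf <- fit_lmm(ka, reference = p$lmm_reference)
        res$lmm <- list(
          coefficients = lf$coefficients,
          sigma_group = lf$sigma_group, sigma_resid = lf$sigma_resid,
          r2_marginal = lf$r2_marginal,
          r2_conditional = lf$r2_conditional, loglik = lf$loglik,
          data_hash = .hash_obj(ka))
      } else res$lmm <- list(skipped = "fewer than 2 colonies")
      jsonlite::write_json(res, file.path(out, "stats.json"),
                           auto_unbox = TRUE, digits = 10, pretty = TRUE)
      c("stats.json")
    },
    stop("unknown stage ", s))
}
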