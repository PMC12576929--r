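#' Split a fix stream into at-sea trips
#'
#' Splits one individual's time-sorted fixes into trips using colony
#' buffers: fixes within the inner buffer (default 500 m) are treated as
#' colony-attendance and removed; a trip closes when the bird dwells
#' inside the return buffer (default 1 km) for at least the minimum
#' return duration (default 14 min). A trailing excursion with no
#' qualifying return is kept but flagged incomplete. "Within a buffer"
#' means distance <= radius (closed boundary). The dwell time of a
#' buffer visit is the elapsed time between its first and last fix; a
#' single-fix visit counts as one nominal sampling interval.
#'
#' @param fixes Single-individual `data.frame` with `lon`, `lat`,
#'   `timestamp` (POSIXct), sorted by time.
#' @param colony List/row with `lon`, `lat` (and `colony_id`).
#' @param inner_buffer_km,return_buffer_km,min_return_min Buffer rules.
#' @param min_trip_fixes Trips with fewer at-sea fixes are discarded
#'   (guards against GPS jitter; default 5).
#' @return A list of trips; each trip is the subset of `fixes` outside
#'   the inner buffer with attributes `trip_id`, `complete`, and column
#'   `dist_colony_km`. Also returned invisibly as a combined
#'   `data.frame` by [trips_to_frame()].
#' @export
split_trips <- function(fixes, colony, inner_buffer_km = 0.5,
                        return_buffer_km = 1.0, min_return_min = 14,
                        min_trip_fixes = 5) {
  if (nrow(fixes) == 0) return(list())
  tt <- as.numeric(fixes$timestamp)
  if (is.unsorted(tt, strictly = FALSE)) {
    stop("fixes must be sorted by timestamp", call. = FALSE)
  }
  d <- great_circle_km(fixes$lon, fixes$lat, colony$lon, colony$lat)
  dt <- diff(tt)
  nominal <- if (length(dt)) median(dt) else 100
  if (any(dt > 3600)) {
    warning("data gap(s) > 1 h in fix stream (max ",
            round(max(dt) / 3600, 2), " h); trips are not broken on gaps")
  }

  in_return <- d <= return_buffer_km
  # runs of consecutive fixes inside the return buffer
  r <- rle(in_return)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  visit <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(visit)) {
    visit$dwell_s <- ifelse(
      visit$end > visit$start,
      tt[visit$end] - tt[visit$start],
      nominal)
    visit$qualify <- visit$dwell_s >= min_return_min * 60
  }

  # trip boundaries: segments of the stream between qualifying visits
  qual <- visit[visit$qualify %in% TRUE, , drop = FALSE]
  bounds_start <- c(1, qual$end + 1)
  bounds_end <- c(qual$start - 1, nrow(fixes))
  trips <- list()
  indiv <- if ("individual_id" %in% names(fixes)) {
    fixes$individual_id[1]
  } else "ind"
  for (k in seq_along(bounds_start)) {
    i0 <- bounds_start[k]; i1 <- bounds_end[k]
    if (i0 > i1) next
    idx <- i0:i1
    idx <- idx[d[idx] > inner_buffer_km]  # drop colony-attendance fixes
    if (length(idx) < min_trip_fixes) next
    # complete iff a qualifying visit follows this segment; the final
    # segment can only be closed by the stream itself ending in a
    # qualifying visit (handled because that visit defines a boundary)
    complete <- k <= nrow(qual)
    tr <- fixes[idx, , drop = FALSE]
    tr$dist_colony_km <- d[idx]
    attr(tr, "trip_id") <- sprintf("%s_t%02d", indiv, length(trips) + 1)
    attr(tr, "complete") <- complete
    attr(tr, "colony_id") <- if (!is.null(colony$colony_id)) {
      colony$colony_id
    } else NA_character_
    trips[[length(trips) + 1]] <- tr
  }
  trips
}

#' Flatten a list of trips into one annotated data.frame
#'
#' @param trips List returned by [split_trips()].
#' @return A `data.frame` with `trip_id` and `complete` columns added.
#' @export
trips_to_frame <- function(trips) {
  if (!length(trips)) return(data.frame())
  do.call(rbind, lapply(trips, function(tr) {
    tr$trip_id <- attr(tr, "trip_id")
    tr$complete <- attr(tr, "complete")
    rownames(tr) <- NULL
    tr
  }))
}

#' Keep only complete trips
#'
#' Drops trips where the bird failed to return to the colony. Order is
#' preserved and the number removed is reported.
#'
#' @param trips List of trips from [split_trips()].
#' @export
filter_complete <- function(trips) {
  keep <- vapply(trips, function(tr) isTRUE(attr(tr, "complete")), logical(1))
  if (any(!keep)) {
    message("filter_complete: removed ", sum(!keep), " incomplete trip(s)")
  }
  trips[keep]
}

#' Trip summary metrics
#'
#' Total distance (sum of consecutive great-circle step distances), the
#' maximum distance from the colony, duration in hours, and fix count.
#'
#' @param trip One trip (a `data.frame` with `lon`, `lat`, `timestamp`),
#'   as produced by [split_trips()].
#' @param colony Colony coordinates (`lon`, `lat`).
#' @export
trip_metrics <- function(trip, colony) {
  if (nrow(trip) < 2) stop("trip_metrics needs >= 2 fixes", call. = FALSE)
  n <- nrow(trip)
  step_d <- great_circle_km(trip$lon[-n], trip$lat[-n],
                            trip$lon[-1], trip$lat[-1])
  dcol <- great_circle_km(trip$lon, trip$lat, colony$lon, colony$lat)
  data.frame(
    trip_id = attr(trip, "trip_id") %||% NA_character_,
    individual_id = trip$individual_id[1] %||% NA_character_,
    colony_id = attr(trip, "colony_id") %||% NA_character_,
    complete = isTRUE(attr(trip, "complete")),
    total_distance_km = sum(step_d),
    max_distance_km = max(dcol),
    duration_h = as.numeric(difftime(trip$timestamp[n], trip$timestamp[1],
                                     units = "hours")),
    n_fixes = n,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Colony inclusion filter
#'
#' A colony is retained only if it has at least `min_individuals`
#' individuals with at least one complete trip AND every year in which
#' it was tracked has at least `min_per_year` tagged individuals.
#'
#' @param trip_table `data.frame` with columns `colony_id`,
#'   `individual_id`, `complete`, and `year` (tagging year of the trip).
#' @param min_individuals,min_per_year Thresholds (defaults 8 and 3).
#' @return Character vector of retained colony ids; excluded colonies
#'   and reasons are attached as attribute `exclusions`.
#' @export
filter_colonies <- function(trip_table, min_individuals = 8,
                            min_per_year = 3) {
  keep <- character(0)
  excl <- data.frame(colony_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  for (cid in unique(trip_table$colony_id)) {
    sub <- trip_table[trip_table$colony_id == cid, , drop = FALSE]
    n_complete_ind <- length(unique(sub$individual_id[sub$complete]))
    yr_counts <- tapply(sub$individual_id, sub$year,
                        function(v) length(unique(v)))
    if (n_complete_ind < min_individuals) {
      excl <- rbind(excl, data.frame(
        colony_id = cid,
        reason = sprintf("only %d individuals with complete trips",
                         n_complete_ind)))
    } else if (any(yr_counts < min_per_year)) {
      bad <- names(yr_counts)[yr_counts < min_per_year][1]
      excl <- rbind(excl, data.frame(
        colony_id = cid,
        reason = sprintf("year %s has %d tagged individuals", bad,
                         yr_counts[[bad]])))
    } else {
      keep <- c(keep, cid)
    }
  }
  if (nrow(excl)) {
    message("filter_colonies: excluded ", nrow(excl), " colony/ies")
  }
  attr(keep, "exclusions") <- excl
  keep
}

#' Linearly interpolate a track to a regular time grid
#'
#' Positions are interpolated in the projected plane at exact multiples
#' of `interval_s` from the first fix; no extrapolation beyond the last
#' fix. Used for the sampling-interval sensitivity analysis.
#'
#' @param fixes `data.frame` with `x`, `y` (km) and `timestamp`.
#' @param interval_s Target sampling interval in seconds (default 100).
#' @return `data.frame` with `x`, `y`, `timestamp` on the regular grid.
#' @export
interpolate_track <- function(fixes, interval_s = 100) {
  stopifnot(nrow(fixes) >= 2)
  t0 <- as.numeric(fixes$timestamp)
  grid <- seq(0, t0[length(t0)] - t0[1], by = interval_s)
  tg <- t0[1] + grid
  data.frame(
    timestamp = as.POSIXct(tg, origin = "1970-01-01", tz = "UTC"),
    x = stats::approx(t0, fixes$x, xout = tg, ties = "ordered")$y,
    y = stats::approx(t0, fixes$y, xout = tg, ties = "ordered")$y
  )
}
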