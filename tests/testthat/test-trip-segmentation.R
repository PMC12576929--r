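test_that("buffer rules split a constructed stream into the right trips", {
  colony <- test_colony()
  # 20 min beyond 1 km, 15 min inside the return buffer, 30 min beyond,
  # then >= 14 min inside at the stream end -> 2 complete trips
  d <- c(rep(5, 12),      # 20 min at 5 km
         rep(0.8, 10),    # 15 min elapsed at 0.8 km (inside return buffer)
         rep(6, 18),      # 30 min at 6 km
         rep(0.7, 10))    # ~15 min inside at the end
  fx <- line_fixes(d, colony)
  trips <- split_trips(fx, colony)
  expect_length(trips, 2)
  expect_true(all(vapply(trips, attr, logical(1), which = "complete")))
  expect_equal(nrow(trips[[1]]), 12)
  expect_equal(nrow(trips[[2]]), 18)
})

test_that("all fixes inside the inner buffer give no trips", {
  colony <- test_colony()
  fx <- line_fixes(rep(0.3, 30), colony)
  expect_length(split_trips(fx, colony), 0)
  expect_length(split_trips(fx[0, ], colony), 0)  # empty input, no error
})

test_that("a trailing return shorter than the minimum duration leaves the
           trip incomplete", {
  colony <- test_colony()
  d <- c(rep(4, 15), rep(0.7, 3))  # only ~5 min inside at stream end
  fx <- line_fixes(d, colony)
  trips <- split_trips(fx, colony)
  expect_length(trips, 1)
  expect_false(attr(trips[[1]], "complete"))
})

test_that("unordered timestamps are rejected", {
  colony <- test_colony()
  fx <- line_fixes(rep(5, 10), colony)
  fx$timestamp[3] <- fx$timestamp[9]
  expect_error(split_trips(fx[c(1:3, 9, 4:8, 10), ], colony), "sorted")
})

test_that("splitting is invariant to colony-buffer padding and conserves
           fixes", {
  colony <- test_colony()
  d <- c(rep(5, 12), rep(0.7, 10))
  fx <- line_fixes(d, colony)
  base <- split_trips(fx, colony)
  pad <- line_fixes(c(rep(0.2, 8), d, rep(0.2, 8)), colony)
  padded <- split_trips(pad, colony)
  expect_length(padded, length(base))
  expect_equal(nrow(padded[[1]]), nrow(base[[1]]))
  expect_true(all(trips_to_frame(base)$dist_colony_km > 0.5))
  expect_lte(sum(vapply(base, nrow, numeric(1))), nrow(fx))
})

test_that("filter_complete keeps order, logs removals and is idempotent", {
  colony <- test_colony()
  d_inc <- c(rep(4, 15), rep(0.7, 3))
  d_com <- c(rep(4, 15), rep(0.7, 10))
  trips <- c(split_trips(line_fixes(d_com, colony), colony),
             split_trips(line_fixes(d_inc, colony), colony))
  expect_message(kept <- filter_complete(trips), "1 incomplete")
  expect_length(kept, 1)
  expect_identical(filter_complete(kept), kept)
  expect_length(filter_complete(split_trips(line_fixes(d_inc, colony),
                                            colony)), 0)
})

test_that("trip metrics match hand arithmetic", {
  colony <- test_colony()
  # collinear at 0 -> excluded by inner buffer, so use 2, 5, 10 km
  fx <- line_fixes(c(2, 5, 10), colony)
  tr <- fx; tr$dist_colony_km <- c(2, 5, 10)
  attr(tr, "complete") <- TRUE
  m <- trip_metrics(tr, colony)
  expect_equal(m$total_distance_km, 8, tolerance = 1e-6)
  expect_equal(m$max_distance_km, 10, tolerance = 1e-6)
  expect_equal(m$duration_h, 200 / 3600, tolerance = 1e-9)

  # out and back along the same line to 5 km
  fx2 <- line_fixes(c(1, 3, 5, 3, 1), colony)
  m2 <- trip_metrics(fx2, colony)
  expect_equal(m2$total_distance_km, 8, tolerance = 1e-6)
  expect_equal(m2$max_distance_km, 5, tolerance = 1e-6)

  # two identical fixes: zero distance travelled
  fx3 <- line_fixes(c(4, 4), colony)
  m3 <- trip_metrics(fx3, colony)
  expect_equal(m3$total_distance_km, 0)
  expect_equal(m3$max_distance_km, 4, tolerance = 1e-6)

  expect_error(trip_metrics(fx3[1, , drop = FALSE], colony), ">= 2")
})

test_that("colony inclusion filter applies both sample-size rules", {
  mk <- function(colony, inds, year, complete = TRUE) {
    data.frame(colony_id = colony, individual_id = inds, year = year,
               complete = complete, stringsAsFactors = FALSE)
  }
  # 8 individuals, one year, all complete -> retained (boundary inclusive)
  t1 <- mk("A", paste0("i", 1:8), 2012)
  expect_equal(as.character(filter_colonies(t1)), "A")
  # 7 individuals -> excluded
  t2 <- mk("B", paste0("i", 1:7), 2012)
  expect_length(suppressMessages(filter_colonies(t2)), 0)
  # 10 individuals split 8 + 2 across years -> excluded (2 < 3 per year)
  t3 <- rbind(mk("C", paste0("i", 1:8), 2012),
              mk("C", paste0("j", 1:2), 2013))
  res <- suppressMessages(filter_colonies(t3))
  expect_length(res, 0)
  expect_match(attr(res, "exclusions")$reason, "year 2013")
})

test_that("interpolation to a regular grid is linear and bounded", {
  t0 <- as.POSIXct("2012-06-01 06:00:00", tz = "UTC")
  fx <- data.frame(x = c(0, 2), y = c(0, 0), timestamp = t0 + c(0, 200))
  out <- interpolate_track(fx, 100)
  expect_equal(nrow(out), 3)
  expect_equal(out$x, c(0, 1, 2))

  # already on the grid: identity
  fx2 <- data.frame(x = 0:5, y = (0:5)^2, timestamp = t0 + 100 * (0:5))
  out2 <- interpolate_track(fx2, 100)
  expect_equal(out2$x, fx2$x)
  expect_equal(out2$y, fx2$y)

  # 1000 s gap -> 9 strictly interior interpolated fixes
  fx3 <- data.frame(x = c(0, 10), y = c(0, 5), timestamp = t0 + c(0, 1000))
  out3 <- interpolate_track(fx3, 100)
  expect_equal(nrow(out3), 11)
  interior <- out3[-c(1, 11), ]
  expect_true(all(interior$x > 0 & interior$x < 10))
})
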