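#' Kernel smoothing parameter from trip ranges ("mag")
#'
#' The bandwidth appropriate for central-place foragers: the natural log
#' of the median per-trip maximum distance from the colony (km), floored
#' at `h_min` because a median range of e km or less would give a
#' non-positive bandwidth.
#'
#' @param max_distances_km Per-trip maximum distances from the colony.
#' @param h_min Lower floor in km (default 0.5).
#' @return Bandwidth h in km.
#' @export
bandwidth_mag <- function(max_distances_km, h_min = 0.5) {
  stopifnot(length(max_distances_km) >= 1, all(max_distances_km > 0))
  h <- log(median(max_distances_km))
  if (h < h_min) {
    warning("mag bandwidth ", round(h, 3), " below floor; using h_min = ",
            h_min, " km")
    h <- h_min
  }
  h
}

#' Build a UD grid specification
#'
#' The grid covers the points' bounding box expanded on every side by
#' `max(margin_frac * extent, 3h)`; cell size defaults to h/10 and is
#' coarsened if the grid would exceed `max_cells` per axis.
#'
#' @param points Matrix/data.frame with `x`, `y` in km.
#' @param h Bandwidth (km).
#' @param cell_size Cell edge in km (default h/10).
#' @param margin_frac Fractional bounding-box margin (default 0.2).
#' @param max_cells Cap on cells per axis (default 2000).
#' @return List with cell-centre vectors `x`, `y` and `cell` size.
#' @export
make_ud_grid <- function(points, h, cell_size = h / 10,
                         margin_frac = 0.2, max_cells = 2000) {
  xr <- range(points$x); yr <- range(points$y)
  pad_x <- max(margin_frac * diff(xr), 3 * h)
  pad_y <- max(margin_frac * diff(yr), 3 * h)
  x0 <- xr[1] - pad_x; x1 <- xr[2] + pad_x
  y0 <- yr[1] - pad_y; y1 <- yr[2] + pad_y
  cell <- max(cell_size, (x1 - x0) / max_cells, (y1 - y0) / max_cells)
  gx <- seq(x0 + cell / 2, x1, by = cell)
  gy <- seq(y0 + cell / 2, y1, by = cell)
  list(x = gx, y = gy, cell = cell)
}

#' Compute a kernel utilisation distribution on a grid
#'
#' Isotropic bivariate Gaussian kernel with standard deviation h per
#' axis, evaluated at cell centres and renormalised so the grid mass
#' (sum of density times cell area) is exactly 1.
#'
#' @param points `data.frame` with `x`, `y` (km); >= 1 row.
#' @param h Bandwidth in km (> 0).
#' @param grid Optional grid from [make_ud_grid()]; built from the
#'   points if omitted.
#' @return A `bk_ud` list: `x`, `y`, `cell`, `density` (matrix
#'   `length(x)` by `length(y)`, probability per km^2).
#' @export
compute_ud <- function(points, h, grid = NULL) {
  stopifnot(nrow(points) >= 1, h > 0)
  if (is.null(grid)) grid <- make_ud_grid(points, h)
  dx <- outer(grid$x, points$x, function(a, b) stats::dnorm(a, b, h))
  dy <- outer(grid$y, points$y, function(a, b) stats::dnorm(a, b, h))
  dens <- (dx %*% t(dy)) / nrow(points)
  cell_area <- grid$cell^2
  tot <- sum(dens) * cell_area
  if (tot <= 0) stop("all kernel mass fell outside the grid", call. = FALSE)
  dens <- dens / tot
  ud <- list(x = grid$x, y = grid$y, cell = grid$cell, density = dens,
             h = h, n_points = nrow(points))
  class(ud) <- "bk_ud"
  ud
}

#' Extract an isopleth from a UD
#'
#' Cells are ranked by descending density and accumulated until the
#' enclosed mass reaches `level`; cells tied with the threshold density
#' are all included (deterministic and level-conservative). The area is
#' the selected-cell count times the cell area; the boundary is the
#' dissolved outline of the selected cells.
#'
#' @param ud A `bk_ud`.
#' @param level Cumulative-mass level in (0, 1), e.g. 0.5 for the core
#'   area.
#' @return A `bk_isopleth` list: `level`, `mask` (logical matrix),
#'   `area_km2`, `rings` (list of two-column x/y matrices), grid
#'   vectors `x`, `y`, `cell`.
#' @export
isopleth <- function(ud, level) {
  stopifnot(level > 0, level < 1)
  v <- as.vector(ud$density)
  cell_area <- ud$cell^2
  ord <- order(v, decreasing = TRUE)
  cmass <- cumsum(v[ord]) * cell_area
  k <- which(cmass >= level)[1]
  if (is.na(k)) k <- length(ord)
  thr <- v[ord[k]]
  mask <- matrix(v >= thr, nrow(ud$density), ncol(ud$density))
  iso <- list(level = level, mask = mask,
              area_km2 = sum(mask) * cell_area,
              rings = .mask_rings(mask, ud$x, ud$y, ud$cell),
              x = ud$x, y = ud$y, cell = ud$cell)
  class(iso) <- "bk_isopleth"
  iso
}

# Dissolve a logical cell mask into boundary rings. Cell (i, j) spans
# corners (i-1, j-1)..(i, j) on a corner lattice; interior shared edges
# cancel, remaining directed edges (CCW around cells) chain into rings.
.mask_rings <- function(mask, gx, gy, cell) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(list())
  nx <- nrow(mask); ny <- ncol(mask)
  nxc <- length(gx) + 1L
  corner_id <- function(i, j) i + j * nxc  # i,j are 0-based corner coords
  # boundary edges, CCW around each cell, found by shifted comparison:
  # a side is boundary where the neighbouring cell is off-grid or FALSE
  no_left <- mask & !rbind(rep(FALSE, ny), mask[-nx, , drop = FALSE])
  no_right <- mask & !rbind(mask[-1, , drop = FALSE], rep(FALSE, ny))
  no_down <- mask & !cbind(rep(FALSE, nx), mask[, -ny, drop = FALSE])
  no_up <- mask & !cbind(mask[, -1, drop = FALSE], rep(FALSE, nx))
  seg <- function(m, from_fn, to_fn) {
    ij <- which(m, arr.ind = TRUE)
    cbind(from_fn(ij[, 1], ij[, 2]), to_fn(ij[, 1], ij[, 2]))
  }
  ee <- rbind(
    seg(no_down, function(i, j) corner_id(i - 1, j - 1),
        function(i, j) corner_id(i, j - 1)),     # bottom, left -> right
    seg(no_right, function(i, j) corner_id(i, j - 1),
        function(i, j) corner_id(i, j)),         # right, bottom -> top
    seg(no_up, function(i, j) corner_id(i, j),
        function(i, j) corner_id(i - 1, j)),     # top, right -> left
    seg(no_left, function(i, j) corner_id(i - 1, j),
        function(i, j) corner_id(i - 1, j - 1))  # left, top -> bottom
  )
  ord <- order(ee[, 1], ee[, 2])  # deterministic chaining order
  ee <- ee[ord, , drop = FALSE]
  # constant-time successor lookup: edge indices bucketed by start
  # corner (a corner carries 2 outgoing edges only at pinch points)
  buckets <- list2env(split(seq_len(nrow(ee)), ee[, 1]),
                      hash = TRUE, parent = emptyenv())
  used <- rep(FALSE, nrow(ee))
  take_from <- function(corner) {
    idx <- buckets[[as.character(corner)]]
    idx <- idx[!used[idx]]
    if (!length(idx)) NA_integer_ else idx[1]
  }
  rings <- list()
  for (e0 in seq_len(nrow(ee))) {
    if (used[e0]) next
    used[e0] <- TRUE
    first <- ee[e0, 1]
    path_ids <- first
    cur <- ee[e0, 2]
    while (cur != first) {
      path_ids <- c(path_ids, cur)
      nxt <- take_from(cur)
      if (is.na(nxt)) break  # should not happen on a well-formed mask
      used[nxt] <- TRUE
      cur <- ee[nxt, 2]
    }
    i <- path_ids %% nxc; j <- path_ids %/% nxc
    rings[[length(rings) + 1]] <- cbind(
      x = gx[1] - cell / 2 + i * cell,
      y = gy[1] - cell / 2 + j * cell)
  }
  rings
}

#' Random-subsample control locations
#'
#' Uniform random sample, without replacement, from all of an
#' individual's fixes, of size equal to the fix count of that
#' individual's most infrequently recorded behaviour. Controls for
#' behaviour-specific UDs being built from fewer locations.
#'
#' @param fixes `data.frame` of the individual's fixes with a `state`
#'   column.
#' @param seed Seed for the draw.
#' @return The sampled subset of `fixes`.
#' @export
subsample_control <- function(fixes, seed = NULL) {
  counts <- vapply(.state_names,
                   function(s) sum(fixes$state == s), numeric(1))
  if (any(counts == 0)) {
    stop("individual lacks fixes for behaviour(s): ",
         paste(.state_names[counts == 0], collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  fixes[sample.int(nrow(fixes), min(counts)), , drop = FALSE]
}

#' Behaviour-specific UD set for one individual
#'
#' Computes the all-behaviour UD, one UD per decoded behaviour, and the
#' random-subsample control, all with the same bandwidth and grid extent
#' so their isopleths are directly comparable. Subsets with fewer than
#' `min_fixes` locations are skipped with a logged reason.
#'
#' @param fixes Projected fixes of one individual with `x`, `y`,
#'   `state`.
#' @param h Bandwidth (km), typically from [bandwidth_mag()].
#' @param levels Isopleth levels (default 0.50, 0.75, 0.95).
#' @param min_fixes Minimum locations per subset (default 10).
#' @param grid Optional shared grid (built from all fixes if omitted).
#' @param seed Seed for the subsample control.
#' @return List with `isopleths[[subset]][[as.character(level)]]`,
#'   `uds[[subset]]`, `h`, `grid`, and a `skipped` data.frame.
#' @export
behaviour_ud_set <- function(fixes, h, levels = c(0.5, 0.75, 0.95),
                             min_fixes = 10, grid = NULL, seed = NULL) {
  if (is.null(grid)) grid <- make_ud_grid(fixes, h)
  subsets <- list(all = fixes)
  for (s in .state_names) subsets[[s]] <- fixes[fixes$state == s, ,
                                                drop = FALSE]
  samp <- try(subsample_control(fixes, seed = seed), silent = TRUE)
  if (!inherits(samp, "try-error")) subsets$sample <- samp
  uds <- list(); isos <- list()
  skipped <- data.frame(subset = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (nm in names(subsets)) {
    pts <- subsets[[nm]]
    if (nrow(pts) < min_fixes) {
      skipped <- rbind(skipped, data.frame(
        subset = nm, reason = sprintf("%d fixes < min_fixes = %d",
                                      nrow(pts), min_fixes)))
      next
    }
    ud <- compute_ud(pts, h, grid)
    uds[[nm]] <- ud
    isos[[nm]] <- setNames(
      lapply(levels, function(l) isopleth(ud, l)),
      as.character(levels))
  }
  if (inherits(samp, "try-error")) {
    skipped <- rbind(skipped, data.frame(
      subset = "sample", reason = "a behaviour has zero fixes"))
  }
  if (nrow(skipped)) {
    message("behaviour_ud_set: skipped ", nrow(skipped), " subset(s): ",
            paste(skipped$subset, collapse = ", "))
  }
  list(isopleths = isos, uds = uds, h = h, grid = grid, skipped = skipped)
}
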