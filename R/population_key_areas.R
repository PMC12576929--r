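#' Representativeness of a tracked sample
#'
#' Bootstrap inclusion analysis: for each sample size k = 1..N-1,
#' repeatedly draw k individuals, pool their locations into a UD on a
#' common grid, and measure the fraction of the held-out individuals'
#' locations falling inside the pooled level-isopleth. A
#' Michaelis-Menten saturating curve, inclusion = a k / (b + k), is
#' fitted to the mean inclusion rates, and representativeness is the
#' predicted inclusion at k = N as a percentage of the asymptote a,
#' i.e. 100 N / (b + N), capped at 100.
#'
#' Pooled UDs are assembled as point-count-weighted averages of the
#' individuals' per-UD grids (mathematically identical to a KDE of the
#' pooled points), so the bootstrap is cheap.
#'
#' @param loc_sets Named list of per-individual location data.frames
#'   (`x`, `y` in km).
#' @param h Bandwidth (km).
#' @param level Isopleth level used for inclusion (default 0.5, the
#'   core-area level used downstream).
#' @param n_iterations Bootstrap draws per sample size (default 50).
#' @param seed Seed.
#' @param grid Optional shared grid (built from all locations pooled if
#'   omitted).
#' @return List of class `bk_repassess`: `representativeness` (percent),
#'   `usable` (representativeness computed and >= threshold handled by
#'   caller), `curve` (data.frame k, mean inclusion), `fit` (a, b),
#'   `n_individuals`, `reason` when unusable.
#' @export
assess_representativeness <- function(loc_sets, h, level = 0.5,
                                      n_iterations = 50, seed = NULL,
                                      grid = NULL) {
  N <- length(loc_sets)
  out <- list(n_individuals = N, usable = FALSE,
              representativeness = NA_real_, curve = NULL, fit = NULL)
  class(out) <- "bk_repassess"
  if (N < 3) {
    out$reason <- "fewer than 3 individuals"
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  pooled <- do.call(rbind, lapply(loc_sets, function(d) d[, c("x", "y")]))
  if (is.null(grid)) grid <- make_ud_grid(pooled, h)
  dens <- lapply(loc_sets, function(d) compute_ud(d, h, grid)$density)
  npts <- vapply(loc_sets, nrow, numeric(1))
  cell_area <- grid$cell^2

  inclusion <- matrix(NA_real_, N - 1, n_iterations)
  for (k in seq_len(N - 1)) {
    for (it in seq_len(n_iterations)) {
      pick <- sample.int(N, k)
      w <- npts[pick] / sum(npts[pick])
      dsum <- Reduce(`+`, Map(function(d, wi) d * wi, dens[pick], w))
      dsum <- dsum / (sum(dsum) * cell_area)
      v <- as.vector(dsum)
      ord <- order(v, decreasing = TRUE)
      kk <- which(cumsum(v[ord]) * cell_area >= level)[1]
      thr <- v[ord[ifelse(is.na(kk), length(ord), kk)]]
      mask <- dsum >= thr
      held <- do.call(rbind, lapply(loc_sets[-pick],
                                    function(d) d[, c("x", "y")]))
      ix <- pmin(pmax(round((held$x - grid$x[1]) / grid$cell) + 1, 1),
                 length(grid$x))
      iy <- pmin(pmax(round((held$y - grid$y[1]) / grid$cell) + 1, 1),
                 length(grid$y))
      inclusion[k, it] <- mean(mask[cbind(ix, iy)])
    }
  }
  curve <- data.frame(k = seq_len(N - 1),
                      inclusion = rowMeans(inclusion))
  out$curve <- curve
  fit <- try(minpack.lm::nlsLM(
    inclusion ~ a * k / (b + k), data = curve,
    start = list(a = max(curve$inclusion), b = 1),
    lower = c(1e-6, 1e-6), upper = c(1, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out$reason <- "saturating-curve fit failed"
    return(out)
  }
  ab <- stats::coef(fit)
  out$fit <- list(a = unname(ab["a"]), b = unname(ab["b"]))
  out$representativeness <- min(100, 100 * N / (ab[["b"]] + N))
  out$usable <- TRUE
  out
}

#' Delineate a population-level key area
#'
#' On a common colony grid, each cell's value is the percentage of the
#' source population predicted to use it: (fraction of tracked
#' individuals whose isopleth covers the cell) x (representativeness /
#' 100) x 100. Cells at or above `threshold_pct` are retained and
#' dissolved into the key-area polygon.
#'
#' @param isopleths Named list of per-individual `bk_isopleth` objects
#'   sharing one grid.
#' @param representativeness Percent (0-100) from
#'   [assess_representativeness()].
#' @param threshold_pct Source-population threshold (default 10).
#' @param min_individuals Minimum tracked individuals required for a
#'   population-level estimate (default 8; lower only for synthetic
#'   experiments).
#' @return List of class `bk_keyarea`: `area_km2`, `mask`, `surface`
#'   (percent-of-population matrix), `rings`, `threshold_pct`,
#'   `representativeness`, grid vectors.
#' @export
find_site <- function(isopleths, representativeness, threshold_pct = 10,
                      min_individuals = 8) {
  stopifnot(representativeness >= 0, representativeness <= 100)
  if (length(isopleths) < min_individuals) {
    stop("need >= ", min_individuals,
         " individuals for a population-level key area", call. = FALSE)
  }
  dims <- dim(isopleths[[1]]$mask)
  for (iso in isopleths) stopifnot(identical(dim(iso$mask), dims))
  frac <- Reduce(`+`, lapply(isopleths, function(i) i$mask * 1)) /
    length(isopleths)
  surface <- frac * (representativeness / 100) * 100
  mask <- surface >= threshold_pct
  g1 <- isopleths[[1]]
  out <- list(
    area_km2 = sum(mask) * g1$cell^2,
    mask = mask, surface = surface,
    rings = .mask_rings(mask, g1$x, g1$y, g1$cell),
    threshold_pct = threshold_pct,
    representativeness = representativeness,
    n_individuals = length(isopleths),
    x = g1$x, y = g1$y, cell = g1$cell)
  class(out) <- "bk_keyarea"
  if (out$area_km2 == 0) {
    message("find_site: no cell reached the ", threshold_pct,
            "% population threshold (empty key area)")
  }
  out
}

#' Key-area size comparison table
#'
#' Tidy rows (colony, subset, level, area_km2, log10_area) for the
#' mixed-model comparison of key-area sizes; colonies excluded by the
#' representativeness rule are listed in the `exclusions` attribute.
#'
#' @param estimates `data.frame` with columns `colony_id`, `subset`,
#'   `level`, `area_km2`, `representativeness`, one row per key-area
#'   estimate.
#' @param rep_threshold Minimum representativeness percent for a colony
#'   to enter the comparison (default 70).
#' @export
compare_key_area_sizes <- function(estimates, rep_threshold = 70) {
  ok <- estimates$representativeness >= rep_threshold &
    estimates$area_km2 > 0
  excl <- estimates[!ok, c("colony_id", "subset", "representativeness",
                           "area_km2")]
  tab <- estimates[ok, , drop = FALSE]
  tab$log10_area <- log10(tab$area_km2)
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- excl
  if (nrow(excl)) {
    message("compare_key_area_sizes: excluded ", nrow(excl),
            " estimate(s) (representativeness < ", rep_threshold,
            "% or empty)")
  }
  tab
}
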