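#' Proportion of a behaviour isopleth captured by the all-behaviour
#' isopleth
#'
#' Both isopleths must be at the same level on the same grid; the
#' proportion is computed exactly as a cell-set intersection:
#' area(behaviour AND all) / area(behaviour). With `mode = "mass"` the
#' overlap is instead the fraction of the behaviour UD's probability
#' mass lying inside the all-behaviour isopleth (requires `beh_ud`).
#'
#' @param beh_iso,all_iso `bk_isopleth` objects on a shared grid.
#' @param mode "area" (default) or "mass".
#' @param beh_ud The behaviour `bk_ud`, needed for `mode = "mass"`.
#' @return Capture proportion x in [0, 1].
#' @export
capture_proportion <- function(beh_iso, all_iso, mode = c("area", "mass"),
                               beh_ud = NULL) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(beh_iso$mask), dim(all_iso$mask)),
            isTRUE(all.equal(beh_iso$cell, all_iso$cell)))
  if (mode == "area") {
    nb <- sum(beh_iso$mask)
    if (nb == 0) stop("behaviour isopleth has zero area", call. = FALSE)
    sum(beh_iso$mask & all_iso$mask) / nb
  } else {
    stopifnot(!is.null(beh_ud))
    sum(beh_ud$density[all_iso$mask]) * beh_ud$cell^2
  }
}

#' Boundary-avoiding proportion transform
#'
#' Shrinks proportions away from exact 0 and 1 so a beta likelihood is
#' defined: x_dot = (x (N - 1) + 0.5) / N, with N the number of records
#' in the dataset. Strictly monotone; [inverse_transform_proportion()]
#' recovers x.
#'
#' @param x Proportions in [0, 1].
#' @param N Sample size (>= 1).
#' @export
transform_proportion <- function(x, N) {
  if (any(N < 1)) stop("N must be >= 1", call. = FALSE)
  stopifnot(all(x >= 0 & x <= 1))
  (x * (N - 1) + 0.5) / N
}

#' @rdname transform_proportion
#' @param x_dot Transformed proportions.
#' @export
inverse_transform_proportion <- function(x_dot, N) {
  (x_dot * N - 0.5) / (N - 1)
}

#' Assemble the behaviour-capture comparison table
#'
#' One record per individual and available subset (resting, foraging,
#' transiting, sample): the proportion of that subset's isopleth
#' captured within the individual's all-behaviour isopleth at the given
#' level, plus the boundary-avoiding transform using the dataset-level
#' record count N. Colony-weighted grand means (weights = individuals
#' per colony) are attached as attribute `grand_means`.
#'
#' @param ud_sets Named list (by individual id) of results from
#'   [behaviour_ud_set()]; each must carry the individual's colony in
#'   `colony_id` (set by the caller) or supply `colony_of`.
#' @param level Isopleth level to compare at.
#' @param colony_of Named character vector mapping individual id to
#'   colony id.
#' @param mode Passed to [capture_proportion()].
#' @return `data.frame` with columns `individual_id`, `colony_id`,
#'   `subset`, `level`, `x`, `x_transformed`.
#' @export
overlap_table <- function(ud_sets, level, colony_of,
                          mode = c("area", "mass")) {
  mode <- match.arg(mode)
  lev_key <- as.character(level)
  recs <- list()
  for (ind in names(ud_sets)) {
    us <- ud_sets[[ind]]
    if (is.null(us$isopleths$all)) next
    all_iso <- us$isopleths$all[[lev_key]]
    for (subset in c("resting", "foraging", "transiting", "sample")) {
      if (is.null(us$isopleths[[subset]])) next
      x <- capture_proportion(us$isopleths[[subset]][[lev_key]], all_iso,
                              mode = mode, beh_ud = us$uds[[subset]])
      recs[[length(recs) + 1]] <- data.frame(
        individual_id = ind, colony_id = unname(colony_of[[ind]]),
        subset = subset, level = level, x = x, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, recs)
  if (is.null(tab)) return(data.frame())
  N <- nrow(tab)
  tab$x_transformed <- transform_proportion(tab$x, N)

  # colony-weighted grand means per subset
  n_ind <- tapply(tab$individual_id, tab$colony_id,
                  function(v) length(unique(v)))
  gm <- vapply(unique(tab$subset), function(ss) {
    sub <- tab[tab$subset == ss, ]
    per_col <- tapply(sub$x, sub$colony_id, mean)
    w <- n_ind[names(per_col)]
    sum(per_col * w) / sum(w)
  }, numeric(1))
  attr(tab, "grand_means") <- gm
  attr(tab, "N") <- N
  tab
}
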