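# Three-stage location sampling: one point per street-network link, a simple
# random stage-two subset, then year-prioritised panorama selection with a
# two-opposite-headings restriction; plus stabilisation diagnostics for the
# running presence proportions.

#' Sampling plan for location selection
#'
#' @param stage2_n Locations drawn (without replacement) in stage two.
#' @param target_locations Locations retained after year-priority selection;
#'   each yields two images, so the default targets 2000 images per city.
#' @param year_priority Ordered preference over panorama years: all locations
#'   offering the first year are taken before any location of the second, and
#'   so on.
#' @param headings Two opposite compass headings (must differ by 180 degrees);
#'   four headings are deliberately not supported because adjacent fields of
#'   view overlap and double-count road users.
#' @return A validated list of class `sc_sampling_plan`.
#' @export
sampling_plan <- function(stage2_n = 2000, target_locations = 1000,
                          year_priority = c(2011, 2012, 2010, 2009, 2008),
                          headings = c(0, 180)) {
  if (stage2_n < target_locations)
    stop("'stage2_n' must be >= 'target_locations'", call. = FALSE)
  if (length(year_priority) == 0 || anyDuplicated(year_priority))
    stop("'year_priority' must be non-empty with no duplicates", call. = FALSE)
  if (length(headings) != 2 || (abs(headings[2] - headings[1]) %% 360) != 180)
    stop("'headings' must be two directions differing by 180 degrees",
         call. = FALSE)
  structure(list(stage2_n = stage2_n, target_locations = target_locations,
                 year_priority = year_priority, headings = headings),
            class = "sc_sampling_plan")
}

#' Stage one: sample one point on each network link
#'
#' Positions are uniform along each link's length, independently across links.
#'
#' @param network Data frame of links with columns `link_id`, `x0`, `y0`,
#'   `x1`, `y1`, `length` (all lengths strictly positive).
#' @param seed Integer seed.
#' @return Data frame with one row per link: `link_id`, `x`, `y` and the
#'   fractional position `t` along the link.
#' @export
sample_link_points <- function(network, seed) {
  if (is.null(network) || nrow(network) == 0)
    stop("network is empty: no links to sample", call. = FALSE)
  bad <- network$length <= 0
  if (any(bad))
    stop("zero-length link(s): ",
         paste(network$link_id[bad], collapse = ", "), call. = FALSE)
  set.seed(seed)
  t <- runif(nrow(network))
  data.frame(link_id = network$link_id,
             x = network$x0 + t * (network$x1 - network$x0),
             y = network$y0 + t * (network$y1 - network$y0),
             t = t)
}

#' Stage two: simple random sample of locations
#'
#' @param points Data frame of candidate points (one per link).
#' @param plan A [sampling_plan()].
#' @param seed Integer seed.
#' @return A subset of `points` with `plan$stage2_n` rows, in draw order.
#' @export
stage2_sample <- function(points, plan, seed) {
  n <- nrow(points)
  if (n < plan$stage2_n)
    stop("cannot draw ", plan$stage2_n, " locations from ", n,
         " candidate points (short by ", plan$stage2_n - n, ")",
         call. = FALSE)
  set.seed(seed)
  points[sample.int(n, plan$stage2_n), , drop = FALSE]
}

#' Stage three: year-prioritised panorama selection
#'
#' Locations are filled strictly in the plan's year-preference order: every
#' location offering a panorama from the first priority year is taken before
#' any location whose best offering is the second year, and so on. When a
#' priority rank is only partially needed, a seeded random subset of its
#' eligible locations fills the remainder. No location is repeated; locations
#' with no panorama in any priority year are excluded entirely.
#'
#' @param metadata Data frame of panorama metadata for one city: `loc_id`,
#'   `pano_id`, `year` (plus any carried columns such as `month`). Locations
#'   with no rows simply never appear.
#' @param plan A [sampling_plan()].
#' @param seed Integer seed for the partial-rank filler subset.
#' @return Data frame of selected panoramas (one per location) with a
#'   `year_rank` column; carries attribute `shortfall` (locations missing
#'   from target, 0 when the target was met) — fewer eligible locations than
#'   the target is reported via this flag, not an error.
#' @export
select_by_year <- function(metadata, plan, seed) {
  pri <- plan$year_priority
  md <- metadata[metadata$year %in% pri, , drop = FALSE]
  if (nrow(md) > 0) {
    md$year_rank <- match(md$year, pri)
    # best (lowest) rank per location; deterministic pano choice within a year
    md <- md[order(md$loc_id, md$year_rank, md$pano_id), , drop = FALSE]
    md <- md[!duplicated(md$loc_id), , drop = FALSE]
  } else {
    md$year_rank <- integer(0)
  }
  target <- plan$target_locations
  chosen <- md[0, , drop = FALSE]
  set.seed(seed)
  for (r in seq_along(pri)) {
    need <- target - nrow(chosen)
    if (need <= 0) break
    pool <- md[md$year_rank == r, , drop = FALSE]
    if (nrow(pool) <= need) {
      chosen <- rbind(chosen, pool)
    } else {
      chosen <- rbind(chosen, pool[sample.int(nrow(pool), need), , drop = FALSE])
    }
  }
  shortfall <- max(0L, target - nrow(chosen))
  if (shortfall > 0)
    warning("only ", nrow(chosen), " locations eligible for target ",
            target, call. = FALSE)
  attr(chosen, "shortfall") <- shortfall
  chosen
}

#' Stabilisation diagnostics for running presence proportions
#'
#' For each road-user category, tracks the running proportion of images with
#' at least one observation as images accumulate, and reports the smallest
#' sample size at which every category's running proportion has settled: the
#' range of the running proportion over the trailing `window` images falls
#' below `tol` for all categories simultaneously.
#'
#' @param annotations Annotation data frame (rows in observation order) with
#'   `bin_<mode>` columns.
#' @param window Trailing window length in images (>= 2).
#' @param tol Absolute tolerance on the running-proportion fluctuation.
#' @return An object of class `sc_stabilisation`: list with `curve` (matrix of
#'   running proportions, one column per mode), `stabilised_at` (integer index
#'   or `NA` if never stabilised), `window`, `tol`.
#' @export
stabilisation <- function(annotations, window = 100, tol = 0.005) {
  if (window < 2) stop("'window' must be >= 2", call. = FALSE)
  modes <- annotation_modes()
  pres <- sapply(modes, function(m) annotations[[paste0("bin_", m)]] != "0")
  pres <- matrix(as.numeric(pres), ncol = length(modes),
                 dimnames = list(NULL, modes))
  n <- nrow(pres)
  curve <- apply(pres, 2, function(p) cumsum(p) / seq_len(n))
  curve <- matrix(curve, ncol = length(modes),
                  dimnames = list(NULL, modes))
  stabilised_at <- NA_integer_
  if (n >= window) {
    for (i in window:n) {
      rng <- apply(curve[(i - window + 1):i, , drop = FALSE], 2,
                   function(z) diff(range(z)))
      if (all(rng < tol)) { stabilised_at <- i; break }
    }
  }
  structure(list(curve = curve, stabilised_at = stabilised_at,
                 window = window, tol = tol),
            class = "sc_stabilisation")
}

#' @export
print.sc_stabilisation <- function(x, ...) {
  cat("Stabilisation of running presence proportions\n")
  cat("  images:        ", nrow(x$curve), "\n")
  cat("  window / tol:  ", x$window, "/", x$tol, "\n")
  cat("  stabilised at: ",
      if (is.na(x$stabilised_at)) "never" else x$stabilised_at, "\n")
  invisible(x)
}
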