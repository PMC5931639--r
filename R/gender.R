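# Cyclist gender-split analysis: cities sorted by the census cycling gender
# ratio are cut into contiguous groups with balanced observation totals;
# group-level ratios from observed counts are compared with survey-weighted
# average ratios.

#' Partition cities into contiguous groups with balanced observation totals
#'
#' Cities must be supplied sorted ascending by the census cycling gender
#' ratio (or the function sorts them when `ratio_col` is present). The cut
#' points are chosen by exhaustive search over all contiguous k-partitions,
#' minimising the variance of the group observation totals; ties are broken
#' by the smallest sum of within-group ranges of the sorting ratio.
#'
#' @param observations Data frame with `city_id`, `females`, `males`
#'   (nonnegative integer counts) and optionally `ratio_col`.
#' @param k Number of groups.
#' @param ratio_col Column used to sort cities (default `Census_Cycle_MF`);
#'   if absent, the rows are taken as already sorted.
#' @return The input rows (sorted) with an added integer `group` column;
#'   attribute `cuts` holds the last index of each of the first k - 1 groups.
#' @export
partition_cities <- function(observations, k = 4,
                             ratio_col = "Census_Cycle_MF") {
  n <- nrow(observations)
  if (k > n) stop("cannot form ", k, " groups from ", n, " cities",
                  call. = FALSE)
  obs <- observations
  if (ratio_col %in% names(obs)) obs <- obs[order(obs[[ratio_col]]), ,
                                            drop = FALSE]
  totals <- obs$females + obs$males
  if (any(totals < 0) || any(totals != round(totals)))
    stop("'females' and 'males' must be nonnegative integer counts",
         call. = FALSE)
  csum <- cumsum(totals)
  ratio <- if (ratio_col %in% names(obs)) obs[[ratio_col]] else seq_len(n)
  cuts_all <- utils::combn(n - 1, k - 1)
  best <- NULL; best_var <- Inf; best_tie <- Inf
  for (j in seq_len(ncol(cuts_all))) {
    cut <- cuts_all[, j]
    bounds <- c(0, cut, n)
    sums <- csum[c(cut, n)] - c(0, csum[cut])
    v <- stats::var(sums)
    if (v > best_var + 1e-12) next
    tie <- sum(vapply(seq_len(k), function(g)
      diff(range(ratio[(bounds[g] + 1):bounds[g + 1]])), numeric(1)))
    if (v < best_var - 1e-12 || (abs(v - best_var) <= 1e-12 && tie < best_tie)) {
      best <- cut; best_var <- v; best_tie <- tie
    }
  }
  grp <- findInterval(seq_len(n), c(0, best) + 1)
  obs$group <- grp
  rownames(obs) <- NULL
  attr(obs, "cuts") <- best
  obs
}

#' Group-level gender ratios from observed counts
#'
#' The ratio within a group is the pooled male count divided by the pooled
#' female count (not an average of city ratios); the overall row pools all
#' groups.
#'
#' @param partition Data frame with `group`, `females`, `males` (as returned
#'   by [partition_cities()]).
#' @return Data frame with one row per group plus an `"All"` row: `group`,
#'   `females`, `males`, `ratio`. A group with zero females gets `NA` ratio
#'   (undefined, not infinity).
#' @export
group_ratios <- function(partition) {
  groups <- sort(unique(partition$group))
  rows <- lapply(groups, function(g) {
    sub <- partition[partition$group == g, , drop = FALSE]
    f <- sum(sub$females); m <- sum(sub$males)
    data.frame(group = as.character(g), females = f, males = m,
               ratio = if (f > 0) m / f else NA_real_)
  })
  all_f <- sum(partition$females); all_m <- sum(partition$males)
  rbind(data.frame(group = "All", females = all_f, males = all_m,
                   ratio = if (all_f > 0) all_m / all_f else NA_real_),
        do.call(rbind, rows))
}

#' Observation-weighted average of city-level survey ratios
#'
#' @param ratios Per-city survey gender ratios.
#' @param weights Per-city gender observation counts (nonnegative, not all
#'   zero).
#' @return `sum(w * r) / sum(w)`.
#' @export
weighted_average_ratio <- function(ratios, weights) {
  if (length(ratios) != length(weights))
    stop("'ratios' and 'weights' must have equal length", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(weights) == 0) stop("all weights are zero", call. = FALSE)
  sum(weights * ratios) / sum(weights)
}

#' Full gender-split comparison table
#'
#' Partitions the cities, computes the observed male/female ratio per group
#' and overall, and appends observation-weighted averages of the supplied
#' survey ratio columns.
#'
#' @param observations Data frame with `city_id`, `females`, `males` and the
#'   survey ratio columns.
#' @param k Number of groups.
#' @param survey_cols Survey ratio columns to average (skipped if absent).
#' @param ratio_col Sorting column (see [partition_cities()]).
#' @return Data frame shaped like the published comparison: one row per group
#'   plus `"All"`, with observed counts, the observed ratio and one weighted
#'   column per survey measure.
#' @export
gender_split_table <- function(observations, k = 4,
                               survey_cols = c("Census_Cycle_MF",
                                               "APS_Prev_All_Cycle_MF",
                                               "APS_Prev_Utly_Cycle_MF"),
                               ratio_col = "Census_Cycle_MF") {
  part <- partition_cities(observations, k = k, ratio_col = ratio_col)
  out <- group_ratios(part)
  w <- part$females + part$males
  for (sc in intersect(survey_cols, names(part))) {
    vals <- vapply(out$group, function(g) {
      sel <- if (g == "All") rep(TRUE, nrow(part)) else part$group == as.integer(g)
      ok <- sel & !is.na(part[[sc]]) & w > 0
      if (!any(ok)) return(NA_real_)
      weighted_average_ratio(part[[sc]][ok], w[ok])
    }, numeric(1))
    out[[paste0("weighted_", sc)]] <- vals
  }
  out
}
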