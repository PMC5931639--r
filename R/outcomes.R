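# Surveillance outcomes: census commute mode shares, survey walking/cycling
# measures, local-authority to city-region aggregation, gender ratios, and
# the city-level CSV dialect used for deposited data.

#' Canonical column names of the city-level outcome/feature CSV dialect
#' @param aps Include the survey (APS-style) block?
#' @return Character vector of column names.
#' @export
s2_columns <- function(aps = TRUE) {
  base <- c("city_id", gsv_predictor_cols(), gsv_month_cols(),
            "Census_Walk", "Census_Cycle", "Census_MC", "Census_Bus",
            "Census_PTWalk", "Census_Car", "Census_Cycle_MF")
  aps_cols <- c("APS_Prev_All_Cycle", "APS_Days_All_Cycle",
                "APS_Duration_All_Cycle", "APS_Prev_Utly_Cycle",
                "APS_Days_Utly_Cycle", "APS_Duration_Utly_Cycle",
                "APS_Prev_All_Walk", "APS_Days_All_Walk",
                "APS_Duration_All_Walk", "APS_Prev_Utly_Walk",
                "APS_Days_Utly_Walk", "APS_Duration_Utly_Walk",
                "APS_Prev_All_Cycle_MF", "APS_Prev_Utly_Cycle_MF")
  if (aps) c(base, aps_cols) else base
}

#' Commute mode shares from commuter counts
#'
#' Shares are percentages of all commuters excluding those working from home.
#' Car combines driving, passenger and taxi; PT+Walk combines walking, bus,
#' underground and train.
#'
#' @param counts Named numeric vector of commuter counts. Recognised names:
#'   `walk`, `cycle`, `bus`, `underground`, `train`, `car_driving`,
#'   `car_passenger`, `taxi`, `car` (already-aggregated alternative to the
#'   three car components), `mc` (or `motorcycle`), `other`, and `home`
#'   (excluded from the denominator).
#' @return Named numeric vector of percentages: `Walk`, `Cycle`, `MC`, `Bus`,
#'   `Car`, `PTWalk`.
#' @export
compute_mode_shares <- function(counts) {
  if (any(counts < 0)) stop("commuter counts must be nonnegative", call. = FALSE)
  get <- function(...) sum(counts[intersect(c(...), names(counts))])
  denom <- sum(counts[setdiff(names(counts), "home")])
  if (denom <= 0) stop("zero commuter denominator (all home workers?)",
                       call. = FALSE)
  car <- get("car", "car_driving", "car_passenger", "taxi")
  c(Walk = 100 * get("walk") / denom,
    Cycle = 100 * get("cycle") / denom,
    MC = 100 * get("mc", "motorcycle") / denom,
    Bus = 100 * get("bus") / denom,
    Car = 100 * car / denom,
    PTWalk = 100 * get("walk", "bus", "underground", "train") / denom)
}

#' Aggregate local-authority records to city-region (PUA) level
#'
#' Commuter counts are summed across each city-region's local authorities
#' before any share computation (pooling, not averaging of shares); survey
#' measures are combined as population-weighted means, reflecting that the
#' survey is population-representative within each local authority.
#'
#' @param la_records Data frame with `la_id`, `pua_id`, count columns, an
#'   optional weight column, and optional survey columns.
#' @param count_cols Names of commuter-count columns to sum.
#' @param aps_cols Names of survey columns to average (may be `NULL`).
#' @param weight_col Weight column for the survey means (default
#'   `"population"`).
#' @return Data frame with one row per `pua_id`.
#' @export
aggregate_to_pua <- function(la_records, count_cols,
                             aps_cols = NULL, weight_col = "population") {
  if (any(is.na(la_records$pua_id)))
    stop("local authority with unknown PUA: ",
         paste(la_records$la_id[is.na(la_records$pua_id)], collapse = ", "),
         call. = FALSE)
  puas <- unique(la_records$pua_id)
  rows <- lapply(puas, function(p) {
    sub <- la_records[la_records$pua_id == p, , drop = FALSE]
    out <- data.frame(pua_id = p)
    for (cc in count_cols) out[[cc]] <- sum(sub[[cc]])
    if (!is.null(aps_cols)) {
      w <- sub[[weight_col]]
      for (ac in aps_cols) out[[ac]] <- sum(w * sub[[ac]]) / sum(w)
    }
    out
  })
  do.call(rbind, rows)
}

#' Male-to-female gender ratio
#'
#' @param male_measure,female_measure Prevalence or mode share by sex.
#' @return `male/female`; `NA` (undefined, not infinity) when the female
#'   measure is zero.
#' @export
gender_ratio <- function(male_measure, female_measure) {
  ifelse(female_measure > 0, male_measure / female_measure, NA_real_)
}

normalise_header <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a city-level outcome/feature CSV
#'
#' Column-name matching is case- and punctuation-insensitive; an explicit
#' `mapping` (canonical = actual) overrides it. Cities with a missing survey
#' block get `aps_available = FALSE`; missing survey values are kept as `NA`,
#' never zeros.
#'
#' @param path CSV path, one row per city.
#' @param mapping Optional named character vector mapping canonical column
#'   names to the file's actual headers.
#' @return Data frame with canonical column names plus `aps_available`.
#' @export
read_s2 <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty city table: ", path, call. = FALSE)
  have <- normalise_header(names(df))
  canonical <- s2_columns(aps = TRUE)
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (cc in canonical) {
    actual <- if (!is.null(mapping) && cc %in% names(mapping)) {
      which(names(df) == mapping[[cc]])
    } else {
      which(have == normalise_header(cc))
    }
    if (length(actual) >= 1) out[[cc]] <- df[[actual[1]]]
  }
  mandatory <- s2_columns(aps = FALSE)
  missing <- setdiff(mandatory, names(out))
  if (length(missing) > 0)
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  aps_main <- setdiff(s2_columns(TRUE), mandatory)
  for (cc in aps_main) if (is.null(out[[cc]])) out[[cc]] <- NA_real_
  out$aps_available <- !is.na(out$APS_Prev_All_Cycle)
  pct_cols <- grep("^(Census_(Walk|Cycle|MC|Bus|PTWalk|Car)$)|APS_Prev",
                   names(out), value = TRUE)
  for (cc in pct_cols) {
    v <- out[[cc]]
    if (any(!is.na(v) & (v < 0 | v > 100)))
      warning("out-of-range values in column ", cc, call. = FALSE)
  }
  out
}

#' Write a city-level outcome/feature table as CSV
#' @param tbl Data frame as produced by the pipeline or [read_s2()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_s2 <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE)
  invisible(path)
}
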