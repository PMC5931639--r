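# Orchestration: end-to-end runs over a synthetic world or a deposited
# city-level CSV, plus descriptive summaries.

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a world, then sample, aggregate, fit,
#'   select and analyse genders) or `"s2"` (read a deposited city-level CSV,
#'   fit and correlate, with genders from an optional fixture).
#' @param seed Integer seed used for every random stage.
#' @param generator A [generator_config()] (synthetic mode).
#' @param s2_path City-level CSV path (s2 mode).
#' @param gender_path Optional per-city gender-observation CSV (s2 mode).
#' @param k_gender_groups Number of gender groups.
#' @return List of class `sc_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "s2"), seed = 1,
                            generator = generator_config(),
                            s2_path = NULL, gender_path = NULL,
                            k_gender_groups = 4) {
  mode <- match.arg(mode)
  if (mode == "s2" && is.null(s2_path))
    stop("s2 mode requires 's2_path'", call. = FALSE)
  if (mode == "synthetic") validate_generator_config(generator)
  structure(list(mode = mode, seed = seed, generator = generator,
                 s2_path = s2_path, gender_path = gender_path,
                 k_gender_groups = k_gender_groups),
            class = "sc_pipeline_config")
}

#' Run the full pipeline
#'
#' Synthetic mode: generate a world (which internally samples locations and
#' annotates images), build the city-level feature table, merge with
#' outcomes, compute the Pearson correlation matrix, fit the ten final
#' models with LOOCV, and build the gender-split table. Data-driven mode:
#' read the city-level CSV and run the same modelling and correlation
#' stages, with genders from the fixture when supplied.
#'
#' @param config A [pipeline_config()].
#' @return List of class `sc_report`: `city_table`, `correlations`, `models`
#'   (an `sc_final_models`), `gender` (or `NULL`), `descriptives`, `world`
#'   (synthetic mode only) and a `manifest` recording mode and seed. Given
#'   the same configuration the bundle is reproduced exactly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sc_pipeline_config"))
  world <- NULL
  if (config$mode == "synthetic") {
    world <- generate_world(config$generator, seed = config$seed)
    features <- build_feature_table(world$annotations)
    city_table <- merge(features, world$outcomes, by = "city_id", sort = TRUE)
    gender_obs <- merge(world$genders,
                        world$outcomes[, c("city_id", "Census_Cycle_MF",
                                           "APS_Prev_All_Cycle_MF",
                                           "APS_Prev_Utly_Cycle_MF")],
                        by = "city_id")
    gender_obs <- gender_obs[!is.na(gender_obs$Census_Cycle_MF) &
                               gender_obs$females + gender_obs$males > 0, ]
  } else {
    if (!file.exists(config$s2_path))
      stop("city-level data file not found: ", config$s2_path, call. = FALSE)
    city_table <- read_s2(config$s2_path)
    gender_obs <- NULL
    if (!is.null(config$gender_path)) {
      if (!file.exists(config$gender_path))
        stop("gender fixture not found: ", config$gender_path, call. = FALSE)
      gender_obs <- utils::read.csv(config$gender_path)
      gender_obs <- merge(gender_obs,
                          city_table[, intersect(names(city_table),
                                                 c("city_id", "Census_Cycle_MF",
                                                   "APS_Prev_All_Cycle_MF",
                                                   "APS_Prev_Utly_Cycle_MF"))],
                          by = "city_id")
    }
  }
  corr_cols <- intersect(c(gsv_predictor_cols(), "Census_Walk", "Census_Cycle",
                           "Census_MC", "Census_Bus", "Census_PTWalk",
                           "Census_Car", "APS_Prev_All_Cycle",
                           "APS_Prev_Utly_Cycle", "APS_Prev_All_Walk",
                           "APS_Prev_Utly_Walk"), names(city_table))
  correlations <- correlation_matrix(city_table, cols = corr_cols)
  models <- fit_final_models(city_table)
  gender <- if (!is.null(gender_obs) && nrow(gender_obs) >= config$k_gender_groups)
    gender_split_table(gender_obs, k = config$k_gender_groups) else NULL
  descriptives <- summarise_descriptives(
    city_table[, setdiff(corr_cols, "city_id"), drop = FALSE])
  structure(list(city_table = city_table, correlations = correlations,
                 models = models, gender = gender,
                 descriptives = descriptives, world = world,
                 manifest = list(mode = config$mode, seed = config$seed,
                                 n_cities = nrow(city_table))),
            class = "sc_report")
}

#' @export
print.sc_report <- function(x, ...) {
  cat("Pipeline report (", x$manifest$mode, " mode, seed ",
      x$manifest$seed, ")\n", sep = "")
  cat("  cities:", x$manifest$n_cities, "\n")
  print(x$models)
  invisible(x)
}

#' Descriptive statistics per variable
#'
#' Mean, SD, minimum, quartiles (linear-interpolation convention), median and
#' maximum for each numeric column.
#'
#' @param data Data frame with at least 2 rows.
#' @param cols Columns to summarise (default: all numeric).
#' @return Data frame with one row per variable.
#' @export
summarise_descriptives <- function(data, cols = NULL) {
  if (nrow(data) < 2) stop("need at least 2 cities to summarise", call. = FALSE)
  if (is.null(cols))
    cols <- names(data)[vapply(data, is.numeric, logical(1))]
  rows <- lapply(cols, function(cc) {
    v <- data[[cc]][!is.na(data[[cc]])]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(variable = cc, mean = mean(v), sd = stats::sd(v),
               min = min(v), q25 = q[1], median = q[2], q75 = q[3],
               max = max(v))
  })
  do.call(rbind, rows)
}
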