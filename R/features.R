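# City-level predictor features from image-level count bins: presence counts
# per mode, monthly and seasonal image proportions, bootstrap uncertainty of
# the counts, and cross-city coefficients of variation.

#' GSV predictor column names (the six modes used in modelling)
#' @return Character vector of feature column names.
#' @export
gsv_predictor_cols <- function() {
  c("GSV_Walk", "GSV_Cycle", "GSV_PCycle", "GSV_Car", "GSV_Bus", "GSV_MC")
}

#' Monthly-proportion column names
#' @return Character vector `GSV_Jan` ... `GSV_Dec`.
#' @export
gsv_month_cols <- function() paste0("GSV_", month.abb)

presence_matrix <- function(annotations) {
  modes <- annotation_modes()
  ok <- count_bins()
  out <- matrix(0, nrow(annotations), length(modes),
                dimnames = list(NULL, modes))
  for (m in modes) {
    b <- annotations[[paste0("bin_", m)]]
    bad <- !(b %in% ok)
    if (any(bad))
      stop("unknown bin label for image(s): ",
           paste(utils::head(annotations$image_id[bad], 5), collapse = ", "),
           call. = FALSE)
    out[, m] <- as.numeric(b != "0")
  }
  out
}

#' Collapse count bins into per-city presence counts
#'
#' The ordinal bin magnitudes are deliberately discarded: the feature is the
#' number of images with at least one observation of each mode. Vans/trucks
#' are tallied (column `GSV_VanTruck`) but are not part of the predictor
#' block.
#'
#' @param annotations Annotation data frame with `city_id` and `bin_<mode>`
#'   columns.
#' @return Data frame with one row per city: `city_id`, `n_images`, the six
#'   `GSV_*` presence counts and `GSV_VanTruck`.
#' @export
collapse_counts <- function(annotations) {
  pres <- presence_matrix(annotations)
  cities <- sort(unique(annotations$city_id))
  counts <- rowsum(pres, group = annotations$city_id)[cities, , drop = FALSE]
  n_img <- as.vector(table(annotations$city_id)[cities])
  fn <- mode_feature_names()
  out <- data.frame(city_id = cities, n_images = n_img)
  for (m in annotation_modes()) out[[fn[[m]]]] <- counts[, m]
  rownames(out) <- NULL
  out
}

#' Monthly and seasonal image proportions per city
#'
#' Percent of each city's images captured in each calendar month, plus the
#' four season shares: spring (Mar-May), summer (Jun-Aug), autumn (Sep-Nov)
#' and winter (Dec-Feb). Images with a missing month are excluded from these
#' proportions (they still count toward presence counts).
#'
#' @param annotations Annotation data frame with `city_id` and `month`.
#' @return Data frame per city: `GSV_Jan` ... `GSV_Dec` and
#'   `GSV_Spring`, `GSV_Summer`, `GSV_Autumn`, `GSV_Winter`, all in percent.
#' @export
monthly_proportions <- function(annotations) {
  ann <- annotations[!is.na(annotations$month), , drop = FALSE]
  cities <- sort(unique(annotations$city_id))
  tab <- table(factor(ann$city_id, levels = cities),
               factor(ann$month, levels = 1:12))
  pct <- 100 * sweep(unclass(tab), 1, pmax(1, rowSums(tab)), "/")
  out <- data.frame(city_id = cities)
  for (i in 1:12) out[[gsv_month_cols()[i]]] <- pct[, i]
  out$GSV_Spring <- rowSums(pct[, 3:5, drop = FALSE])
  out$GSV_Summer <- rowSums(pct[, 6:8, drop = FALSE])
  out$GSV_Autumn <- rowSums(pct[, 9:11, drop = FALSE])
  out$GSV_Winter <- rowSums(pct[, c(12, 1, 2), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Bootstrap standard deviation of a city's presence counts
#'
#' Resamples `n` images with replacement from one city's annotations and
#' records the per-mode presence count in each of `B` bootstrap samples; the
#' reported SD is the population SD across replicates.
#'
#' @param city_annotations Annotations of a single city.
#' @param B Number of bootstrap samples.
#' @param n Resample size (defaults to the number of images).
#' @param seed Integer seed.
#' @return Named numeric vector of SDs (feature-column names), in count units.
#' @export
bootstrap_sd <- function(city_annotations, B = 5000, n = NULL, seed = 1) {
  if (is.null(city_annotations) || nrow(city_annotations) == 0)
    stop("no annotations supplied for bootstrap", call. = FALSE)
  pres <- presence_matrix(city_annotations)
  N <- nrow(pres)
  if (is.null(n)) n <- N
  set.seed(seed)
  counts <- matrix(0, B, ncol(pres))
  for (b in seq_len(B)) {
    idx <- sample.int(N, n, replace = TRUE)
    counts[b, ] <- colSums(pres[idx, , drop = FALSE])
  }
  sds <- apply(counts, 2, function(x) sqrt(mean((x - mean(x))^2)))
  names(sds) <- mode_feature_names()[colnames(pres)]
  sds
}

#' Coefficient of variation of a cross-city feature
#'
#' Sample SD (n - 1 denominator) divided by the mean.
#'
#' @param x Numeric vector (one value per city).
#' @return The CV as a single number.
#' @export
coefficient_of_variation <- function(x) {
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean",
                   call. = FALSE)
  stats::sd(x) / m
}

#' Assemble the full city-level feature table
#'
#' Joins presence counts and monthly/seasonal proportions; optionally appends
#' per-mode bootstrap SDs (`SD_<feature>` columns).
#'
#' @param annotations Annotation data frame covering all cities.
#' @param bootstrap Add bootstrap SDs?
#' @param B,seed Bootstrap parameters (see [bootstrap_sd()]).
#' @return Data frame with one row per city.
#' @export
build_feature_table <- function(annotations, bootstrap = FALSE, B = 5000,
                                seed = 1) {
  counts <- collapse_counts(annotations)
  months <- monthly_proportions(annotations)
  out <- merge(counts, months, by = "city_id", sort = TRUE)
  if (bootstrap) {
    sds <- t(sapply(out$city_id, function(cid) {
      bootstrap_sd(annotations[annotations$city_id == cid, , drop = FALSE],
                   B = B, seed = substream_seed(seed, cid, "boot"))
    }))
    colnames(sds) <- paste0("SD_", colnames(sds))
    out <- cbind(out, as.data.frame(sds))
  }
  rownames(out) <- NULL
  out
}

#' Diagnostic: cross-city spread of the car count-bin distribution
#'
#' Reports, for each non-zero bin, the per-city proportion of images in that
#' bin and its cross-city coefficient of variation. Low CVs indicate that the
#' ordinal bin split carries little between-city information beyond the
#' presence count, motivating the collapse to presence/absence.
#'
#' @param annotations Annotation data frame covering all cities.
#' @param mode Road-user category (default `"car"`).
#' @return Data frame with one row per non-zero bin: `bin`, `mean_prop`, `cv`.
#' @export
bin_profile <- function(annotations, mode = "car") {
  b <- annotations[[paste0("bin_", mode)]]
  cities <- unique(annotations$city_id)
  bins <- count_bins()[-1]
  props <- sapply(bins, function(lab) {
    vapply(cities, function(cid) {
      sel <- annotations$city_id == cid
      mean(b[sel] == lab)
    }, numeric(1))
  })
  props <- matrix(props, ncol = length(bins), dimnames = list(cities, bins))
  data.frame(bin = bins,
             mean_prop = colMeans(props),
             cv = apply(props, 2, function(x)
               if (mean(x) == 0) NA_real_ else coefficient_of_variation(x)),
             row.names = NULL)
}
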