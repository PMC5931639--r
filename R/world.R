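# Synthetic study worlds: latent cities, street networks, panorama metadata,
# image annotations, surveillance outcomes and cyclist genders, all with
# known ground truth so every downstream stage can be tested end to end.

#' Road-user categories annotated in each image
#'
#' Seven categories are recorded per image; vans/trucks are tallied but
#' excluded from the city-level predictor block.
#'
#' @return Character vector of mode identifiers.
#' @export
annotation_modes <- function() {
  c("pedestrian", "cyclist", "parked_cycle", "car", "motorcycle", "bus",
    "van_truck")
}

#' Ordinal count-bin labels used by the annotation questionnaire
#' @return Character vector of the four bin labels.
#' @export
count_bins <- function() c("0", "1-3", "4-6", ">6")

# Map annotation modes to the city-level feature column they feed.
mode_feature_names <- function() {
  c(pedestrian = "GSV_Walk", cyclist = "GSV_Cycle",
    parked_cycle = "GSV_PCycle", car = "GSV_Car",
    motorcycle = "GSV_MC", bus = "GSV_Bus", van_truck = "GSV_VanTruck")
}

#' Configuration for the synthetic-city generator
#'
#' Defaults encode the study conditions the generator emulates: 34 city
#' units, 2000 stage-two locations targeting 1000 selected locations (two
#' images each), 94\% panorama availability, a seasonal mix with near-zero
#' winter mass, sparse cyclist/bus/motorcycle presence against near-saturated
#' car presence, and a male cycling share that falls with the cycling level.
#'
#' @param n_cities Number of city units.
#' @param aps_fraction Fraction of cities carrying the survey (APS-style)
#'   outcome block; the remainder have those fields missing.
#' @param stage2_n Locations drawn per city in the second sampling stage.
#' @param target_locations Locations to retain after year-priority selection.
#' @param availability Probability that a stage-two location has at least one
#'   panorama.
#' @param network_meanlog,network_sdlog Lognormal parameters for the full-scale
#'   link-count distribution (mean about 22,760 links, maximum about 124,600).
#' @param network_scale Desk-scale multiplier applied to link counts; counts
#'   are floored at `stage2_n` so stage-two sampling is always feasible.
#' @param old_city_fraction Fraction of cities with predominantly older
#'   panorama coverage (sparse 2011/2012, richer 2009).
#' @param year_span Calendar years panoramas may carry.
#' @param share_means,share_sds Logit-scale location and spread of the latent
#'   commute shares for modes walk, cycle, bus, other_pt, mc, car (normalised
#'   to sum to one after drawing).
#' @param fixed_shares Optional named vector of shares (same names) used for
#'   every city instead of random draws; must sum to 1.
#' @param census_noise_sd Logit-scale SD of the multiplicative perturbation
#'   taking true shares to census-reported shares; 0 reproduces the truth
#'   exactly.
#' @param aps_noise Multiplier on all survey-outcome noise SDs.
#' @param rate_k Named per-mode constants linking latent shares to per-image
#'   Poisson rates (rate = k * share; parked cycles ride on the cycle share).
#' @param van_rate Constant per-image Poisson rate for vans/trucks.
#' @param summer_boost,winter_damp Multiplicative month effects on the rates
#'   of active modes (Jun-Aug and Dec-Feb respectively).
#' @param gender_a,gender_b Intercept and slope of the gender link
#'   male_share = plogis(a - b * log(cycle share)), b > 0 so that gender
#'   equality of cycling increases with the cycling level.
#' @param child_fraction Fraction of observed cyclists classified as children
#'   and excluded from gender ratios.
#' @param detection_fraction Fraction of cyclist images in which gender can be
#'   determined.
#'
#' @return A validated list of class `sc_generator_config`.
#' @export
generator_config <- function(n_cities = 34,
                             aps_fraction = 29 / 34,
                             stage2_n = 2000,
                             target_locations = 1000,
                             availability = 0.94,
                             network_meanlog = log(22760) - 0.5 * 0.8^2,
                             network_sdlog = 0.8,
                             network_scale = 1 / 4,
                             old_city_fraction = 0.15,
                             year_span = 2008:2017,
                             share_means = c(walk = 0.117, cycle = 0.027,
                                             bus = 0.083, other_pt = 0.079,
                                             mc = 0.007, car = 0.687),
                             share_sds = c(walk = 0.25, cycle = 0.65,
                                           bus = 0.40, other_pt = 0.50,
                                           mc = 0.40, car = 0.20),
                             fixed_shares = NULL,
                             census_noise_sd = 0.05,
                             aps_noise = 1,
                             rate_k = c(pedestrian = 0.87, cyclist = 0.19,
                                        parked_cycle = 0.167, car = 1.926,
                                        motorcycle = 0.69, bus = 0.127),
                             van_rate = 0.18,
                             summer_boost = 1.25,
                             winter_damp = 0.8,
                             gender_a = -0.17,
                             gender_b = 0.3,
                             child_fraction = 0.19,
                             detection_fraction = 0.52) {
  cfg <- list(n_cities = n_cities, aps_fraction = aps_fraction,
              stage2_n = stage2_n, target_locations = target_locations,
              availability = availability,
              network_meanlog = network_meanlog,
              network_sdlog = network_sdlog, network_scale = network_scale,
              old_city_fraction = old_city_fraction, year_span = year_span,
              share_means = share_means, share_sds = share_sds,
              fixed_shares = fixed_shares,
              census_noise_sd = census_noise_sd, aps_noise = aps_noise,
              rate_k = rate_k, van_rate = van_rate,
              summer_boost = summer_boost, winter_damp = winter_damp,
              gender_a = gender_a, gender_b = gender_b,
              child_fraction = child_fraction,
              detection_fraction = detection_fraction)
  validate_generator_config(cfg)
  class(cfg) <- "sc_generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  need_count <- function(field, min = 1) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min)
      stop("invalid generator config: '", field, "' must be a number >= ",
           min, call. = FALSE)
  }
  need_prob <- function(field) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("invalid generator config: '", field, "' must lie in [0, 1]",
           call. = FALSE)
  }
  need_count("n_cities"); need_count("stage2_n"); need_count("target_locations")
  need_prob("aps_fraction"); need_prob("availability")
  need_prob("old_city_fraction"); need_prob("child_fraction")
  need_prob("detection_fraction")
  if (cfg$stage2_n < cfg$target_locations)
    stop("invalid generator config: 'stage2_n' must be >= 'target_locations'",
         call. = FALSE)
  if (cfg$network_scale <= 0)
    stop("invalid generator config: 'network_scale' must be positive",
         call. = FALSE)
  if (cfg$census_noise_sd < 0)
    stop("invalid generator config: 'census_noise_sd' must be nonnegative",
         call. = FALSE)
  if (cfg$aps_noise < 0)
    stop("invalid generator config: 'aps_noise' must be nonnegative",
         call. = FALSE)
  if (any(cfg$rate_k < 0))
    stop("invalid generator config: 'rate_k' entries must be nonnegative",
         call. = FALSE)
  if (!is.null(cfg$fixed_shares)) {
    fs <- cfg$fixed_shares
    if (any(fs < 0) || abs(sum(fs) - 1) > 1e-8)
      stop("invalid generator config: 'fixed_shares' must be nonnegative and sum to 1",
           call. = FALSE)
  }
  invisible(cfg)
}

# Stable 31-adic hash of a string, used to expand one global seed into
# independent per-city substreams: adding a city never perturbs the draws of
# any other city.
stable_hash <- function(s) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  h
}

substream_seed <- function(seed, id, salt = "") {
  as.integer((as.numeric(seed) + 1000003 * stable_hash(paste0(id, ":", salt))) %%
               2147483647)
}

# Jittered-grid planar street network with n_links positive-length segments.
make_street_network <- function(city_id, n_links, seed) {
  set.seed(substream_seed(seed, city_id, "network"))
  m <- ceiling(sqrt(n_links / 2)) + 1  # nodes per grid side
  gx <- matrix(rep(seq_len(m), m), m, m)
  gy <- matrix(rep(seq_len(m), each = m), m, m)
  jx <- gx + matrix(runif(m * m, -0.35, 0.35), m, m)
  jy <- gy + matrix(runif(m * m, -0.35, 0.35), m, m)
  # horizontal then vertical edges between neighbouring jittered nodes
  h <- cbind(x0 = as.vector(jx[-m, ]), y0 = as.vector(jy[-m, ]),
             x1 = as.vector(jx[-1, ]), y1 = as.vector(jy[-1, ]))
  v <- cbind(x0 = as.vector(jx[, -m]), y0 = as.vector(jy[, -m]),
             x1 = as.vector(jx[, -1]), y1 = as.vector(jy[, -1]))
  e <- rbind(h, v)[seq_len(n_links), , drop = FALSE]
  net <- data.frame(link_id = paste0(city_id, "_L", seq_len(n_links)), e)
  net$length <- sqrt((net$x1 - net$x0)^2 + (net$y1 - net$y0)^2)
  # centre the coordinates on the city centroid
  cx <- mean(c(net$x0, net$x1)); cy <- mean(c(net$y0, net$y1))
  net$x0 <- net$x0 - cx; net$x1 <- net$x1 - cx
  net$y0 <- net$y0 - cy; net$y1 <- net$y1 - cy
  net$city_id <- city_id
  net
}

# Latent per-city truths: population, link count, commute shares, gender link,
# seasonal month mix and panorama-year coverage profile.
draw_latent_city <- function(city_id, cfg, seed) {
  set.seed(substream_seed(seed, city_id, "latent"))
  population <- rlnorm(1, meanlog = 13.04, sdlog = 0.87)
  n_links <- max(cfg$stage2_n,
                 round(rlnorm(1, cfg$network_meanlog, cfg$network_sdlog) *
                         cfg$network_scale))
  if (is.null(cfg$fixed_shares)) {
    raw <- plogis(qlogis(cfg$share_means) +
                    rnorm(length(cfg$share_means), 0, cfg$share_sds))
    shares <- raw / sum(raw)
  } else {
    shares <- cfg$fixed_shares
  }
  names(shares) <- names(cfg$share_means)
  male_cycle_share <- plogis(cfg$gender_a - cfg$gender_b * log(shares[["cycle"]]))
  # month mix: Dirichlet concentrated on Mar-Nov, near-zero winter mass
  alpha <- c(0.02, 0.02, 1, 1, 1, 1.5, 1.5, 1.5, 1, 1, 1, 0.02)
  g <- rgamma(12, shape = alpha)
  season_mix <- g / sum(g)
  old_city <- runif(1) < cfg$old_city_fraction
  list(city_id = city_id, population = population, n_links = n_links,
       true_shares = shares, male_cycle_share = male_cycle_share,
       season_mix = season_mix, old_city = old_city)
}

# Per-location panorama metadata for the stage-two sample of one city.
# "Old" cities have sparse 2011/2012 coverage and richer 2009 coverage;
# 2010 panoramas only co-occur with 2011/2012 ones.
draw_panoramas <- function(city, points, cfg, seed) {
  set.seed(substream_seed(seed, city$city_id, "panorama"))
  n <- nrow(points)
  available <- runif(n) < cfg$availability
  if (city$old_city) {
    p_year <- c(`2008` = 0.15, `2009` = 0.45, `2011` = 0.05, `2012` = 0.10)
  } else {
    p_year <- c(`2008` = 0.04, `2009` = 0.25, `2011` = 0.22, `2012` = 0.80)
  }
  has <- sapply(p_year, function(p) runif(n) < p)  # n x 4 matrix
  has_2010 <- (has[, "2011"] | has[, "2012"]) & runif(n) < 0.12
  has_late <- runif(n) < 0.55  # 2013-2017 catch-all so availability is honest
  year_mat <- cbind(has[, "2008"], has[, "2009"], has_2010,
                    has[, "2011"], has[, "2012"], has_late)
  colnames(year_mat) <- c("2008", "2009", "2010", "2011", "2012", "late")
  # every available location must offer at least one panorama
  none <- available & rowSums(year_mat) == 0
  year_mat[none, "late"] <- TRUE
  year_mat[!available, ] <- FALSE
  rows <- which(year_mat, arr.ind = TRUE)
  yr_label <- colnames(year_mat)[rows[, 2]]
  late_year <- sample(setdiff(cfg$year_span, 2008:2012),
                      nrow(rows), replace = TRUE)
  year <- suppressWarnings(as.integer(yr_label))
  year[yr_label == "late"] <- late_year[yr_label == "late"]
  loc <- rows[, 1]
  month <- sample.int(12, nrow(rows), replace = TRUE, prob = city$season_mix)
  pan <- data.frame(city_id = city$city_id,
                    loc_id = points$loc_id[loc],
                    x = points$x[loc], y = points$y[loc],
                    year = as.integer(year), month = month)
  pan <- pan[order(pan$loc_id, pan$year), ]
  pan$pano_id <- paste0(pan$loc_id, "_Y", pan$year)
  locations <- data.frame(city_id = city$city_id, loc_id = points$loc_id,
                          x = points$x, y = points$y, available = available)
  list(locations = locations, panoramas = pan)
}

# Per-image per-mode Poisson rates for one city in one month.
mode_rates <- function(city, month, cfg) {
  shares <- city$true_shares
  lam <- c(pedestrian = cfg$rate_k[["pedestrian"]] * shares[["walk"]],
           cyclist = cfg$rate_k[["cyclist"]] * shares[["cycle"]],
           parked_cycle = cfg$rate_k[["parked_cycle"]] * shares[["cycle"]],
           car = cfg$rate_k[["car"]] * shares[["car"]],
           motorcycle = cfg$rate_k[["motorcycle"]] * shares[["mc"]],
           bus = cfg$rate_k[["bus"]] * shares[["bus"]],
           van_truck = cfg$van_rate)
  active <- c("pedestrian", "cyclist", "parked_cycle", "motorcycle")
  mult <- rep(1, length(month))
  mult[month %in% 6:8] <- cfg$summer_boost
  mult[month %in% c(12, 1, 2)] <- cfg$winter_damp
  out <- matrix(lam, nrow = length(month), ncol = length(lam), byrow = TRUE)
  colnames(out) <- names(lam)
  out[, active] <- out[, active] * mult
  out
}

#' Simulate image annotations for one city
#'
#' Each selected panorama yields two images at opposite headings (0 and 180
#' degrees). Per-image road-user counts are Poisson with
#' log-rate = base(mode) + city effect + month effect, then collapsed into the
#' ordinal bins 0 / 1-3 / 4-6 / >6 exactly as a human annotator would record
#' them. The cyclist rate is proportional to the city's latent cycle share, so
#' presence counts are monotone in the underlying cycling level.
#'
#' @param city A latent-city list as stored in `world$latent`.
#' @param panoramas Data frame of selected panoramas (`pano_id`, `loc_id`,
#'   `year`, `month`).
#' @param seed Integer seed (expanded to a city substream).
#' @param config A [generator_config()].
#' @return Data frame with one row per image: identifiers, heading, year,
#'   month and one `bin_<mode>` column per road-user category.
#' @export
simulate_annotations <- function(city, panoramas, seed,
                                 config = generator_config()) {
  set.seed(substream_seed(seed, city$city_id, "annotate"))
  if (nrow(panoramas) == 0) {
    return(empty_annotations())
  }
  idx <- rep(seq_len(nrow(panoramas)), each = 2)
  heading <- rep(c(0L, 180L), nrow(panoramas))
  lam <- mode_rates(city, panoramas$month[idx], config)
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
  bins <- matrix(bin_count(counts), nrow = nrow(lam))
  colnames(bins) <- paste0("bin_", colnames(lam))
  ann <- data.frame(image_id = paste0(panoramas$pano_id[idx], "_H", heading),
                    city_id = city$city_id,
                    loc_id = panoramas$loc_id[idx],
                    pano_id = panoramas$pano_id[idx],
                    heading = heading,
                    year = panoramas$year[idx],
                    month = panoramas$month[idx])
  cbind(ann, as.data.frame(bins))
}

empty_annotations <- function() {
  out <- data.frame(image_id = character(), city_id = character(),
                    loc_id = character(), pano_id = character(),
                    heading = integer(), year = integer(), month = integer())
  for (m in annotation_modes()) out[[paste0("bin_", m)]] <- character()
  out
}

#' Collapse raw counts into the questionnaire's ordinal bins
#' @param x Nonnegative integer counts.
#' @return Character bins among `"0"`, `"1-3"`, `"4-6"`, `">6"`.
#' @export
bin_count <- function(x) {
  as.character(cut(x, breaks = c(-0.5, 0.5, 3.5, 6.5, Inf),
                   labels = count_bins()))
}

# Survey-map constants: monotone maps from latent shares to APS-style
# measures, centred on the descriptive marginals the generator emulates.
aps_maps <- function(shares, noise_mult, rnorm1 = function(sd) rnorm(1, 0, sd)) {
  cy <- shares[["cycle"]]; wk <- shares[["walk"]]
  nm <- function(sd) rnorm1(sd * noise_mult)
  list(
    APS_Prev_All_Cycle = 100 * plogis(0.71 + 0.78 * qlogis(cy) + nm(0.15)),
    APS_Prev_Utly_Cycle = 100 * plogis(0.62 + 0.99 * qlogis(cy) + nm(0.20)),
    APS_Days_All_Cycle = max(0.05, 0.13 + 6.1 * cy + nm(0.05)),
    APS_Days_Utly_Cycle = max(0.02, 0.01 + 5.5 * cy + nm(0.04)),
    APS_Duration_All_Cycle = max(0.05, 0.19 + 4.3 * cy + nm(0.05)),
    APS_Duration_Utly_Cycle = max(0.02, 0.02 + 3.9 * cy + nm(0.04)),
    APS_Prev_All_Walk = 100 * plogis(qlogis(0.852) + 8 * (wk - 0.127) + nm(0.08)),
    APS_Prev_Utly_Walk = 100 * plogis(qlogis(0.584) + 6 * (wk - 0.127) + nm(0.15)),
    APS_Days_All_Walk = max(1, 3.56 + 4 * (wk - 0.127) + nm(0.10)),
    APS_Days_Utly_Walk = max(0.5, 2.06 + 5 * (wk - 0.127) + nm(0.12)),
    APS_Duration_All_Walk = max(1, 4.14 + 3 * (wk - 0.127) + nm(0.30)),
    APS_Duration_Utly_Walk = max(0.5, 2.65 + 2 * (wk - 0.127) + nm(0.25))
  )
}

#' Simulate surveillance outcomes for one city
#'
#' Census-style mode shares are a logistic-normal perturbation of the latent
#' true shares (noise 0 reproduces them exactly); survey-style prevalence,
#' days and duration measures are stated monotone maps of the latent walking
#' and cycling levels plus truncated Gaussian noise; gender ratios derive from
#' the latent male cycling share.
#'
#' @param city Latent-city list.
#' @param noise List with elements `census_sd` (logit-scale SD) and `aps`
#'   (multiplier on survey noise); both default to the generator defaults.
#' @param seed Integer seed.
#' @param aps_available Should the survey block be filled (TRUE) or left
#'   missing (FALSE)?
#' @return One-row data frame in the city-level outcome dialect.
#' @export
simulate_outcomes <- function(city, noise = list(census_sd = 0.05, aps = 1),
                              seed = 1, aps_available = TRUE) {
  stopifnot(noise$census_sd >= 0, noise$aps >= 0)
  set.seed(substream_seed(seed, city$city_id, "outcome"))
  sh <- city$true_shares
  pert <- sh * exp(rnorm(length(sh), 0, noise$census_sd))
  pert <- pert / sum(pert)
  mf <- city$male_cycle_share
  census_mf <- (mf / (1 - mf)) * exp(rnorm(1, 0, 0.08 * noise$aps))
  out <- data.frame(
    city_id = city$city_id,
    Census_Walk = 100 * pert[["walk"]],
    Census_Cycle = 100 * pert[["cycle"]],
    Census_MC = 100 * pert[["mc"]],
    Census_Bus = 100 * pert[["bus"]],
    Census_PTWalk = 100 * (pert[["walk"]] + pert[["bus"]] + pert[["other_pt"]]),
    Census_Car = 100 * pert[["car"]],
    Census_Cycle_MF = census_mf,
    aps_available = aps_available
  )
  aps_cols <- names(aps_maps(sh, 0, function(sd) 0))
  if (aps_available) {
    vals <- aps_maps(sh, noise$aps)
    for (nm in aps_cols) out[[nm]] <- vals[[nm]]
    ratio <- mf / (1 - mf)
    out$APS_Prev_All_Cycle_MF <- ratio * exp(rnorm(1, 0, 0.10 * noise$aps))
    out$APS_Prev_Utly_Cycle_MF <- ratio^1.3 * exp(rnorm(1, 0, 0.15 * noise$aps))
  } else {
    for (nm in c(aps_cols, "APS_Prev_All_Cycle_MF", "APS_Prev_Utly_Cycle_MF"))
      out[[nm]] <- NA_real_
  }
  out
}

#' Simulate cyclist gender observations for one city
#'
#' Gender is determinable in a configurable fraction of cyclist images; a
#' configurable fraction of observed cyclists are children (excluded from
#' ratios, matching surveys that cover ages 16+); remaining adults are male
#' with probability equal to the city's latent male cycling share.
#'
#' @param city Latent-city list.
#' @param n_cyclist_images Number of images containing at least one cyclist.
#' @param seed Integer seed.
#' @param child_fraction Probability an observed cyclist is a child.
#' @param detection_fraction Probability gender is determinable in an image.
#' @return One-row data frame with `city_id`, `females`, `males`, `children`.
#' @export
simulate_genders <- function(city, n_cyclist_images, seed,
                             child_fraction = 0.19,
                             detection_fraction = 0.52) {
  set.seed(substream_seed(seed, city$city_id, "gender"))
  n_obs <- rbinom(1, n_cyclist_images, detection_fraction)
  children <- rbinom(1, n_obs, child_fraction)
  adults <- n_obs - children
  males <- rbinom(1, adults, city$male_cycle_share)
  data.frame(city_id = city$city_id, females = adults - males,
             males = males, children = children)
}

#' Generate a complete synthetic study world
#'
#' Runs, for every city: street-network construction, stage-one sampling of
#' one point per link, stage-two simple random sampling, panorama-metadata
#' simulation, year-priority selection of locations, image annotation at two
#' opposite headings, surveillance outcomes and cyclist gender observations.
#' The result is fully deterministic given `(config, seed)` and retains the
#' latent ground truth for recovery tests.
#'
#' @param config A [generator_config()].
#' @param seed Integer global seed; per-city substreams are derived by stable
#'   hashing of the city identifier.
#' @return An object of class `sc_world`: a list with `config`, `seed`,
#'   `cities` (latent truths as a data frame), `latent` (per-city lists),
#'   `networks`, `locations`, `panoramas`, `selection`, `annotations`,
#'   `outcomes` and `genders`.
#' @examples
#' w <- generate_world(generator_config(n_cities = 2, stage2_n = 60,
#'                                      target_locations = 30), seed = 1)
#' nrow(w$outcomes)
#' @export
generate_world <- function(config = generator_config(), seed = 1) {
  validate_generator_config(config)
  plan <- sampling_plan(stage2_n = config$stage2_n,
                        target_locations = config$target_locations)
  ids <- sprintf("city%02d", seq_len(config$n_cities))
  n_aps <- round(config$n_cities * config$aps_fraction)
  latent <- lapply(ids, draw_latent_city, cfg = config, seed = seed)
  names(latent) <- ids
  networks <- list(); locations <- list(); panoramas <- list()
  selection <- list(); annotations <- list(); outcomes <- list()
  genders <- list()
  for (i in seq_along(ids)) {
    city <- latent[[i]]
    net <- make_street_network(city$city_id, city$n_links, seed)
    pts <- sample_link_points(net, substream_seed(seed, city$city_id, "stage1"))
    pts$loc_id <- paste0(city$city_id, "_P", seq_len(nrow(pts)))
    s2 <- stage2_sample(pts, plan, substream_seed(seed, city$city_id, "stage2"))
    pan <- draw_panoramas(city, s2, config, seed)
    sel <- select_by_year(pan$panoramas, plan,
                          substream_seed(seed, city$city_id, "select"))
    ann <- simulate_annotations(city, sel, seed, config)
    out <- simulate_outcomes(city,
                             noise = list(census_sd = config$census_noise_sd,
                                          aps = config$aps_noise),
                             seed = seed, aps_available = i <= n_aps)
    n_cyc <- sum(ann$bin_cyclist != "0")
    gen <- simulate_genders(city, n_cyc, seed,
                            child_fraction = config$child_fraction,
                            detection_fraction = config$detection_fraction)
    networks[[i]] <- net; locations[[i]] <- pan$locations
    panoramas[[i]] <- pan$panoramas; selection[[i]] <- sel
    annotations[[i]] <- ann; outcomes[[i]] <- out; genders[[i]] <- gen
  }
  cities <- data.frame(
    city_id = ids,
    population = vapply(latent, `[[`, numeric(1), "population"),
    n_links = vapply(latent, `[[`, numeric(1), "n_links"),
    male_cycle_share = vapply(latent, `[[`, numeric(1), "male_cycle_share"),
    old_city = vapply(latent, `[[`, logical(1), "old_city"),
    aps_available = seq_along(ids) <= n_aps
  )
  shares <- t(vapply(latent, `[[`, numeric(6), "true_shares"))
  colnames(shares) <- paste0("share_", names(config$share_means))
  cities <- cbind(cities, as.data.frame(shares))
  structure(list(config = config, seed = seed, cities = cities,
                 latent = latent, networks = networks,
                 locations = do.call(rbind, locations),
                 panoramas = do.call(rbind, panoramas),
                 selection = do.call(rbind, selection),
                 annotations = do.call(rbind, annotations),
                 outcomes = do.call(rbind, outcomes),
                 genders = do.call(rbind, genders)),
            class = "sc_world")
}

#' @export
print.sc_world <- function(x, ...) {
  cat("Synthetic street-imagery world\n")
  cat("  cities:      ", nrow(x$cities), "\n")
  cat("  locations:   ", nrow(x$locations), "\n")
  cat("  images:      ", nrow(x$annotations), "\n")
  cat("  seed:        ", x$seed, "\n")
  invisible(x)
}

#' Write a world's tabular artifacts to CSV files
#'
#' Emits `locations.csv`, `annotations.csv`, `outcomes.csv` (city-level
#' outcome dialect), `genders.csv` and `cities.csv` under `dir`.
#'
#' @param world An `sc_world`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_world <- function(world, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(locations = file.path(dir, "locations.csv"),
             annotations = file.path(dir, "annotations.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             genders = file.path(dir, "genders.csv"),
             cities = file.path(dir, "cities.csv"))
  utils::write.csv(world$locations, paths["locations"], row.names = FALSE)
  utils::write.csv(world$annotations, paths["annotations"], row.names = FALSE)
  utils::write.csv(world$outcomes, paths["outcomes"], row.names = FALSE)
  utils::write.csv(world$genders, paths["genders"], row.names = FALSE)
  utils::write.csv(world$cities, paths["cities"], row.names = FALSE)
  invisible(paths)
}
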