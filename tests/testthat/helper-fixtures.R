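# Shared fixtures, built in code. Worlds are cached per test run so the
# full-scale default world is generated once.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(key, config, seed) {
  if (is.null(.world_cache[[key]]))
    .world_cache[[key]] <- generate_world(config, seed)
  .world_cache[[key]]
}

# Full study-scale world: 34 cities, 2000 stage-two locations, 1000 selected.
default_world <- function() cached_world("default", generator_config(), 101)

small_config <- function(n_cities = 8) {
  generator_config(n_cities = n_cities, stage2_n = 150, target_locations = 80)
}

small_world <- function() cached_world("small", small_config(), 7)

city_table <- function(world) {
  merge(build_feature_table(world$annotations), world$outcomes,
        by = "city_id", sort = TRUE)
}

# A hand-built latent city for direct calls into the simulators.
latent_city <- function(city_id = "testcity", cycle = 0.027, walk = 0.117,
                        bus = 0.083, other_pt = 0.079, mc = 0.007,
                        male_cycle_share = NULL) {
  car <- 1 - (walk + cycle + bus + other_pt + mc)
  stopifnot(car > 0)
  shares <- c(walk = walk, cycle = cycle, bus = bus, other_pt = other_pt,
              mc = mc, car = car)
  if (is.null(male_cycle_share))
    male_cycle_share <- if (cycle > 0) plogis(-0.17 - 0.3 * log(cycle)) else 0.7
  list(city_id = city_id, population = 5e5, n_links = 1000,
       true_shares = shares, male_cycle_share = male_cycle_share,
       season_mix = rep(1 / 12, 12), old_city = FALSE)
}

# Panorama rows for a fixed month, enough for n_locations * 2 images.
flat_panoramas <- function(n_locations, month = 6, year = 2012,
                           prefix = "loc") {
  data.frame(city_id = "testcity",
             loc_id = paste0(prefix, seq_len(n_locations)),
             x = 0, y = 0, year = year, month = month,
             pano_id = paste0(prefix, seq_len(n_locations), "_Y", year))
}

# Annotation table with every mode "0" except explicit overrides.
blank_annotations <- function(n, city_id = "c1", month = 6) {
  ann <- data.frame(image_id = paste0(city_id, "_img", seq_len(n)),
                    city_id = city_id, loc_id = paste0("l", seq_len(n)),
                    pano_id = paste0("p", seq_len(n)), heading = 0L,
                    year = 2012L, month = month)
  for (m in annotation_modes()) ann[[paste0("bin_", m)]] <- "0"
  ann
}

# The published 4-group gender counts (overall 82 females / 172 males).
published_gender_counts <- function() {
  read.csv(system.file("extdata", "published_gender_group_counts.csv",
                       package = "streetcount"))
}

# Independent naive LOOCV: explicit loop over folds calling the public fit.
naive_loocv <- function(spec, data) {
  n <- nrow(data)
  obs <- data[[spec$outcome]]
  if (spec$percent) obs <- obs / 100
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(fit_model(spec, data[-i, , drop = FALSE]))
    pred[i] <- predict(fit, data[i, , drop = FALSE])
  }
  err <- obs - pred
  list(press = sum(err^2), mae = mean(abs(err)), mdae = median(abs(err)),
       pred = pred)
}

# Independent beta-ML oracle: Nelder-Mead maximisation of the same density
# from a neutral start, no gradient, no shared code path with fit_beta.
beta_oracle <- function(y, X) {
  negll <- function(p) {
    k <- ncol(X)
    mu <- plogis(drop(X %*% p[seq_len(k)]))
    phi <- exp(p[k + 1])
    -sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  best <- NULL
  for (start_phi in c(1, 10, 100)) {
    o <- optim(c(rep(0, ncol(X)), log(start_phi)), negll,
               method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(beta = best$par[seq_len(ncol(X))], phi = exp(best$par[ncol(X) + 1]),
       loglik = -best$value)
}

# Random small regression instances across the three families.
random_instance <- function(seed, family) {
  set.seed(seed)
  n <- sample(10:20, 1)
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2)
  if (family == "beta") {
    mu <- plogis(-0.5 + 0.6 * x1 - 0.3 * x2)
    d$y <- rbeta(n, mu * 30, (1 - mu) * 30)
  } else {
    d$y <- 1 + 0.8 * x1 - 0.5 * x2 + rnorm(n, 0, 0.4)
  }
  list(spec = model_spec("y", c("x1", "x2"), family = family), data = d)
}
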