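# The synthetic-city generator: determinism, validation, calibration of
# panorama availability and road-user presence, and ground-truth recovery.

test_that("identical config and seed reproduce the world exactly", {
  cfg <- small_config(n_cities = 3)
  w1 <- generate_world(cfg, seed = 11)
  w2 <- generate_world(cfg, seed = 11)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  w3 <- generate_world(cfg, seed = 12)
  expect_false(identical(w1$annotations, w3$annotations))
})

test_that("adding a city leaves existing cities' draws untouched", {
  w4 <- generate_world(small_config(n_cities = 4), seed = 9)
  w5 <- generate_world(small_config(n_cities = 5), seed = 9)
  shared <- w4$annotations$city_id %in% sprintf("city%02d", 1:4)
  expect_identical(w4$annotations,
                   w5$annotations[w5$annotations$city_id %in%
                                    sprintf("city%02d", 1:4), ])
  expect_identical(w4$cities$share_cycle, w5$cities$share_cycle[1:4])
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(generator_config(availability = 1.2), "availability")
  expect_error(generator_config(n_cities = 0), "n_cities")
  expect_error(generator_config(child_fraction = -0.1), "child_fraction")
  expect_error(generator_config(stage2_n = 100, target_locations = 200),
               "stage2_n")
  expect_error(generator_config(fixed_shares = c(walk = 0.5, cycle = 0.6)),
               "fixed_shares")
})

test_that("panorama availability matches its configured rate at scale", {
  w <- default_world()  # 34 cities x 2000 stage-two locations = 68000 draws
  expect_equal(nrow(w$locations), 68000)
  expect_equal(mean(w$locations$available), 0.94, tolerance = 0.011)
})

test_that("zero noise and fixed shares give identical rates and exact shares", {
  fs <- c(walk = 0.117, cycle = 0.027, bus = 0.083, other_pt = 0.079,
          mc = 0.007, car = 0.687)
  cfg <- generator_config(n_cities = 4, stage2_n = 60, target_locations = 30,
                          fixed_shares = fs, census_noise_sd = 0)
  w <- generate_world(cfg, seed = 2)
  # the latent car rate (expected presence) is constant across cities
  expect_equal(length(unique(w$cities$share_car)), 1L)
  # census shares reproduce the truth exactly at zero noise
  expect_equal(w$outcomes$Census_Cycle, rep(100 * fs[["cycle"]], 4))
  expect_equal(w$outcomes$Census_Car, rep(100 * fs[["car"]], 4))
})

test_that("cyclist presence is monotone in the latent cycle share", {
  # two cities at cycle shares 0.02 and 0.30, 2000 images each, 10 seeds
  lo <- latent_city("lo", cycle = 0.02)
  hi <- latent_city("hi", cycle = 0.30, other_pt = 0.05)
  pan <- flat_panoramas(1000)
  ok <- vapply(1:10, function(s) {
    a_lo <- simulate_annotations(lo, pan, seed = s)
    a_hi <- simulate_annotations(hi, pan, seed = s)
    sum(a_hi$bin_cyclist != "0") > sum(a_lo$bin_cyclist != "0")
  }, logical(1))
  expect_true(all(ok))
  # and nondecreasing in expectation over a finer grid of rates
  grid <- c(0.01, 0.05, 0.1, 0.2, 0.3)
  means <- vapply(grid, function(cs) {
    city <- latent_city(paste0("g", cs), cycle = cs, other_pt = 0.05)
    mean(vapply(1:3, function(s)
      sum(simulate_annotations(city, pan, seed = s)$bin_cyclist != "0"),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("car presence calibrated to probability 0.72 yields ~1438/2000 images", {
  # car share 1 with rate constant -log(1 - 0.72) makes presence exactly 0.72
  city <- latent_city("carcal", cycle = 1e-6, walk = 1e-6, bus = 1e-6,
                      other_pt = 1e-6, mc = 1e-6)
  cfg <- generator_config(rate_k = c(pedestrian = 0, cyclist = 0,
                                     parked_cycle = 0, car = -log(1 - 0.72),
                                     motorcycle = 0, bus = 0))
  pan <- flat_panoramas(1000)
  with_cars <- mean(vapply(1:5, function(s)
    sum(simulate_annotations(city, pan, seed = s, config = cfg)$bin_car != "0"),
    numeric(1)))
  expect_equal(with_cars, 1438, tolerance = 0.03)
})

test_that("a zero cyclist rate produces only zero cyclist bins", {
  city <- latent_city("nocycle", cycle = 0)
  ann <- simulate_annotations(city, flat_panoramas(200), seed = 4)
  expect_true(all(ann$bin_cyclist == "0"))
  expect_true(all(ann$bin_parked_cycle == "0"))
})

test_that("per-city presence counts fall in the study envelopes", {
  ft <- build_feature_table(default_world()$annotations)
  expect_true(all(ft$GSV_Cycle >= 0 & ft$GSV_Cycle <= 150))
  expect_true(all(ft$GSV_Bus >= 0 & ft$GSV_Bus <= 150))
  expect_true(all(ft$GSV_MC >= 0 & ft$GSV_MC <= 150))
  expect_true(all(ft$GSV_Car >= 1000 & ft$GSV_Car <= 1700))
})

test_that("census walk shares and winter image mass match the emulated city mix", {
  w <- default_world()
  expect_gt(mean(w$outcomes$Census_Walk), 8)
  expect_lt(mean(w$outcomes$Census_Walk), 20)
  ft <- build_feature_table(w$annotations)
  expect_lt(mean(ft$GSV_Winter), 1)
})

test_that("downstream cyclist feature recovers the latent cycle share", {
  w <- default_world()
  ct <- city_table(w)
  expect_gt(cor(ct$GSV_Cycle, w$cities$share_cycle), 0.7)
  expect_gt(cor(ct$GSV_Cycle, ct$Census_Cycle), 0.7)
})

test_that("simulated survey outcomes track the latent activity levels", {
  set.seed(31)
  cities <- lapply(1:1000, function(i)
    latent_city(paste0("mc", i), cycle = plogis(rnorm(1, -3.58, 0.65)),
                walk = plogis(rnorm(1, qlogis(0.117), 0.25)) ))
  rows <- do.call(rbind, lapply(cities, function(ci)
    simulate_outcomes(ci, seed = 17)))
  cyc <- vapply(cities, function(ci) ci$true_shares[["cycle"]], numeric(1))
  expect_gt(cor(cyc, rows$APS_Prev_All_Cycle), 0.8)
})

test_that("gender draws respect symmetry, child handling and the gender link", {
  even <- latent_city("even", male_cycle_share = 0.5)
  g <- simulate_genders(even, 40000, seed = 3, child_fraction = 0,
                        detection_fraction = 1)
  expect_identical(g$children, 0L)
  expect_equal(g$males / g$females, 1, tolerance = 0.05)
  # male share decreasing in cycling level => group ratios monotone decreasing
  shares <- c(0.01, 0.05, 0.15, 0.30)
  monotone <- vapply(1:20, function(s) {
    ratios <- vapply(seq_along(shares), function(i) {
      ci <- latent_city(paste0("grp", i), cycle = shares[i], other_pt = 0.05)
      gg <- simulate_genders(ci, 4000, seed = s)
      gg$males / gg$females
    }, numeric(1))
    all(diff(ratios) < 0)
  }, logical(1))
  expect_gte(sum(monotone), 18)
})

test_that("world CSV artifacts round-trip through disk", {
  w <- generate_world(small_config(n_cities = 2), seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[["annotations"]])
  expect_equal(nrow(back), nrow(w$annotations))
  expect_equal(back$bin_car, w$annotations$bin_car)
})
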