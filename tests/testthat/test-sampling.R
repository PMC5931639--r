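# Staged location sampling: per-link points, stage-two SRS, year-priority
# selection, heading restriction and stabilisation diagnostics.

unit_links <- function(n, prefix = "L") {
  data.frame(link_id = sprintf("%s%d", prefix, seq_len(n)),
             x0 = as.numeric(seq_len(n)), y0 = rep(0, n),
             x1 = as.numeric(seq_len(n)), y1 = rep(1, n),
             length = rep(1, n))
}

test_that("stage one yields exactly one point per link, uniformly placed", {
  net <- unit_links(5)
  pts <- sample_link_points(net, seed = 1)
  expect_equal(nrow(pts), 5)
  expect_equal(sort(pts$link_id), sort(net$link_id))
  expect_true(all(pts$t >= 0 & pts$t <= 1))
  # positions along identical unit links are iid uniform
  big <- sample_link_points(unit_links(5000), seed = 2)
  ks <- suppressWarnings(ks.test(big$t, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate networks are rejected informatively", {
  expect_error(sample_link_points(unit_links(0), seed = 1), "empty")
  bad <- unit_links(3)
  bad$length[2] <- 0
  expect_error(sample_link_points(bad, seed = 1), "L2")
})

test_that("stage two is a deterministic simple random sample without replacement", {
  pts <- sample_link_points(unit_links(5000), seed = 3)
  plan <- sampling_plan(stage2_n = 2000, target_locations = 1000)
  s1 <- stage2_sample(pts, plan, seed = 4)
  expect_equal(nrow(s1), 2000)
  expect_equal(anyDuplicated(s1$link_id), 0L)
  expect_identical(s1, stage2_sample(pts, plan, seed = 4))
  # identity when the sample size equals the pool
  plan_all <- sampling_plan(stage2_n = 50, target_locations = 10)
  small <- pts[1:50, ]
  expect_setequal(stage2_sample(small, plan_all, seed = 5)$link_id,
                  small$link_id)
  expect_error(stage2_sample(pts[1:10, ], plan, seed = 6), "1990")
})

test_that("sampling plans validate their invariants", {
  expect_error(sampling_plan(stage2_n = 10, target_locations = 20), "stage2_n")
  expect_error(sampling_plan(year_priority = c(2011, 2011)), "year_priority")
  expect_error(sampling_plan(headings = c(0, 90)), "headings")
})

test_that("year-priority selection is forced by the preference order", {
  plan <- sampling_plan(stage2_n = 2000, target_locations = 1000,
                        year_priority = c(2011, 2012, 2010, 2009, 2008))
  md <- data.frame(loc_id = paste0("l", 1:1100),
                   pano_id = paste0("p", 1:1100),
                   year = rep(c(2011, 2012), c(600, 500)))
  sel <- select_by_year(md, plan, seed = 1)
  expect_equal(nrow(sel), 1000)
  expect_equal(sum(sel$year == 2011), 600)
  expect_equal(sum(sel$year == 2012), 400)
  # only older years available: 2009 exhausted before any 2008 chosen
  md2 <- data.frame(loc_id = paste0("m", 1:1200),
                    pano_id = paste0("q", 1:1200),
                    year = rep(c(2009, 2008), c(300, 900)))
  sel2 <- select_by_year(md2, plan, seed = 2)
  expect_equal(sum(sel2$year == 2009), 300)
  expect_equal(sum(sel2$year == 2008), 700)
  # shortfall flagged with a warning, not an error
  md3 <- md2[1:100, ]
  expect_warning(sel3 <- select_by_year(md3, plan, seed = 3), "100")
  expect_equal(attr(sel3, "shortfall"), 900)
})

test_that("dominance and uniqueness hold across 50 seeded worlds", {
  plan <- sampling_plan(stage2_n = 100, target_locations = 40,
                        year_priority = c(2011, 2012, 2010, 2009, 2008))
  for (s in 1:50) {
    set.seed(1000 + s)
    n_loc <- sample(30:120, 1)
    years <- sample(c(2008:2013), n_loc * 2, replace = TRUE)
    md <- data.frame(loc_id = paste0("w", rep(seq_len(n_loc), 2)),
                     pano_id = paste0("wp", seq_len(n_loc * 2)),
                     year = years)
    sel <- suppressWarnings(select_by_year(md, plan, seed = s))
    expect_equal(anyDuplicated(sel$loc_id), 0L)
    expect_equal(anyDuplicated(sel$pano_id), 0L)
    if (nrow(sel) > 0) {
      # no unchosen location can have a strictly better best rank than the
      # worst chosen rank
      md_pri <- md[md$year %in% plan$year_priority, , drop = FALSE]
      best_rank <- tapply(match(md_pri$year, plan$year_priority),
                          md_pri$loc_id, min)
      unchosen <- setdiff(names(best_rank), sel$loc_id)
      if (length(unchosen) > 0)
        expect_gte(min(best_rank[unchosen]), max(sel$year_rank))
    }
  }
})

test_that("the default world reproduces the study's selected-year ordering", {
  w <- default_world()
  tab <- table(factor(w$selection$year, levels = c(2012, 2011, 2009, 2008, 2010)))
  expect_true(tab[["2012"]] > tab[["2011"]])
  expect_true(tab[["2011"]] > tab[["2009"]])
  expect_true(tab[["2009"]] > tab[["2008"]])
  expect_true(tab[["2008"]] > tab[["2010"]])
  # heading restriction: exactly two images per selected location, 180 apart
  per_loc <- table(w$annotations$loc_id)
  expect_true(all(per_loc == 2))
  hd <- tapply(w$annotations$heading, w$annotations$loc_id,
               function(h) abs(diff(sort(h))))
  expect_true(all(hd == 180))
})

test_that("stabilisation finds the settling point of running proportions", {
  # constant stream settles exactly at the window end
  ann <- blank_annotations(150)
  ann$bin_car <- "1-3"
  st <- stabilisation(ann, window = 50, tol = 0.005)
  expect_equal(st$stabilised_at, 50)
  expect_true(all(st$curve[, "car"] == 1))
  # alternating cyclist presence: running mean has closed form floor(n/2)/n
  alt <- blank_annotations(2000)
  alt$bin_cyclist <- rep(c("0", "1-3"), 1000)
  st2 <- stabilisation(alt, window = 100, tol = 0.005)
  n <- seq_len(2000)
  p_closed <- floor(n / 2) / n
  expect_equal(unname(st2$curve[, "cyclist"]), p_closed)
  oracle <- NA_integer_
  for (i in 100:2000) {
    if (diff(range(p_closed[(i - 99):i])) < 0.005) { oracle <- i; break }
  }
  expect_equal(st2$stabilised_at, oracle)
})

test_that("study-like annotation streams stabilise near 1000 images", {
  w <- default_world()
  idx <- vapply(sprintf("city%02d", 1:10), function(cid) {
    ann <- w$annotations[w$annotations$city_id == cid, ]
    stabilisation(ann, window = 100, tol = 0.005)$stabilised_at
  }, integer(1))
  expect_true(all(!is.na(idx)))
  expect_true(all(idx <= 1500))
  expect_lte(median(idx), 1200)
})
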