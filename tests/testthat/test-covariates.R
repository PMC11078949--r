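test_that("haversine distances match closed forms and the formula oracle", {
  expect_equal(haversine_distance(10, 20, 10, 20), 0)
  expect_equal(haversine_distance(0, 0, 0, 180), pi * 6378137)
  expect_equal(haversine_distance(0, 0, 0, 90), pi * 6378137 / 2)
  set.seed(31)
  lat1 <- runif(50, -90, 90); lon1 <- runif(50, -180, 180)
  lat2 <- runif(50, -90, 90); lon2 <- runif(50, -180, 180)
  expect_equal(haversine_distance(lat1, lon1, lat2, lon2),
               oracle_haversine(lat1, lon1, lat2, lon2), tolerance = 1e-9)
  expect_equal(haversine_distance(lat1, lon1, lat2, lon2),
               haversine_distance(lat2, lon2, lat1, lon1))
  expect_error(haversine_distance(95, 0, 0, 0), "range")
})

test_that("circular day distance folds onto [0, 180] with year-end wrap", {
  expect_equal(circular_day_distance(100, 100), 0)
  expect_equal(circular_day_distance(1, 365), 360 - 364 * 0.986) # 1.096
  expect_equal(circular_day_distance(1, 183), 182 * 0.986)       # 179.452
  expect_error(circular_day_distance(0, 10), "366")
  set.seed(8)
  j1 <- sample(1:366, 200, TRUE); j2 <- sample(1:366, 200, TRUE)
  d12 <- circular_day_distance(j1, j2)
  expect_true(all(d12 >= 0 & d12 <= 180))
  expect_equal(d12, circular_day_distance(j2, j1))
  # triangle inequality on the annual circle
  j3 <- sample(1:366, 200, TRUE)
  expect_true(all(circular_day_distance(j1, j3) <=
                    d12 + circular_day_distance(j2, j3) + 1e-9))
})

test_that("mean absolute latitude reproduces the four benchmark pairs", {
  expect_identical(mean_abs_latitude(0, 0), 0)
  expect_identical(mean_abs_latitude(90, 90), 90)
  expect_identical(mean_abs_latitude(90, -90), 90)
  expect_identical(mean_abs_latitude(90, 0), 45)
  expect_error(mean_abs_latitude(91, 0), "latitude")
})

test_that("worked-example pair table matches the hand enumeration", {
  d <- make_worked_example()
  p <- build_pair_table(d)
  expect_s3_class(p, "pair_table")
  expect_equal(nrow(p), choose(7, 2))
  # balancing weights: each of the 6 site pairs carries total weight 1
  key <- paste(pmin(p$site_i, p$site_j), pmax(p$site_i, p$site_j))
  expect_equal(length(unique(key)), 6L)
  expect_true(all(abs(tapply(p$weight, key, sum) - 1) < 1e-12))
  expect_equal(sum(p$weight), 6)
  expect_true(all(p$delta_space_m[p$site_i == p$site_j] == 0))
  expect_true(all(p$delta_space_m[p$site_i != p$site_j] > 0))
  # hand-checked components
  r <- p[p$event_i == "EQ_w1" & p$event_j == "EQ_w2", ]
  expect_equal(r$beta_total, 4 / 6)
  expect_equal(r$beta_repl, 4 / 6)
  expect_equal(r$beta_rich, 0)
  expect_equal(r$delta_time_deg, 7 * 0.986)
  r2 <- p[p$event_i == "POL_w1" & p$event_j == "POL_w2", ]
  expect_equal(r2$beta_total, 1 / 3)
  expect_equal(r2$beta_repl, 0)
  expect_equal(r2$beta_rich, 1 / 3)
  # covariates against the standalone operations
  r3 <- p[p$event_i == "EQ_w1" & p$event_j == "MID_w1", ]
  expect_equal(r3$mean_abs_lat, 22.5)
  expect_equal(r3$delta_space_m, haversine_distance(0, -60, 45, 10))
  expect_equal(r3$delta_time_deg, circular_day_distance(20, 150))
  # conservation across the whole table
  expect_equal(p$beta_repl + p$beta_rich, p$beta_total, tolerance = 1e-12)
})

test_that("weight normalisation covers single- and multi-event sites", {
  sites <- tibble::tibble(site_id = c("s1", "s2"), latitude = c(0, 10),
                          longitude = c(0, 10), region = "R1")
  sets <- list(a = "x", b = "y", c = "z", d = c("x", "y"))
  d <- dataset_from_sets(sets, rep("s1", 4), c(1, 8, 15, 22), sites[1, ])
  p <- build_pair_table(d)
  expect_equal(nrow(p), 6L)
  expect_equal(p$weight, rep(1 / 6, 6))
  d2 <- dataset_from_sets(sets[1:2], c("s1", "s2"), c(1, 8), sites)
  p2 <- build_pair_table(d2)
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$weight, 1)
})

test_that("scopes and pair toggles subset the table correctly", {
  d <- make_worked_example()
  p_eu <- build_pair_table(d, scope = "Eurasia") # MID (2) + POL (3) events
  expect_equal(nrow(p_eu), choose(5, 2))
  expect_true(all(c(p_eu$site_i, p_eu$site_j) %in% c("MID", "POL")))
  p_ns <- build_pair_table(d, include_within_site = FALSE)
  expect_equal(nrow(p_ns), 21L - choose(2, 2) - choose(2, 2) - choose(3, 2))
  expect_true(all(p_ns$site_i != p_ns$site_j))
  p_wr <- build_pair_table(d, include_cross_region = FALSE)
  # EQ within-site (1) + all Eurasia pairs (10)
  expect_equal(nrow(p_wr), 11L)
  expect_error(build_pair_table(d, scope = "Atlantis"), "Atlantis")
})
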