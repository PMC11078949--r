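two_sites <- tibble::tibble(site_id = c("sA", "sB"),
                            latitude = c(10, 60), longitude = c(0, 30),
                            region = c("R1", "R2"))

test_that("main-effect tests drop the associated latitude interactions", {
  fr <- reduced_full_for_main_effects("DeltaS")
  expect_setequal(fr$full$terms, c("DeltaS", "DeltaT", "Lat", "Lat:DeltaT"))
  expect_setequal(fr$reduced$terms, c("DeltaT", "Lat", "Lat:DeltaT"))
  fr <- reduced_full_for_main_effects("DeltaT")
  expect_setequal(fr$reduced$terms, c("DeltaS", "Lat", "Lat:DeltaS"))
  fr <- reduced_full_for_main_effects("Lat")
  expect_setequal(fr$full$terms, c("DeltaS", "DeltaT", "Lat"))
  expect_setequal(fr$reduced$terms, c("DeltaS", "DeltaT"))
  expect_error(reduced_full_for_main_effects("Lat:DeltaS"), "main effect")
})

test_that("each term maps to its permutation scheme and five-term fulls", {
  tt <- betadecay:::term_test_spec("Lat:DeltaS")
  expect_setequal(tt$full, c("DeltaS", "DeltaT", "Lat", "Lat:DeltaS",
                             "Lat:DeltaT"))
  expect_equal(tt$scheme, "permute_sites")
  expect_equal(betadecay:::term_test_spec("Lat:DeltaT")$scheme,
               "permute_sites_and_dates")
  expect_equal(betadecay:::term_test_spec("DeltaT")$scheme,
               "permute_dates_within_sites")
  expect_equal(betadecay:::term_test_spec("Lat")$scheme, "permute_sites")
})

test_that("site permutation moves coordinates, never communities or dates", {
  d <- make_worked_example()
  p0 <- build_pair_table(d)
  expect_equal(build_pair_table(permute_sites(d, perm = 1:3)), p0)
  d2 <- permute_sites(d, perm = c(2, 3, 1))
  p2 <- build_pair_table(d2)
  expect_equal(p2$beta_total, p0$beta_total)       # responses untouched
  expect_equal(p2$delta_time_deg, p0$delta_time_deg) # dates untouched
  expect_equal(sort(unique(d2$sites$latitude)), sort(unique(d$sites$latitude)))
  # two sites: the only non-identity permutation swaps coordinates,
  # leaving the single between-site distance unchanged
  sets <- list(e1 = c("a", "b"), e2 = c("b", "c"))
  ds <- dataset_from_sets(sets, c("sA", "sB"), c(10, 100), two_sites)
  q0 <- build_pair_table(ds)
  q1 <- build_pair_table(permute_sites(ds, perm = c(2, 1)))
  expect_equal(q1$delta_space_m, q0$delta_space_m)
  expect_equal(q1$mean_abs_lat, q0$mean_abs_lat) # symmetric in a 2-site pair
  one_site_ds <- dataset_from_sets(sets["e1"], "sA", 10, two_sites[1, ])
  expect_error(permute_sites(one_site_ds), "2 sites")
  expect_error(permute_sites(ds, perm = c(1, 1)), "permutation")
})

test_that("date permutation stays within sites and preserves day multisets", {
  d <- make_worked_example()
  # singleton and explicit two-event swap
  d2 <- permute_dates_within_sites(
    d, assignments = list(EQ = c(2, 1), MID = 1:2, POL = 1:3)
  )
  days <- function(x, s) x$events$julian_day[x$events$site_id == s]
  expect_equal(days(d2, "EQ"), rev(days(d, "EQ")))
  expect_equal(days(d2, "MID"), days(d, "MID"))
  set.seed(4)
  for (rep in 1:10) {
    dr <- permute_dates_within_sites(d)
    for (s in c("EQ", "MID", "POL")) {
      expect_equal(sort(days(dr, s)), sort(days(d, s)))
    }
    expect_equal(dr$species, d$species)
    expect_equal(dr$sites, d$sites)
  }
  # within-site temporal distances are a preserved multiset; the swapped
  # pairing changes cross-site distances
  p0 <- build_pair_table(d)
  p2 <- build_pair_table(d2)
  within <- p0$site_i == p0$site_j
  expect_equal(sort(p2$delta_time_deg[within]),
               sort(p0$delta_time_deg[within]))
})

test_that("fast covariate path agrees with dataset-level permutation", {
  d <- make_worked_example()
  ctx <- betadecay:::pair_context(d)
  perm <- c(3, 1, 2)
  cov <- betadecay:::ctx_covariates(ctx, perm = perm)
  p2 <- build_pair_table(permute_sites(d, perm = perm))
  expect_equal(cov$DeltaS, p2$delta_space_m)
  expect_equal(cov$Lat, p2$mean_abs_lat)
  expect_equal(cov$DeltaT, p2$delta_time_deg)
  # identity relabeling reproduces the observed covariates exactly
  cov_id <- betadecay:::ctx_covariates(ctx, perm = 1:3, days = ctx$day)
  cov_obs <- betadecay:::ctx_covariates(ctx)
  expect_identical(cov_id, cov_obs)
})

test_that("permutation tests are reproducible and honestly bounded", {
  ds <- simulate_metacommunity(null_preset(sites_per_region = 1,
                                           weeks_per_site = 6, seed = 21))
  t1 <- test_term(ds, "DeltaS", n_perm = 29, seed = 77)
  t2 <- test_term(ds, "DeltaS", n_perm = 29, seed = 77)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$llr_null, t2$llr_null)
  expect_gte(t1$llr_observed, 0)
  expect_true(all(t1$llr_null >= -1e-8))
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)
  t3 <- test_term(ds, "DeltaS", n_perm = 29, seed = 78)
  expect_false(identical(t1$llr_null, t3$llr_null))
  # conservative tie rule can never report p = 0
  t4 <- test_term(ds, "DeltaS", n_perm = 29, seed = 77,
                  tie_rule = "conservative")
  expect_gte(t4$p_value, 1 / 30)
})

test_that("a planted distance-decay effect is detected with + direction", {
  ds <- simulate_metacommunity(effect_preset(seed = 91))
  tt <- test_term(ds, "DeltaS", n_perm = 49, seed = 92)
  expect_lte(tt$p_value, 0.05)
  expect_equal(tt$direction, "+")
})

test_that("run_full_analysis yields the term-by-scope grid, skipping thin scopes", {
  ds <- simulate_metacommunity(null_preset(seed = 33))
  # each region has only 2 sites: below the default min_sites floor
  expect_warning(
    res <- run_full_analysis(ds, scopes = c("Global", "North America"),
                             responses = "total", n_perm = 19, seed = 3),
    "North America"
  )
  expect_equal(nrow(res), 5L)
  expect_setequal(res$term,
                  c("DeltaS", "DeltaT", "Lat", "Lat:DeltaS", "Lat:DeltaT"))
  expect_true(all(res$scope == "Global"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$significant, res$p_value <= 0.05)
  # per-cell child seeds reproduce the cell in isolation
  cell <- res[res$term == "Lat", ]
  redo <- test_term(ds, "Lat", response = "total", n_perm = 19,
                    seed = cell$seed)
  expect_equal(redo$p_value, cell$p_value)
  expect_equal(redo$llr_observed, cell$llr_observed)
})
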