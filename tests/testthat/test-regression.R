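test_that("unit weights reproduce ordinary least squares and its loglik", {
  p <- random_pair_table(120, seed = 5)
  spec <- model_spec("total", c("DeltaS", "DeltaT", "Lat"))
  fit <- fit_wls(p, spec)
  ref <- lm(beta_total ~ delta_space_m + delta_time_deg + mean_abs_lat,
            data = p)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
})

test_that("weighted fits match the normal-equation oracle and weighted lm", {
  set.seed(17)
  w <- sample(c(1, 1 / 4), 150, replace = TRUE)
  p <- random_pair_table(150, seed = 6, weights = w)
  # keep the explicit normal equations well conditioned: express distance
  # in Mm so the interaction columns stay O(100)
  p$delta_space_m <- p$delta_space_m / 1e6
  terms <- c("DeltaS", "DeltaT", "Lat", "Lat:DeltaS", "Lat:DeltaT")
  fit <- fit_wls(p, model_spec("total", terms))
  X <- cbind(1, p$delta_space_m, p$delta_time_deg, p$mean_abs_lat,
             p$mean_abs_lat * p$delta_space_m,
             p$mean_abs_lat * p$delta_time_deg)
  expect_equal(unname(coef(fit)), unname(oracle_wls(X, p$beta_total, w)),
               tolerance = 1e-8)
  ref <- lm(beta_total ~ delta_space_m * mean_abs_lat +
              delta_time_deg * mean_abs_lat, data = p, weights = w)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-10)
})

test_that("degenerate and rank-deficient designs are refused", {
  p <- random_pair_table(40, seed = 9)
  p$beta_total <- 0.1 + 2e-9 * p$delta_space_m # exact line
  expect_error(fit_wls(p, model_spec("total", "DeltaS")),
               "residual variance")
  p2 <- random_pair_table(40, seed = 10)
  p2$mean_abs_lat <- 45 # constant: collinear with the intercept
  expect_error(fit_wls(p2, model_spec("total", c("DeltaS", "Lat"))), "Lat")
})

test_that("adding a term never lowers the likelihood", {
  for (seed in 1:10) {
    p <- random_pair_table(90, seed = 100 + seed)
    reduced <- fit_wls(p, model_spec("total", c("DeltaS", "DeltaT")))
    full <- fit_wls(p, model_spec("total",
                                  c("DeltaS", "DeltaT", "Lat", "Lat:DeltaS")))
    expect_gte(loglik_ratio(full, reduced), -1e-8)
  }
})

test_that("rescaling a covariate rescales only its coefficient", {
  p <- random_pair_table(100, seed = 12)
  spec <- model_spec("total", c("DeltaS", "DeltaT", "Lat"))
  f1 <- fit_wls(p, spec)
  p2 <- p
  p2$delta_space_m <- p2$delta_space_m / 1000 # meters -> km
  f2 <- fit_wls(p2, spec)
  expect_equal(coef(f2)[["DeltaS"]], coef(f1)[["DeltaS"]] * 1000,
               tolerance = 1e-8)
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]],
               tolerance = 1e-8)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
})

test_that("duplicating every pair at half weight leaves coefficients intact", {
  # the site-pair balancing motivation: total influence per site pair is
  # what matters, not how many event pairs carry it
  p <- random_pair_table(60, seed = 13,
                         weights = rep(c(1, 1 / 2, 1 / 4), 20))
  dup <- rbind(p, p)
  dup$weight <- dup$weight / 2
  class(dup) <- class(p)
  spec <- model_spec("total", c("DeltaS", "Lat"))
  f1 <- fit_wls(p, spec)
  f2 <- fit_wls(dup, spec)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-10)
  # per-observation weighted RSS is unchanged; n doubles, so sigma2 halves
  expect_equal(f2$sigma2, f1$sigma2 / 2, tolerance = 1e-10)
})

test_that("model specs validate their terms and responses", {
  expect_error(model_spec("total", "Elevation"), "unknown term")
  expect_error(model_spec("total", c("Lat", "Lat")), "duplicated")
  expect_error(model_spec("banana", "Lat"))
  s <- model_spec("richness_difference", character(0))
  expect_equal(s$terms, character(0))
  p <- random_pair_table(50, seed = 14)
  f0 <- fit_wls(p, s) # intercept-only fit is legal
  expect_named(coef(f0), "(Intercept)")
  js <- jsonlite::fromJSON(fit_to_json(f0))
  expect_equal(js$n_obs, 50)
  expect_equal(js$loglik, f0$loglik)
})
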