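# Independent brute-force oracles and small fixture builders shared by the
# test files. These never call the code paths they are used to check.

# components from explicit set operations
oracle_components <- function(first, second) {
  first <- unique(first)
  second <- unique(second)
  a <- length(intersect(first, second))
  b <- length(setdiff(first, second))
  cc <- length(setdiff(second, first))
  denom <- a + b + cc
  c(
    total = (b + cc) / denom,
    replacement = 2 * min(b, cc) / denom,
    richness_difference = abs(b - cc) / denom
  )
}

# weighted least squares by explicit normal equations
oracle_wls <- function(X, y, w) {
  drop(solve(crossprod(X, w * X), crossprod(X, w * y)))
}

# haversine from the textbook formula
oracle_haversine <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  k <- pi / 180
  h <- sin((lat2 - lat1) * k / 2)^2 +
    cos(lat1 * k) * cos(lat2 * k) * sin((lon2 - lon1) * k / 2)^2
  2 * r * asin(sqrt(pmin(1, h)))
}

# beta_dataset from literal species sets
dataset_from_sets <- function(sets, site_of, days, sites) {
  n_sp <- lengths(sets)
  ev <- tibble::tibble(
    event_id = rep(names(sets), n_sp),
    site_id = rep(site_of, n_sp),
    julian_day = rep(days, n_sp),
    species_id = unlist(sets, use.names = FALSE)
  )
  load_events(ev, sites, verbose = FALSE)
}

# quick synthetic pair table for regression tests (not via the pipeline)
random_pair_table <- function(n, seed, weights = NULL) {
  set.seed(seed)
  p <- tibble::tibble(
    event_i = sprintf("a%03d", seq_len(n)),
    event_j = sprintf("b%03d", seq_len(n)),
    site_i = "s1", site_j = "s2",
    delta_space_m = runif(n, 0, 2e7),
    delta_time_deg = runif(n, 0, 180),
    mean_abs_lat = runif(n, 0, 90),
    weight = if (is.null(weights)) rep(1, n) else weights
  )
  p$beta_total <- pmin(1, pmax(0, 0.4 + 2e-8 * p$delta_space_m +
                                 1e-3 * p$delta_time_deg -
                                 2e-3 * p$mean_abs_lat + rnorm(n, 0, 0.08)))
  p$beta_repl <- p$beta_total * runif(n, 0.3, 0.9)
  p$beta_rich <- p$beta_total - p$beta_repl
  class(p) <- c("pair_table", class(p))
  p
}
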