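default_region_table <- function(n_regions) {
  if (n_regions == 5) {
    tibble::tibble(
      region = c("North America", "South America", "Eurasia", "Africa",
                 "Oceania"),
      lat_lo = c(15, -56, 10, -35, -47),
      lat_hi = c(78, 12, 78, 35, -10),
      lon_lo = c(-130, -80, 0, -15, 110),
      lon_hi = c(-60, -35, 140, 50, 155)
    )
  } else {
    width <- 360 / n_regions
    tibble::tibble(
      region = paste0("R", seq_len(n_regions)),
      lat_lo = rep(-80, n_regions),
      lat_hi = rep(80, n_regions),
      lon_lo = -180 + (seq_len(n_regions) - 1) * width,
      lon_hi = -180 + seq_len(n_regions) * width
    )
  }
}

#' Configuration for the metacommunity simulator
#'
#' Bundles every knob of [simulate_metacommunity()]. Defaults describe a
#' moderately structured multi-region trapping campaign; see
#' [null_preset()] and [effect_preset()] for the two canonical bundles.
#'
#' @param n_regions number of biogeographic regions (5 gives named
#'   continental regions with realistic latitude/longitude bands).
#' @param sites_per_region sites placed uniformly inside each region's
#'   bands.
#' @param weeks_per_site consecutive weekly trapping events per site.
#' @param gamma_pool_size total species pool size.
#' @param community_size expected number of species held by one site.
#' @param lat_diversity_slope relative decline of the local species pool
#'   per degree of absolute latitude: species latitudinal range limits
#'   are drawn Exponential with this rate, so the pool available at
#'   absolute latitude `x` has expected size
#'   `gamma_pool_size * exp(-lat_diversity_slope * x)` and species
#'   reaching high latitudes have wide, mutually nested ranges
#'   (0 = no latitudinal structure).
#' @param distance_decay_rate per-km decline rate of a species'
#'   suitability away from its geographic range centre (0 = no spatial
#'   structure).
#' @param seasonal_niche_breadth circular-Gaussian s.d. of species
#'   activity windows, degrees on the annual circle (0.986 degrees per
#'   day); `Inf` = aseasonal.
#' @param detection_prob per-species, per-week detection probability for
#'   locally present, seasonally active species.
#' @param replacement_vs_nestedness_mix in `[0, 1]`: share of the
#'   community assembled by site-specific weighted draws (generating
#'   species replacement between sites) versus a ranked, strictly nested
#'   pool (generating richness difference). 1 = pure replacement.
#' @param region_table optional tibble (`region`, `lat_lo`, `lat_hi`,
#'   `lon_lo`, `lon_hi`) overriding the default region bands.
#' @param seed integer seed; drives site placement, species traits,
#'   community assembly and detections through separately derived
#'   substreams.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 5, sites_per_region = 3,
                       weeks_per_site = 22, gamma_pool_size = 300,
                       community_size = 50, lat_diversity_slope = 0.02,
                       distance_decay_rate = 8e-4,
                       seasonal_niche_breadth = 45,
                       detection_prob = 0.8,
                       replacement_vs_nestedness_mix = 0.8,
                       region_table = NULL, seed = 1L) {
  cfg <- list(
    n_regions = as.integer(n_regions),
    sites_per_region = as.integer(sites_per_region),
    weeks_per_site = as.integer(weeks_per_site),
    gamma_pool_size = as.integer(gamma_pool_size),
    community_size = as.integer(community_size),
    lat_diversity_slope = lat_diversity_slope,
    distance_decay_rate = distance_decay_rate,
    seasonal_niche_breadth = seasonal_niche_breadth,
    detection_prob = detection_prob,
    replacement_vs_nestedness_mix = replacement_vs_nestedness_mix,
    region_table = region_table,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_regions >= 1, sites_per_region >= 1, weeks_per_site >= 1,
      gamma_pool_size >= 1, community_size >= 1,
      lat_diversity_slope >= 0, distance_decay_rate >= 0,
      seasonal_niche_breadth > 0,
      detection_prob > 0, detection_prob <= 1,
      replacement_vs_nestedness_mix >= 0, replacement_vs_nestedness_mix <= 1
    )
  })
  if (cfg$community_size > cfg$gamma_pool_size) {
    stop("community_size cannot exceed gamma_pool_size", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Null-structure simulator preset
#'
#' No latitudinal range limits, no spatial decay, aseasonal activity and
#' pure replacement assembly: site communities are independent
#' equal-size uniform draws from the pool, so site attributes and dates
#' are exchangeable by construction. This is the preset permutation-test
#' calibration runs on. Default size (5 regions x 2 sites, 8 weeks, 200
#' species) keeps one dataset at 80 events / 3160 pairs.
#'
#' @param sites_per_region,weeks_per_site,gamma_pool_size,seed overrides.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
null_preset <- function(sites_per_region = 2, weeks_per_site = 8,
                        gamma_pool_size = 200, seed = 1L, ...) {
  sim_config(
    n_regions = 5, sites_per_region = sites_per_region,
    weeks_per_site = weeks_per_site, gamma_pool_size = gamma_pool_size,
    community_size = 40, lat_diversity_slope = 0, distance_decay_rate = 0,
    seasonal_niche_breadth = Inf, detection_prob = 0.85,
    replacement_vs_nestedness_mix = 1, seed = seed, ...
  )
}

#' Structured-effects simulator preset
#'
#' Strong built-in latitudinal gradient (species pool densest at the
#' Equator), spatial distance decay of suitability and pronounced
#' seasonality, so expected total dissimilarity increases toward the
#' Equator, with spatial distance and with seasonal distance. This is the
#' preset recovery/power runs use.
#'
#' @param sites_per_region,weeks_per_site,gamma_pool_size,seed overrides.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config`.
#' @export
effect_preset <- function(sites_per_region = 5, weeks_per_site = 14,
                          gamma_pool_size = 400, seed = 1L, ...) {
  sim_config(
    n_regions = 5, sites_per_region = sites_per_region,
    weeks_per_site = weeks_per_site, gamma_pool_size = gamma_pool_size,
    community_size = 50, lat_diversity_slope = 0.03,
    distance_decay_rate = 2e-4, seasonal_niche_breadth = 45,
    detection_prob = 0.8, replacement_vs_nestedness_mix = 0.9,
    seed = seed, ...
  )
}

# Latitudinal range limits: species s occupies |lat| <= L_s, with
# L ~ Exponential(rate = slope). The local pool at absolute latitude x is
# then G * exp(-slope * x): `lat_diversity_slope` is literally the
# relative decline in pool size per degree. Species reaching high
# latitudes necessarily have wide ranges (Rapoport-style nesting), so
# high-latitude communities are drawn from small, mutually shared pools.
# slope = 0 gives every species an unbounded range: no latitudinal
# structure at all.
sample_range_limits <- function(n, slope) {
  if (slope == 0) rep(Inf, n) else stats::rexp(n, rate = slope)
}

#' Simulate a multi-region weekly trapping campaign
#'
#' Generates a presence/absence metacommunity dataset shaped like a
#' global Malaise-trap programme: georeferenced sites in several regions,
#' consecutive weekly trapping events per site, and a species pool whose
#' members carry a latitudinal niche, a geographic range centre with
#' distance-decaying suitability, and a circular seasonal activity
#' window. Site communities are drawn once per site (a weighted sample
#' for the replacement fraction, a ranked strictly nested subset for the
#' rest); each weekly event then detects every locally present,
#' seasonally active species independently with `detection_prob`.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `beta_dataset`; the generating config is attached as
#'   attribute `"sim_config"`.
#' @export
simulate_metacommunity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  # expected-emptiness guard: error out rather than emit all-empty events
  mean_act <- if (is.infinite(cfg$seasonal_niche_breadth)) 1 else {
    mean(exp(-(0:180)^2 / (2 * cfg$seasonal_niche_breadth^2)))
  }
  p_empty <- (1 - cfg$detection_prob * mean_act)^cfg$community_size
  if (p_empty > 0.5) {
    stop("configuration would leave most trapping events empty ",
         "(expected per-species detection ", signif(cfg$detection_prob * mean_act, 2),
         ", community_size ", cfg$community_size, "); raise detection_prob, ",
         "community_size or seasonal_niche_breadth", call. = FALSE)
  }

  regions <- if (is.null(cfg$region_table)) {
    default_region_table(cfg$n_regions)
  } else {
    tibble::as_tibble(cfg$region_table)
  }
  if (nrow(regions) != cfg$n_regions) {
    stop("region_table must have n_regions rows", call. = FALSE)
  }

  # --- sites ---------------------------------------------------------
  set.seed(derive_seed(cfg$seed, "sites"))
  S <- cfg$n_regions * cfg$sites_per_region
  reg_idx <- rep(seq_len(cfg$n_regions), each = cfg$sites_per_region)
  # latitude-stratified placement within each region's band: one site per
  # equal-width slice (marginally uniform, but every realisation spans
  # the band, as in a designed trap network)
  k <- cfg$sites_per_region
  strat <- (rep(seq_len(k), times = cfg$n_regions) - runif(S)) / k
  sites <- tibble::tibble(
    site_id = sprintf("site%02d", seq_len(S)),
    latitude = regions$lat_lo[reg_idx] +
      strat * (regions$lat_hi[reg_idx] - regions$lat_lo[reg_idx]),
    longitude = runif(S, regions$lon_lo[reg_idx], regions$lon_hi[reg_idx]),
    region = regions$region[reg_idx]
  )

  # --- species traits ------------------------------------------------
  set.seed(derive_seed(cfg$seed, "species"))
  G <- cfg$gamma_pool_size
  mix <- cfg$replacement_vs_nestedness_mix
  n_nested <- round((1 - mix) * G)
  n_repl <- G - n_nested
  sp_id <- sprintf("sp%04d", seq_len(G))
  range_limit <- sample_range_limits(G, cfg$lat_diversity_slope)
  center_lat <- runif(G, -pmin(range_limit, 80), pmin(range_limit, 80))
  center_lon <- runif(G, -180, 180)
  phase <- runif(G, 0, 360)
  u_rank <- runif(G) # only used for the nested fraction

  # --- site communities ---------------------------------------------
  set.seed(derive_seed(cfg$seed, "communities"))
  q_repl <- round(mix * cfg$community_size)
  if (q_repl > n_repl) {
    stop("replacement quota exceeds replacement pool; increase ",
         "gamma_pool_size or lower community_size", call. = FALSE)
  }
  repl_ids <- seq_len(n_repl)
  nested_ids <- if (n_nested > 0) n_repl + seq_len(n_nested) else integer(0)
  keep_frac0 <- if (n_nested > 0) {
    min(1, (1 - mix) * cfg$community_size / n_nested)
  } else 0

  if (n_repl > 0 && q_repl > 0) {
    d_km <- geosphere::distm(
      cbind(sites$longitude, sites$latitude),
      cbind(center_lon[repl_ids], center_lat[repl_ids]),
      fun = geosphere::distHaversine
    ) / 1000
    in_range <- outer(abs(sites$latitude), range_limit[repl_ids], "<=")
    # tiny floor keeps the weighted draw feasible when a high-latitude
    # site has fewer in-range species than its quota (rare vagrants)
    suit <- in_range * exp(-cfg$distance_decay_rate * d_km) + 1e-12
  }
  community <- vector("list", S)
  for (s in seq_len(S)) {
    memb <- integer(0)
    if (n_repl > 0 && q_repl > 0) {
      memb <- repl_ids[sample.int(n_repl, q_repl, prob = suit[s, ])]
    }
    if (n_nested > 0) {
      keep_s <- keep_frac0 * exp(-cfg$lat_diversity_slope * abs(sites$latitude[s]))
      memb <- c(memb, nested_ids[u_rank[nested_ids] > 1 - keep_s])
    }
    community[[s]] <- sort(memb)
  }

  # --- weekly events -------------------------------------------------
  set.seed(derive_seed(cfg$seed, "events"))
  w <- cfg$weeks_per_site
  rows_event <- character(0)
  rows_site <- character(0)
  rows_day <- integer(0)
  rows_sp <- character(0)
  for (s in seq_len(S)) {
    start <- sample.int(366, 1)
    days <- ((start - 1L) + 7L * (0:(w - 1L))) %% 366L + 1L
    memb <- community[[s]]
    k <- length(memb)
    for (t in seq_len(w)) {
      eid <- sprintf("%s_w%03d", sites$site_id[s], t)
      if (k > 0) {
        act <- if (is.infinite(cfg$seasonal_niche_breadth)) 1 else {
          delta <- abs(days[t] * 0.986 - phase[memb]) %% 360
          cd <- pmin(delta, 360 - delta)
          exp(-cd^2 / (2 * cfg$seasonal_niche_breadth^2))
        }
        hit <- memb[runif(k) < cfg$detection_prob * act]
      } else {
        hit <- integer(0)
      }
      if (length(hit) == 0) {
        # represent the empty harvest; load_events() drops and reports it
        rows_event <- c(rows_event, eid)
        rows_site <- c(rows_site, sites$site_id[s])
        rows_day <- c(rows_day, days[t])
        rows_sp <- c(rows_sp, NA_character_)
      } else {
        nh <- length(hit)
        rows_event <- c(rows_event, rep(eid, nh))
        rows_site <- c(rows_site, rep(sites$site_id[s], nh))
        rows_day <- c(rows_day, rep(days[t], nh))
        rows_sp <- c(rows_sp, sp_id[hit])
      }
    }
  }
  events <- tibble::tibble(
    event_id = rows_event, site_id = rows_site,
    julian_day = rows_day, species_id = rows_sp
  )
  out <- load_events(events, sites, verbose = FALSE)
  attr(out, "sim_config") <- cfg
  out
}

#' Tiny hand-auditable worked example
#'
#' Three sites (equatorial, mid-latitude, subpolar), seven trapping
#' events, twelve species with fixed presence sets, so every pairwise
#' (a, b, c) triple, Podani component, covariate and balancing weight can
#' be checked by hand. The species sets are:
#'
#' \preformatted{
#'   EQ_w1  (day  20): sp01 sp02 sp03 sp04
#'   EQ_w2  (day  27): sp02 sp03 sp05 sp06
#'   MID_w1 (day 150): sp05 sp06 sp07
#'   MID_w2 (day 157): sp06 sp07 sp08
#'   POL_w1 (day 180): sp07 sp08 sp09
#'   POL_w2 (day 187): sp08 sp09
#'   POL_w3 (day 194): sp08 sp09 sp10 sp11 sp12
#' }
#'
#' E.g. pair (EQ_w1, EQ_w2): a = 2, b = 2, c = 2, total = 4/6,
#' replacement = 4/6, richness difference = 0; pair (POL_w1, POL_w2):
#' a = 2, b = 1, c = 0, total = 1/3, replacement = 0, richness
#' difference = 1/3. The 7 events yield C(7,2) = 21 pair records; each
#' of the 6 site pairs (including the 3 within-site ones) carries total
#' weight 1.
#'
#' @return a `beta_dataset`.
#' @export
make_worked_example <- function() {
  sites <- tibble::tibble(
    site_id = c("EQ", "MID", "POL"),
    latitude = c(0, 45, 70),
    longitude = c(-60, 10, 25),
    region = c("South America", "Eurasia", "Eurasia")
  )
  sets <- list(
    EQ_w1 = c("sp01", "sp02", "sp03", "sp04"),
    EQ_w2 = c("sp02", "sp03", "sp05", "sp06"),
    MID_w1 = c("sp05", "sp06", "sp07"),
    MID_w2 = c("sp06", "sp07", "sp08"),
    POL_w1 = c("sp07", "sp08", "sp09"),
    POL_w2 = c("sp08", "sp09"),
    POL_w3 = c("sp08", "sp09", "sp10", "sp11", "sp12")
  )
  meta <- tibble::tibble(
    event_id = names(sets),
    site_id = c("EQ", "EQ", "MID", "MID", "POL", "POL", "POL"),
    julian_day = c(20L, 27L, 150L, 157L, 180L, 187L, 194L)
  )
  n_sp <- lengths(sets)
  events <- tibble::tibble(
    event_id = rep(meta$event_id, n_sp),
    site_id = rep(meta$site_id, n_sp),
    julian_day = rep(meta$julian_day, n_sp),
    species_id = unlist(sets, use.names = FALSE)
  )
  load_events(events, sites, verbose = FALSE)
}
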