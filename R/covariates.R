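#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere, delegating to
#' [geosphere::distHaversine()]. The default radius (6,378,137 m, the
#' WGS84 equatorial radius) matches that function's default so distances
#' are bit-comparable with analyses built on it.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param radius sphere radius in meters.
#' @return distance(s) in meters.
#' @examples
#' haversine_distance(0, 0, 0, 180) / 1e6 # half the equatorial circumference
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2, radius = 6378137) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = radius)
}

#' Circular distance between two days of year
#'
#' Day-of-year differences are treated as angles on the annual circle at
#' 0.986 degrees per day (360/365.2 rounded to the conventional 3
#' decimals), so late December and early January are close. With
#' \eqn{\Delta = |j_1 - j_2|} and \eqn{\theta = 0.986\,\Delta}, the
#' distance is \eqn{\min(\theta, 360 - \theta)}, in `[0, 180]` degrees.
#'
#' @param j1,j2 integer day(s) of year in `[1, 366]` (vectorised).
#' @return circular distance(s) in degrees.
#' @examples
#' circular_day_distance(1, 365) # wraps around the new year: 1.096 degrees
#' @export
circular_day_distance <- function(j1, j2) {
  if (any(j1 < 1 | j1 > 366 | j2 < 1 | j2 > 366)) {
    stop("day of year out of [1, 366]", call. = FALSE)
  }
  theta <- abs(j1 - j2) * 0.986
  pmin(theta, 360 - theta)
}

#' Mean absolute latitude of a site pair
#'
#' \eqn{(|lat_1| + |lat_2|) / 2}: the pair-level position along the
#' latitudinal diversity gradient. A pair at the Equator scores 0, a pair
#' at the two Poles scores 90, a Pole-Equator pair scores 45.
#'
#' @param lat1,lat2 latitudes in decimal degrees (vectorised).
#' @return degrees in `[0, 90]`.
#' @export
mean_abs_latitude <- function(lat1, lat2) {
  if (any(abs(c(lat1, lat2)) > 90)) {
    stop("latitude out of [-90, 90]", call. = FALSE)
  }
  (abs(lat1) + abs(lat2)) / 2
}

site_distance_matrix <- function(sites) {
  pts <- cbind(sites$longitude, sites$latitude)
  m <- geosphere::distm(pts, fun = geosphere::distHaversine)
  dimnames(m) <- list(sites$site_id, sites$site_id)
  m
}

# Everything test_term()/build_pair_table() need about one analysis scope,
# precomputed once: responses and weights never change under any
# permutation scheme, only covariates do.
pair_context <- function(dataset, scope = "Global",
                         include_within_site = TRUE,
                         include_cross_region = TRUE) {
  stopifnot(inherits(dataset, "beta_dataset"))
  ev <- dataset$events
  sites <- dataset$sites
  if (!identical(scope, "Global")) {
    if (!scope %in% sites$region) {
      stop("unknown region scope: ", scope, call. = FALSE)
    }
    keep_sites <- sites$site_id[sites$region == scope]
    ev <- ev[ev$site_id %in% keep_sites, , drop = FALSE]
  }
  if (nrow(ev) < 2) {
    stop("scope '", scope, "' has fewer than 2 events", call. = FALSE)
  }
  sites <- sites[sites$site_id %in% unique(ev$site_id), , drop = FALSE]

  mat <- presence_absence_matrix(dataset, ev$event_id)
  part <- partition_pairs(mat)
  rm(mat)

  site_of <- match(ev$site_id, sites$site_id)
  pi <- part$i
  pj <- part$j
  si <- site_of[pi]
  sj <- site_of[pj]
  keep <- rep(TRUE, length(pi))
  if (!include_within_site) keep <- keep & (si != sj)
  if (identical(scope, "Global") && !include_cross_region) {
    keep <- keep & (sites$region[si] == sites$region[sj])
  }
  if (!all(keep)) {
    pi <- pi[keep]; pj <- pj[keep]; si <- si[keep]; sj <- sj[keep]
  }
  if (length(pi) == 0) stop("no event pairs left in scope", call. = FALSE)

  S <- nrow(sites)
  key <- pmin(si, sj) * (S + 1L) + pmax(si, sj)
  kf <- match(key, unique(key))
  w <- 1 / tabulate(kf)[kf]

  list(
    scope = scope,
    events = ev,
    sites = sites,
    n_sites = S,
    site_of = site_of,
    day = ev$julian_day,
    events_by_site = split(seq_len(nrow(ev)), site_of),
    pi = pi, pj = pj, si = si, sj = sj,
    D = site_distance_matrix(sites),
    abslat = abs(sites$latitude),
    weight = w,
    n_site_pairs = length(unique(key)),
    responses = list(
      total = part$total[keep],
      replacement = part$replacement[keep],
      richness_difference = part$richness_difference[keep]
    )
  )
}

# Pairwise covariates under an optional site-attribute permutation and an
# optional reassignment of days to events. `base` supplies columns a
# scheme leaves untouched so they are not recomputed per permutation.
ctx_covariates <- function(ctx, perm = NULL, days = NULL, base = NULL) {
  if (is.null(perm)) {
    if (!is.null(base)) {
      dS <- base$DeltaS
      lat <- base$Lat
    } else {
      dS <- ctx$D[cbind(ctx$si, ctx$sj)]
      lat <- (ctx$abslat[ctx$si] + ctx$abslat[ctx$sj]) / 2
    }
  } else {
    psi <- perm[ctx$si]
    psj <- perm[ctx$sj]
    dS <- ctx$D[cbind(psi, psj)]
    lat <- (ctx$abslat[psi] + ctx$abslat[psj]) / 2
  }
  if (is.null(days)) {
    if (!is.null(base)) {
      dT <- base$DeltaT
    } else {
      dT <- circular_day_distance(ctx$day[ctx$pi], ctx$day[ctx$pj])
    }
  } else {
    dT <- circular_day_distance(days[ctx$pi], days[ctx$pj])
  }
  list(DeltaS = dS, DeltaT = dT, Lat = lat)
}

#' Assemble the weighted pair table for one analysis scope
#'
#' One row per unordered pair of trapping events in scope, carrying the
#' three partitioned responses, the three covariates and the balancing
#' weight. The weight of a pair is `1 / n[s1, s2]` where `n[s1, s2]` is
#' the number of event pairs joining the same unordered site pair, so
#' every site pair contributes total weight exactly 1 to the regression
#' regardless of how many weeks each site was sampled. Within-site pairs
#' (same site, different weeks; `delta_space_m == 0`) are included by
#' default: they are what identifies the temporal terms.
#'
#' @param dataset a `beta_dataset`.
#' @param scope `"Global"` (all events; cross-region pairs included) or a
#'   region name.
#' @param include_within_site keep pairs of events from one site?
#' @param include_cross_region keep Global pairs spanning two regions?
#' @return a tibble of class `pair_table` with columns `event_i`,
#'   `event_j`, `site_i`, `site_j`, `delta_space_m`, `delta_time_deg`,
#'   `mean_abs_lat`, `beta_total`, `beta_repl`, `beta_rich`, `weight`,
#'   in [pair_indices()] order; the scope is stored in attribute
#'   `"scope"`.
#' @export
build_pair_table <- function(dataset, scope = "Global",
                             include_within_site = TRUE,
                             include_cross_region = TRUE) {
  ctx <- pair_context(dataset, scope, include_within_site, include_cross_region)
  cov <- ctx_covariates(ctx)
  out <- tibble::tibble(
    event_i = ctx$events$event_id[ctx$pi],
    event_j = ctx$events$event_id[ctx$pj],
    site_i = ctx$sites$site_id[ctx$si],
    site_j = ctx$sites$site_id[ctx$sj],
    delta_space_m = cov$DeltaS,
    delta_time_deg = cov$DeltaT,
    mean_abs_lat = cov$Lat,
    beta_total = ctx$responses$total,
    beta_repl = ctx$responses$replacement,
    beta_rich = ctx$responses$richness_difference,
    weight = ctx$weight
  )
  attr(out, "scope") <- scope
  class(out) <- c("pair_table", class(out))
  out
}
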