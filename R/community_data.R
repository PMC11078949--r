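#' Day of year from a calendar date
#'
#' Converts calendar dates to 1-based Julian day of year. In leap years
#' Feb 29 maps to 60 and all subsequent days shift by one, so the same
#' calendar date can map to neighbouring day numbers in different years;
#' the circular temporal metric downstream is insensitive to this 1-day
#' jitter.
#'
#' @param date a `Date` vector, or character coercible via [as.Date()].
#' @return integer vector of day-of-year values in `[1, 366]`.
#' @examples
#' julian_day_of(as.Date(c("2015-01-01", "2016-02-29", "2016-03-01")))
#' @export
julian_day_of <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (anyNA(d)) stop("invalid calendar date(s) in `date`", call. = FALSE)
  as.integer(as.POSIXlt(d)$yday + 1L)
}

#' Load and validate event-level community data
#'
#' Assembles a validated dataset from a long-format detection table (one
#' row per detection of one species in one trapping event) and a site
#' table. Detections are collapsed to presence/absence: duplicated
#' (event, species) rows count once. Events left with no species are
#' dropped (the pairwise dissimilarity denominators are undefined for
#' empty communities) and reported in the load report. Rows with a
#' missing or blank `species_id` are treated as empty detections.
#'
#' Either a `julian_day` column or a `date` column must be present in
#' `event_table`; if both are present, `julian_day` wins (the analysis
#' operates on day of year; the year itself is discarded by the circular
#' temporal metric).
#'
#' @param event_table data frame with columns `event_id`, `site_id`,
#'   `species_id` and `julian_day` (integer, 1-366) and/or `date`.
#' @param site_table data frame with columns `site_id`, `latitude`
#'   (degrees, \eqn{[-90, 90]}), `longitude` (degrees, \eqn{[-180, 180]})
#'   and `region`.
#' @param verbose emit a message summarising dropped/deduplicated rows?
#' @return an object of class `beta_dataset`: a list with elements
#'   `sites` (tibble), `events` (tibble: `event_id`, `site_id`,
#'   `julian_day`), `species` (named list of character vectors, one per
#'   event), `species_universe` (sorted character vector) and
#'   `load_report` (list of row/event counts satisfying
#'   `rows_in == rows_kept + rows_deduplicated + rows_in_dropped_events`).
#' @examples
#' ev <- data.frame(event_id = "e1", site_id = "s1", julian_day = 10,
#'                  species_id = c("spA", "spA", "spB"))
#' st <- data.frame(site_id = "s1", latitude = 12, longitude = 4,
#'                  region = "Africa")
#' d <- load_events(ev, st, verbose = FALSE)
#' d$species$e1
#' @export
load_events <- function(event_table, site_table, verbose = TRUE) {
  sites <- tibble::as_tibble(site_table)
  need_s <- c("site_id", "latitude", "longitude", "region")
  if (!all(need_s %in% names(sites))) {
    stop("site_table must have columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id in site_table: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_lat <- !is.finite(sites$latitude) | abs(sites$latitude) > 90
  if (any(bad_lat)) {
    stop("latitude out of [-90, 90] for site(s): ",
         paste(sites$site_id[bad_lat], collapse = ", "), call. = FALSE)
  }
  bad_lon <- !is.finite(sites$longitude) | abs(sites$longitude) > 180
  if (any(bad_lon)) {
    stop("longitude out of [-180, 180] for site(s): ",
         paste(sites$site_id[bad_lon], collapse = ", "), call. = FALSE)
  }
  sites$region <- as.character(sites$region)

  ev <- tibble::as_tibble(event_table)
  need_e <- c("event_id", "site_id", "species_id")
  if (!all(need_e %in% names(ev))) {
    stop("event_table must have columns: ", paste(need_e, collapse = ", "),
         call. = FALSE)
  }
  ev$event_id <- as.character(ev$event_id)
  ev$site_id <- as.character(ev$site_id)
  ev$species_id <- as.character(ev$species_id)
  if ("julian_day" %in% names(ev)) {
    jd <- as.integer(ev$julian_day)
  } else if ("date" %in% names(ev)) {
    jd <- julian_day_of(ev$date)
  } else {
    stop("event_table needs a `julian_day` or `date` column", call. = FALSE)
  }
  if (anyNA(jd) || any(jd < 1L | jd > 366L)) {
    stop("julian_day must be an integer in [1, 366]", call. = FALSE)
  }
  ev$julian_day <- jd

  unknown <- setdiff(unique(ev$site_id), sites$site_id)
  if (length(unknown) > 0) {
    stop("event(s) reference unknown site_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  # each event_id must map to exactly one (site_id, julian_day)
  meta <- unique(ev[, c("event_id", "site_id", "julian_day")])
  if (anyDuplicated(meta$event_id)) {
    stop("event_id with inconsistent site_id/julian_day: ",
         paste(unique(meta$event_id[duplicated(meta$event_id)]), collapse = ", "),
         call. = FALSE)
  }

  rows_in <- nrow(ev)
  valid <- !is.na(ev$species_id) & nzchar(ev$species_id)
  dup <- valid & duplicated(paste(ev$event_id, ev$species_id, sep = "\r"))
  kept <- valid & !dup

  n_kept_per_event <- tapply(kept, ev$event_id, sum)
  dropped_events <- names(n_kept_per_event)[n_kept_per_event == 0]
  in_dropped <- ev$event_id %in% dropped_events
  # blank-species rows inside kept events also count as dropped content
  rows_in_dropped <- sum(in_dropped) + sum(!valid & !in_dropped)
  rows_dedup <- sum(dup & !in_dropped)
  rows_kept <- sum(kept & !in_dropped)

  keep_rows <- kept & !in_dropped
  ev_keep <- ev[keep_rows, , drop = FALSE]
  if (nrow(ev_keep) == 0) stop("no non-empty events after loading", call. = FALSE)

  meta <- meta[!(meta$event_id %in% dropped_events), , drop = FALSE]
  species <- split(ev_keep$species_id, factor(ev_keep$event_id, levels = meta$event_id))
  species <- lapply(species, function(x) sort(unique(x)))

  report <- list(
    rows_in = rows_in,
    rows_kept = rows_kept,
    rows_deduplicated = rows_dedup,
    rows_in_dropped_events = rows_in_dropped,
    events_in = length(n_kept_per_event),
    events_kept = nrow(meta),
    events_dropped = length(dropped_events),
    dropped_event_ids = dropped_events
  )
  if (verbose && (rows_dedup > 0 || length(dropped_events) > 0)) {
    message("load_events: kept ", nrow(meta), " events; collapsed ",
            rows_dedup, " duplicate detection rows; dropped ",
            length(dropped_events), " empty event(s)")
  }

  structure(
    list(
      sites = sites,
      events = meta,
      species = species,
      species_universe = sort(unique(ev_keep$species_id)),
      load_report = report
    ),
    class = "beta_dataset"
  )
}

#' @export
print.beta_dataset <- function(x, ...) {
  cat("<beta_dataset>\n")
  cat("  sites:   ", nrow(x$sites), " in ",
      length(unique(x$sites$region)), " region(s)\n", sep = "")
  cat("  events:  ", nrow(x$events), "\n", sep = "")
  cat("  species: ", length(x$species_universe), "\n", sep = "")
  invisible(x)
}

#' Number of trapping events in a dataset
#' @param dataset a `beta_dataset`.
#' @return integer count.
#' @export
n_events <- function(dataset) {
  stopifnot(inherits(dataset, "beta_dataset"))
  nrow(dataset$events)
}

#' Presence/absence incidence matrix
#'
#' Builds the binary events-by-species matrix underlying all pairwise
#' dissimilarity computations. Rows follow `dataset$events` order, columns
#' are the sorted species universe.
#'
#' @param dataset a `beta_dataset`.
#' @param event_ids optional subset (and ordering) of event ids.
#' @return integer matrix of 0/1 with dimnames (event_id, species_id).
#' @export
presence_absence_matrix <- function(dataset, event_ids = NULL) {
  stopifnot(inherits(dataset, "beta_dataset"))
  if (is.null(event_ids)) event_ids <- dataset$events$event_id
  if (!all(event_ids %in% dataset$events$event_id)) {
    stop("unknown event_id requested", call. = FALSE)
  }
  spp <- dataset$species_universe
  m <- matrix(0L, nrow = length(event_ids), ncol = length(spp),
              dimnames = list(event_ids, spp))
  for (i in seq_along(event_ids)) {
    m[i, dataset$species[[event_ids[i]]]] <- 1L
  }
  m
}

#' Export the incidence matrix as a wide CSV
#'
#' @param dataset a `beta_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_incidence_csv <- function(dataset, path) {
  m <- presence_absence_matrix(dataset)
  df <- data.frame(event_id = rownames(m), m, check.names = FALSE)
  readr::write_csv(tibble::as_tibble(df), path)
  invisible(path)
}
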