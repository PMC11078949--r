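stamp_line <- function(seed = NULL, config = NULL) {
  paste0(
    "# betadecay ", as.character(utils::packageVersion("betadecay")),
    if (!is.null(seed)) paste0(" | seed=", seed),
    if (!is.null(config)) paste0(" | config=", rlang::hash(config))
  )
}

write_stamped_csv <- function(x, path, seed = NULL, config = NULL) {
  writeLines(stamp_line(seed, config), path)
  readr::write_csv(tibble::as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

sniff_delim <- function(path) {
  for (line in readr::read_lines(path, n_max = 10)) {
    if (startsWith(line, "#") || !nzchar(line)) next
    return(if (grepl("\t", line, fixed = TRUE)) "\t" else ",")
  }
  ","
}

read_plain <- function(path, delim = NULL) {
  if (is.null(delim)) delim <- sniff_delim(path)
  readr::read_delim(path, delim = delim, comment = "#",
                    show_col_types = FALSE, progress = FALSE)
}

#' Write a dataset to load-ready CSV files
#'
#' Emits `events.csv` (long format: `event_id`, `site_id`, `julian_day`,
#' `species_id`) and `sites.csv` in `dir`, the exact dialect
#' [read_dataset_csv()] and [load_events()] consume. Files begin with a
#' `#` comment line recording the package version (and seed/config hash
#' when a simulator config is attached to the dataset).
#'
#' @param dataset a `beta_dataset`.
#' @param dir output directory (created if missing).
#' @return paths of the two files, invisibly.
#' @export
write_dataset_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "beta_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(dataset, "sim_config")
  seed <- if (!is.null(cfg)) cfg$seed else NULL
  n_sp <- lengths(dataset$species[dataset$events$event_id])
  long <- tibble::tibble(
    event_id = rep(dataset$events$event_id, n_sp),
    site_id = rep(dataset$events$site_id, n_sp),
    julian_day = rep(dataset$events$julian_day, n_sp),
    species_id = unlist(dataset$species[dataset$events$event_id],
                        use.names = FALSE)
  )
  p1 <- file.path(dir, "events.csv")
  p2 <- file.path(dir, "sites.csv")
  write_stamped_csv(long, p1, seed, cfg)
  write_stamped_csv(dataset$sites, p2, seed, cfg)
  invisible(c(events = p1, sites = p2))
}

#' Read a dataset from CSV files
#'
#' @param events_path,sites_path paths to the long-format events table
#'   and site table (UTF-8 CSV/TSV with header; delimiter sniffed unless
#'   given; `#` lines ignored).
#' @param delim optional explicit delimiter.
#' @param verbose passed to [load_events()].
#' @return a `beta_dataset`.
#' @export
read_dataset_csv <- function(events_path, sites_path, delim = NULL,
                             verbose = TRUE) {
  if (!file.exists(events_path)) stop("missing events file: ", events_path,
                                      call. = FALSE)
  if (!file.exists(sites_path)) stop("missing sites file: ", sites_path,
                                     call. = FALSE)
  load_events(read_plain(events_path, delim), read_plain(sites_path, delim),
              verbose = verbose)
}

#' Write / read a pair table
#'
#' Persisting the pair table lets the expensive all-pairs partition be
#' computed once and reused: permutations never alter any community, so
#' downstream analyses only recompute covariates.
#'
#' @param pairs a `pair_table`.
#' @param path CSV path.
#' @return `path` (write) or a `pair_table` (read).
#' @export
write_pair_table <- function(pairs, path) {
  stopifnot(inherits(pairs, "pair_table"))
  write_stamped_csv(pairs, path, config = attr(pairs, "scope"))
  invisible(path)
}

#' @rdname write_pair_table
#' @param delim optional explicit delimiter.
#' @export
read_pair_table <- function(path, delim = NULL) {
  out <- read_plain(path, delim)
  need <- c("event_i", "event_j", "site_i", "site_j", "delta_space_m",
            "delta_time_deg", "mean_abs_lat", "beta_total", "beta_repl",
            "beta_rich", "weight")
  if (!all(need %in% names(out))) {
    stop("not a pair table: missing ",
         paste(setdiff(need, names(out)), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("pair_table", class(out))
  out
}

#' Run the whole pipeline: simulate/load, partition, analyse
#'
#' Orchestrates the full analysis end to end and archives every
#' intermediate next to the results: the input CSVs (when simulating),
#' the Global pair table, the term-by-scope-by-response significance
#' table and the run configuration as YAML. All outputs are plain text
#' and fully determined by the inputs plus `seed`.
#'
#' @param preset `"null"` or `"effect"` to simulate, or `NULL` to read
#'   `events_path`/`sites_path`.
#' @param events_path,sites_path input CSVs when `preset` is `NULL`.
#' @param out_dir output directory.
#' @param scopes,responses,n_perm,alpha,tie_rule,min_sites,min_pairs,
#'   include_within_site,include_cross_region passed to
#'   [run_full_analysis()].
#' @param seed master seed (also the simulator seed when simulating).
#' @param progress print per-test progress lines?
#' @return the results tibble, invisibly; files under `out_dir`.
#' @export
run_pipeline <- function(preset = NULL, events_path = NULL, sites_path = NULL,
                         out_dir = "results", scopes = NULL,
                         responses = RESPONSES, n_perm = 1000, seed = 1L,
                         alpha = 0.05, tie_rule = "strict",
                         min_sites = 3, min_pairs = 30,
                         include_within_site = TRUE,
                         include_cross_region = TRUE, progress = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(preset)) {
    cfg <- switch(preset,
      null = null_preset(seed = seed),
      effect = effect_preset(seed = seed),
      stop("unknown preset '", preset, "'; available: null, effect",
           call. = FALSE)
    )
    dataset <- simulate_metacommunity(cfg)
    write_dataset_csv(dataset, file.path(out_dir, "data"))
  } else {
    if (is.null(events_path) || is.null(sites_path)) {
      stop("either a preset or both events_path and sites_path are required",
           call. = FALSE)
    }
    dataset <- read_dataset_csv(events_path, sites_path, verbose = FALSE)
  }

  pairs <- build_pair_table(dataset,
                            include_within_site = include_within_site,
                            include_cross_region = include_cross_region)
  write_pair_table(pairs, file.path(out_dir, "pairs.csv"))

  results <- run_full_analysis(
    dataset, scopes = scopes, responses = responses, n_perm = n_perm,
    seed = seed, alpha = alpha, tie_rule = tie_rule,
    min_sites = min_sites, min_pairs = min_pairs,
    include_within_site = include_within_site,
    include_cross_region = include_cross_region, progress = progress
  )
  run_cfg <- list(
    preset = preset, events_path = events_path, sites_path = sites_path,
    scopes = scopes, responses = responses, n_perm = n_perm, seed = seed,
    alpha = alpha, tie_rule = tie_rule, min_sites = min_sites,
    min_pairs = min_pairs, include_within_site = include_within_site,
    include_cross_region = include_cross_region,
    package_version = as.character(utils::packageVersion("betadecay"))
  )
  write_stamped_csv(results, file.path(out_dir, "results.csv"),
                    seed = seed, config = run_cfg)
  yaml::write_yaml(run_cfg, file.path(out_dir, "run_config.yaml"))
  invisible(results)
}
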