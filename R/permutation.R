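# Which full model, reduced model and permutation scheme belong to each
# testable term. Main-effect tests drop the interaction "associated with"
# the tested variable from the full model; the latitude test drops both
# latitude interactions (both are associated with it).
term_test_spec <- function(term) {
  full <- switch(term,
    "Lat:DeltaS" = TERM_SET,
    "Lat:DeltaT" = TERM_SET,
    "DeltaS" = setdiff(TERM_SET, "Lat:DeltaS"),
    "DeltaT" = setdiff(TERM_SET, "Lat:DeltaT"),
    "Lat" = c("DeltaS", "DeltaT", "Lat"),
    stop("unknown term: ", term, call. = FALSE)
  )
  scheme <- switch(term,
    "Lat:DeltaS" = "permute_sites",
    "Lat:DeltaT" = "permute_sites_and_dates",
    "DeltaS" = "permute_sites",
    "Lat" = "permute_sites",
    "DeltaT" = "permute_dates_within_sites"
  )
  list(term = term, full = full, reduced = setdiff(full, term),
       scheme = scheme)
}

#' Full and reduced model specs for a main-effect test
#'
#' For a main effect the full model excludes the interaction(s)
#' associated with the tested variable: `DeltaS` is tested in a model
#' without `Lat:DeltaS`, `DeltaT` without `Lat:DeltaT`, and `Lat` without
#' both latitude interactions. The reduced model then drops the tested
#' term itself.
#'
#' @param term `"DeltaS"`, `"DeltaT"` or `"Lat"`.
#' @param response response the specs are for (default `"total"`).
#' @return list with `model_spec` elements `full` and `reduced`.
#' @export
reduced_full_for_main_effects <- function(term, response = "total") {
  if (term %in% c("Lat:DeltaS", "Lat:DeltaT")) {
    stop("`term` must be a main effect, not an interaction", call. = FALSE)
  }
  tt <- term_test_spec(term)
  list(full = model_spec(response, tt$full),
       reduced = model_spec(response, tt$reduced))
}

#' Permute site attributes across sites
#'
#' Reassigns the (latitude, longitude) tuples to sites uniformly at
#' random while every site keeps its own trapping events (communities and
#' dates untouched). Responses are therefore preserved exactly while all
#' site-derived covariates are scrambled at the site level — the
#' exchangeable unit of the spatial/latitudinal permutation tests.
#' Region labels stay with the physical site group.
#'
#' @param dataset a `beta_dataset` with at least 2 sites.
#' @param perm optional explicit permutation (integer vector over sites
#'   in `dataset$sites` order); random if `NULL`.
#' @return a new `beta_dataset` with permuted coordinates.
#' @export
permute_sites <- function(dataset, perm = NULL) {
  stopifnot(inherits(dataset, "beta_dataset"))
  S <- nrow(dataset$sites)
  if (S < 2) stop("nothing to permute: fewer than 2 sites", call. = FALSE)
  if (is.null(perm)) perm <- sample.int(S)
  if (!identical(sort(as.integer(perm)), seq_len(S))) {
    stop("`perm` is not a permutation of the sites", call. = FALSE)
  }
  dataset$sites$latitude <- dataset$sites$latitude[perm]
  dataset$sites$longitude <- dataset$sites$longitude[perm]
  dataset
}

#' Permute sampling dates within each site
#'
#' Within every site, the observed multiset of Julian days is kept but
#' reassigned at random to that site's trapping events; communities and
#' site attributes are untouched. Within-site temporal distances are
#' unchanged as a multiset; what changes is which community sits on which
#' date.
#'
#' @param dataset a `beta_dataset`.
#' @param assignments optional named list (site_id -> integer permutation
#'   of that site's events, in `dataset$events` order within site);
#'   random if `NULL`.
#' @return a new `beta_dataset` with reassigned days.
#' @export
permute_dates_within_sites <- function(dataset, assignments = NULL) {
  stopifnot(inherits(dataset, "beta_dataset"))
  ev <- dataset$events
  for (s in unique(ev$site_id)) {
    idx <- which(ev$site_id == s)
    if (length(idx) < 2) next
    prm <- if (is.null(assignments)) sample.int(length(idx)) else assignments[[s]]
    if (is.null(prm)) next
    ev$julian_day[idx] <- ev$julian_day[idx][prm]
  }
  dataset$events <- ev
  dataset
}

shuffle_days_ctx <- function(ctx) {
  days <- ctx$day
  for (idx in ctx$events_by_site) {
    k <- length(idx)
    if (k > 1) days[idx] <- days[idx][sample.int(k)]
  }
  days
}

# Deterministic child seed from a master seed and a string key; keeps the
# result a positive 32-bit integer.
derive_seed <- function(master, ...) {
  key <- paste(..., sep = "|")
  h <- 0
  for (k in utf8ToInt(key)) h <- (h * 131 + k) %% 1013904223
  as.integer(((as.numeric(master) %% 99991) * 20011 + h * 2 + 1) %% 2147483647L)
}

# Core permutation LLR test on a precomputed pair context. Covariates are
# rebuilt per permutation; responses, weights and the condensed
# partitions are computed once (no permutation alters any community).
perm_test_engine <- function(ctx, term, response, n_perm = 1000,
                             seed = NULL, tie_rule = c("strict", "conservative"),
                             max_attempts = 10 * n_perm + 100) {
  tie_rule <- match.arg(tie_rule)
  tt <- term_test_spec(term)
  y <- ctx$responses[[response]]
  if (is.null(y)) stop("unknown response: ", response, call. = FALSE)
  w <- ctx$weight
  n <- length(y)
  p_full <- length(tt$full) + 1L
  if (n <= p_full + 1L) {
    stop("too few pairs (", n, ") to estimate the full model", call. = FALSE)
  }
  sqw <- sqrt(w)
  sum_log_w <- sum(log(w))
  yw <- y * sqw

  llr_of_cov <- function(cov) {
    Xf <- design_from_cov(cov, tt$full, n) * sqw
    Xr <- design_from_cov(cov, tt$reduced, n) * sqw
    lf <- ll_fast(Xf, yw, n, sum_log_w)
    lr <- ll_fast(Xr, yw, n, sum_log_w)
    if (is.na(lf) || is.na(lr)) return(NA_real_)
    lf - lr
  }

  cov0 <- ctx_covariates(ctx)
  # observed fit via lm.wfit for named, original-order coefficients
  X0 <- design_from_cov(cov0, tt$full, n)
  obs_fit <- stats::lm.wfit(X0, y, w)
  if (anyNA(obs_fit$coefficients)) {
    stop("rank-deficient design on the observed data; collinear term(s): ",
         paste(names(obs_fit$coefficients)[is.na(obs_fit$coefficients)],
               collapse = ", "), call. = FALSE)
  }
  llr_obs <- llr_of_cov(cov0)
  if (is.na(llr_obs)) {
    stop("degenerate fit on the observed data", call. = FALSE)
  }

  permute_sites_too <- tt$scheme %in% c("permute_sites", "permute_sites_and_dates")
  permute_dates_too <- tt$scheme %in% c("permute_dates_within_sites",
                                        "permute_sites_and_dates")
  if (permute_sites_too && ctx$n_sites < 2) {
    stop("site permutation needs at least 2 sites in scope", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(seed)
  llr_null <- numeric(n_perm)
  got <- 0L
  attempts <- 0L
  while (got < n_perm) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("too many rank-deficient permutations (", attempts - 1L,
           " attempts for ", n_perm, " draws)", call. = FALSE)
    }
    perm <- if (permute_sites_too) sample.int(ctx$n_sites) else NULL
    days <- if (permute_dates_too) shuffle_days_ctx(ctx) else NULL
    llr <- llr_of_cov(ctx_covariates(ctx, perm, days, base = cov0))
    if (is.na(llr)) next
    got <- got + 1L
    llr_null[got] <- llr
  }

  p_value <- if (tie_rule == "strict") {
    mean(llr_obs < llr_null)
  } else {
    (sum(llr_null >= llr_obs) + 1) / (n_perm + 1)
  }
  coef_focal <- unname(obs_fit$coefficients[term])

  structure(
    list(
      term = term,
      scope = ctx$scope,
      response = response,
      p_value = p_value,
      direction = if (coef_focal >= 0) "+" else "-",
      coefficient = coef_focal,
      llr_observed = llr_obs,
      llr_null = llr_null,
      n_permutations = n_perm,
      n_resampled = attempts - got,
      seed = seed,
      tie_rule = tie_rule,
      scheme = tt$scheme,
      full_terms = tt$full,
      reduced_terms = tt$reduced
    ),
    class = "perm_test"
  )
}

#' Permutation log-likelihood-ratio test for one model term
#'
#' Tests whether `term` contributes to the weighted regression of a
#' beta-diversity component by comparing the observed log-likelihood
#' ratio between the full model (including the term) and the reduced
#' model (excluding it) with its null distribution under `n_perm`
#' permutations of the data. Pairs of trapping events are not independent
#' — every event takes part in many pairs — so the permutations operate
#' on the exchangeable units instead: site attributes are relabelled
#' across sites (spatial/latitudinal terms), or sampling dates are
#' shuffled within sites (temporal terms); for `Lat:DeltaT` both are
#' applied. The p-value is the proportion of permutations whose LLR
#' strictly exceeds the observed one; the direction is the sign of the
#' term's coefficient in the full model on the observed data.
#'
#' @param dataset a `beta_dataset`.
#' @param term one of `DeltaS`, `DeltaT`, `Lat`, `Lat:DeltaS`,
#'   `Lat:DeltaT`.
#' @param response `"total"`, `"replacement"` or `"richness_difference"`.
#' @param scope `"Global"` or a region name.
#' @param n_perm number of permutations (the reference analysis used
#'   1000).
#' @param seed integer seed making the draw reproducible.
#' @param tie_rule `"strict"` counts only permutations whose null LLR
#'   strictly exceeds the observed (permits p of exactly 0 and 1);
#'   `"conservative"` uses the add-one rule `(b + 1) / (N + 1)`.
#' @param include_within_site,include_cross_region pair-table toggles,
#'   see [build_pair_table()].
#' @return object of class `perm_test` with the p-value, direction,
#'   observed LLR and all null LLR draws.
#' @export
test_term <- function(dataset, term, response = "total", scope = "Global",
                      n_perm = 1000, seed = NULL,
                      tie_rule = c("strict", "conservative"),
                      include_within_site = TRUE,
                      include_cross_region = TRUE) {
  ctx <- pair_context(dataset, scope, include_within_site, include_cross_region)
  perm_test_engine(ctx, term, response, n_perm, seed, tie_rule)
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$term, " on ", x$response, " [", x$scope, "]\n",
      "  p = ", format(x$p_value, digits = 3), " (", x$tie_rule, "), dir ",
      x$direction, ", LLR = ", format(x$llr_observed, digits = 5),
      ", N = ", x$n_permutations, "\n", sep = "")
  invisible(x)
}

#' Run the full term-by-scope-by-response permutation analysis
#'
#' For every requested scope (by default the global dataset plus each
#' region), every beta-diversity component and every model term, runs the
#' matching permutation LLR test and collects the results in one tidy
#' table (the shape of the reference analysis' significance table:
#' covariate x region with a p-value and direction per component).
#' Scopes with too few sites or pairs are skipped with a warning. Child
#' seeds for each (scope, response, term) are derived deterministically
#' from `seed`, so any single cell can be reproduced in isolation with
#' [test_term()].
#'
#' @param dataset a `beta_dataset`.
#' @param scopes character vector of scopes; default `"Global"` plus all
#'   regions present.
#' @param responses components to model (default all three).
#' @param terms model terms to test (default all five).
#' @param n_perm permutations per test.
#' @param seed master seed.
#' @param alpha significance level used for the `significant` flag.
#' @param min_sites,min_pairs floors below which a scope is skipped.
#' @param tie_rule,include_within_site,include_cross_region see
#'   [test_term()].
#' @param progress print one line per completed test?
#' @return tibble with columns `term`, `scope`, `response`, `p_value`,
#'   `direction`, `significant`, `coefficient`, `llr_observed`,
#'   `n_permutations`, `seed`.
#' @export
run_full_analysis <- function(dataset, scopes = NULL,
                              responses = RESPONSES,
                              terms = TERM_SET,
                              n_perm = 1000, seed = 1L, alpha = 0.05,
                              min_sites = 3, min_pairs = 30,
                              tie_rule = c("strict", "conservative"),
                              include_within_site = TRUE,
                              include_cross_region = TRUE,
                              progress = FALSE) {
  stopifnot(inherits(dataset, "beta_dataset"))
  tie_rule <- match.arg(tie_rule)
  if (is.null(scopes)) {
    scopes <- c("Global", sort(unique(dataset$sites$region)))
  }
  rows <- list()
  for (scope in scopes) {
    ctx <- tryCatch(
      pair_context(dataset, scope, include_within_site, include_cross_region),
      error = function(e) e
    )
    if (inherits(ctx, "error")) {
      warning("skipping scope '", scope, "': ", conditionMessage(ctx),
              call. = FALSE)
      next
    }
    if (ctx$n_sites < min_sites || length(ctx$pi) < min_pairs) {
      warning("skipping scope '", scope, "': ", ctx$n_sites, " site(s), ",
              length(ctx$pi), " pair(s) below floors (", min_sites, ", ",
              min_pairs, ")", call. = FALSE)
      next
    }
    for (response in responses) {
      for (term in terms) {
        child <- derive_seed(seed, scope, response, term)
        res <- perm_test_engine(ctx, term, response, n_perm, child, tie_rule)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = term, scope = scope, response = response,
          p_value = res$p_value, direction = res$direction,
          significant = res$p_value <= alpha,
          coefficient = res$coefficient,
          llr_observed = res$llr_observed,
          n_permutations = n_perm, seed = child
        )
        if (progress) {
          message(sprintf("%-10s %-14s %-20s p = %.3f %s",
                          term, scope, response, res$p_value, res$direction))
        }
      }
    }
  }
  if (length(rows) == 0) stop("no scope could be analysed", call. = FALSE)
  do.call(rbind, rows)
}
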