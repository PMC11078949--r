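TERM_SET <- c("DeltaS", "DeltaT", "Lat", "Lat:DeltaS", "Lat:DeltaT")
RESPONSES <- c("total", "replacement", "richness_difference")

response_column <- function(response) {
  switch(response,
    total = "beta_total",
    replacement = "beta_repl",
    richness_difference = "beta_rich",
    stop("unknown response: ", response, call. = FALSE)
  )
}

#' Specify a weighted regression model for one beta-diversity component
#'
#' @param response one of `"total"`, `"replacement"`,
#'   `"richness_difference"`.
#' @param terms character subset of `DeltaS` (spatial distance), `DeltaT`
#'   (circular temporal distance), `Lat` (mean absolute latitude) and the
#'   interactions `Lat:DeltaS`, `Lat:DeltaT`. The intercept is always
#'   included. An interaction may appear without its main effects: the
#'   permutation tests' reduced models need this.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(response, terms) {
  response <- match.arg(response, RESPONSES)
  if (length(terms) == 0) terms <- character(0)
  bad <- setdiff(terms, TERM_SET)
  if (length(bad) > 0) {
    stop("unknown term(s): ", paste(bad, collapse = ", "),
         "; valid terms are ", paste(TERM_SET, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(terms)) stop("duplicated terms", call. = FALSE)
  structure(list(response = response, terms = as.character(terms)),
            class = "model_spec")
}

term_column <- function(cov, term) {
  switch(term,
    DeltaS = cov$DeltaS,
    DeltaT = cov$DeltaT,
    Lat = cov$Lat,
    `Lat:DeltaS` = cov$Lat * cov$DeltaS,
    `Lat:DeltaT` = cov$Lat * cov$DeltaT
  )
}

design_from_cov <- function(cov, terms, n) {
  cols <- vector("list", length(terms) + 1L)
  cols[[1L]] <- rep.int(1, n)
  for (k in seq_along(terms)) cols[[k + 1L]] <- term_column(cov, terms[k])
  X <- do.call(cbind, cols)
  colnames(X) <- c("(Intercept)", terms)
  X
}

pair_table_cov <- function(pairs) {
  list(DeltaS = pairs$delta_space_m, DeltaT = pairs$delta_time_deg,
       Lat = pairs$mean_abs_lat)
}

# Gaussian log-likelihood of a weighted least-squares fit, weights as
# error precisions: sigma2 = sum(w r^2) / n,
# loglik = 0.5 * (sum(log w) - n * (log(2 pi sigma2) + 1)).
# Identical to stats::logLik() on lm(..., weights = w).
wls_loglik_value <- function(rss, n, sum_log_w) {
  sigma2 <- rss / n
  0.5 * (sum_log_w - n * (log(2 * pi * sigma2) + 1))
}

# Hot path used by the permutation engine: X and y pre-scaled by sqrt(w).
# Returns NA for rank-deficient designs (caller decides what that means).
ll_fast <- function(Xw, yw, n, sum_log_w) {
  fit <- stats::.lm.fit(Xw, yw)
  if (fit$rank < ncol(Xw)) return(NA_real_)
  rss <- sum(fit$residuals^2)
  if (rss <= 0) return(NA_real_)
  wls_loglik_value(rss, n, sum_log_w)
}

#' Fit a weighted linear model of a beta-diversity component
#'
#' Weighted least squares of the chosen response on the requested terms,
#' solved by a QR decomposition (deterministic; no iterative
#' optimisation). The weights are taken from the pair table, i.e. the
#' site-pair balancing weights. The Gaussian log-likelihood treats the
#' weights as error precisions and matches [stats::logLik()] on an
#' equivalent `lm(..., weights = )` fit; its weight-dependent constant
#' cancels in every log-likelihood ratio between models fitted to the
#' same pair table.
#'
#' @param pairs a `pair_table` from [build_pair_table()].
#' @param spec a [model_spec()].
#' @return object of class `wls_fit`: list with `coefficients` (named),
#'   `loglik`, `sigma2`, `n_obs`, `spec`.
#' @examples
#' d <- make_worked_example()
#' p <- build_pair_table(d)
#' fit_wls(p, model_spec("total", c("DeltaS", "DeltaT", "Lat")))
#' @export
fit_wls <- function(pairs, spec) {
  stopifnot(inherits(spec, "model_spec"))
  y <- pairs[[response_column(spec$response)]]
  w <- pairs$weight
  if (is.null(y) || is.null(w)) {
    stop("`pairs` must be a pair_table with response and weight columns",
         call. = FALSE)
  }
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  n <- length(y)
  p <- length(spec$terms) + 1L
  if (n <= p + 1L) {
    stop("too few observations (", n, ") for ", p, " coefficients",
         call. = FALSE)
  }
  X <- design_from_cov(pair_table_cov(pairs), spec$terms, n)
  fit <- stats::lm.wfit(X, y, w)
  if (anyNA(fit$coefficients)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)],
               collapse = ", "), call. = FALSE)
  }
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / n
  if (sigma2 < 1e-12) {
    stop("(near-)zero residual variance: degenerate Gaussian likelihood",
         call. = FALSE)
  }
  structure(
    list(
      coefficients = fit$coefficients,
      loglik = wls_loglik_value(rss, n, sum(log(w))),
      sigma2 = sigma2,
      n_obs = n,
      spec = spec
    ),
    class = "wls_fit"
  )
}

#' @export
print.wls_fit <- function(x, ...) {
  cat("<wls_fit> response:", x$spec$response,
      "| n =", x$n_obs, "| logLik =", format(x$loglik, digits = 6), "\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.wls_fit <- function(object, ...) object$coefficients

#' @export
logLik.wls_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$coefficients) + 1L,
            nobs = object$n_obs, class = "logLik")
}

#' Log-likelihood ratio between two nested weighted fits
#'
#' @param full,reduced `wls_fit` objects fitted to the same pair table,
#'   `reduced`'s terms a subset of `full`'s.
#' @return nonnegative log-likelihood ratio
#'   `loglik(full) - loglik(reduced)`.
#' @export
loglik_ratio <- function(full, reduced) {
  stopifnot(inherits(full, "wls_fit"), inherits(reduced, "wls_fit"))
  if (full$n_obs != reduced$n_obs) {
    stop("fits are not on the same data", call. = FALSE)
  }
  full$loglik - reduced$loglik
}

#' Serialise a fit for audit logs
#'
#' @param fit a `wls_fit`.
#' @return JSON string (terms, coefficients, loglik, n_obs).
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "wls_fit"))
  jsonlite::toJSON(
    list(
      response = fit$spec$response,
      terms = fit$spec$terms,
      coefficients = as.list(fit$coefficients),
      loglik = fit$loglik,
      sigma2 = fit$sigma2,
      n_obs = fit$n_obs
    ),
    auto_unbox = TRUE, digits = NA
  )
}
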