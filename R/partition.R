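#' Incidence components of a pair of communities
#'
#' Counts the species shared between two presence/absence communities
#' (`a`), unique to the first (`b`) and unique to the second (`c`). These
#' are the quantities every index in the Podani family is written in.
#'
#' @param first,second character (or other atomic) vectors of species
#'   identifiers; duplicates are ignored.
#' @return named integer vector `c(a =, b =, c =)`.
#' @examples
#' abc_counts(c("x", "y", "z"), c("y", "z", "w"))
#' @export
abc_counts <- function(first, second) {
  first <- unique(first)
  second <- unique(second)
  if (length(first) == 0 && length(second) == 0) {
    stop("both communities are empty: a + b + c = 0 leaves the ",
         "dissimilarity denominator undefined", call. = FALSE)
  }
  a <- length(intersect(first, second))
  c(a = a, b = length(first) - a, c = length(second) - a)
}

check_abc <- function(t) {
  if (!is.numeric(t) || length(t) != 3 || !all(c("a", "b", "c") %in% names(t))) {
    stop("expected a named vector c(a=, b=, c=) as produced by abc_counts()",
         call. = FALSE)
  }
  if (any(t < 0) || sum(t) < 1) stop("invalid abc triple", call. = FALSE)
  t
}

#' Total Jaccard dissimilarity from incidence components
#'
#' \eqn{(b + c) / (a + b + c)}: 0 for identical communities, 1 when no
#' species is shared.
#'
#' @param t named vector from [abc_counts()].
#' @return dissimilarity in `[0, 1]`.
#' @export
jaccard_total <- function(t) {
  t <- check_abc(t)
  unname((t["b"] + t["c"]) / sum(t))
}

#' Species-replacement component (Podani family, Jaccard base)
#'
#' \eqn{2 \min(b, c) / (a + b + c)}: the share of total dissimilarity due
#' to one-for-one substitution of species between the two communities.
#' Zero for nested communities.
#'
#' @inheritParams jaccard_total
#' @return component in `[0, 1]`.
#' @export
podani_replacement <- function(t) {
  t <- check_abc(t)
  unname(2 * min(t["b"], t["c"]) / sum(t))
}

#' Richness-difference component (Podani family, Jaccard base)
#'
#' \eqn{|b - c| / (a + b + c)}: the share of total dissimilarity due to
#' one community simply holding more species than the other. Together
#' with [podani_replacement()] it sums exactly to [jaccard_total()].
#'
#' @inheritParams jaccard_total
#' @return component in `[0, 1]`.
#' @export
podani_richness_difference <- function(t) {
  t <- check_abc(t)
  unname(abs(t["b"] - t["c"]) / sum(t))
}

#' Canonical pair enumeration for n items
#'
#' All unordered pairs (i, j), i < j, in row-major order:
#' (1,2), (1,3), ..., (1,n), (2,3), ... This ordering is part of the
#' public contract of every condensed pairwise structure in the package.
#'
#' @param n number of items (>= 2).
#' @return list with integer vectors `i` and `j`, each of length
#'   `n * (n - 1) / 2`.
#' @export
pair_indices <- function(n) {
  n <- as.integer(n)
  if (n < 2) stop("need at least 2 items for pairwise enumeration", call. = FALSE)
  list(
    i = rep.int(seq_len(n - 1L), times = (n - 1L):1L),
    j = rep.int(seq_len(n - 1L), times = (n - 1L):1L) + sequence((n - 1L):1L)
  )
}

#' Partition pairwise dissimilarity for all event pairs
#'
#' Computes, for every unordered pair of rows of a binary incidence
#' matrix, total Jaccard dissimilarity and its Podani-family species
#' replacement and richness difference components. Shared-species counts
#' for all pairs come from one cross-product of the incidence matrix, so
#' the per-pair components are exact integer ratios and the conservation
#' identity `replacement + richness_difference == total` holds to machine
#' precision.
#'
#' Results are condensed lower-triangle vectors of length
#' `n * (n - 1) / 2` in [pair_indices()] order (full matrices would be
#' wasteful at thousands of events).
#'
#' @param mat binary matrix (events x species); no all-zero rows.
#' @return object of class `beta_partition`: list with `event_ids`, the
#'   pair index vectors `i`, `j`, the numeric vectors `total`,
#'   `replacement`, `richness_difference`, and `n_events`.
#' @examples
#' m <- rbind(e1 = c(1, 1, 0), e2 = c(0, 1, 1))
#' partition_pairs(m)$total
#' @export
partition_pairs <- function(mat) {
  if (!is.matrix(mat)) stop("`mat` must be a matrix", call. = FALSE)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 events", call. = FALSE)
  storage.mode(mat) <- "double"
  rs <- unname(rowSums(mat))
  if (any(rs == 0)) {
    offenders <- rownames(mat)[rs == 0]
    if (is.null(offenders)) offenders <- which(rs == 0)
    stop("all-zero (empty) event row(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  idx <- pair_indices(n)
  A <- tcrossprod(mat)
  a <- A[cbind(idx$i, idx$j)]
  rm(A)
  b <- rs[idx$i] - a
  cc <- rs[idx$j] - a
  denom <- a + b + cc
  structure(
    list(
      event_ids = rownames(mat),
      i = idx$i,
      j = idx$j,
      total = (b + cc) / denom,
      replacement = 2 * pmin(b, cc) / denom,
      richness_difference = abs(b - cc) / denom,
      n_events = n
    ),
    class = "beta_partition"
  )
}

#' @export
print.beta_partition <- function(x, ...) {
  cat("<beta_partition> ", x$n_events, " events, ",
      length(x$total), " pairs\n", sep = "")
  cat("  mean total/replacement/richness-difference: ",
      paste(signif(c(mean(x$total), mean(x$replacement),
                     mean(x$richness_difference)), 3), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}
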