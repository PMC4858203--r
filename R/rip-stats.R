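#' Two-sample Kolmogorov-Smirnov comparison of mutation-count distributions
#'
#' Two-sided two-sample KS test of per-spore mutation totals. The D
#' statistic is the maximum absolute difference between the two empirical
#' CDFs, evaluated at the pooled observed values (so ties in the integer
#' counts are handled by construction). The p-value is exact — computed
#' conditionally on the observed tie pattern — when n * m <= 10000, and
#' asymptotic otherwise; the method used is reported.
#'
#' @param a,b numeric vectors of non-negative per-spore totals (any numeric
#'   samples are accepted).
#' @return `list(D, p, method)` with `method` `"exact"` or `"asymptotic"`.
#' @examples
#' ksCompare(c(1, 2, 3), c(10, 11, 12))  # D = 1, exact p = 0.1
#' @export
ksCompare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  exact <- length(a) * length(b) <= 10000
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                         exact = exact))
  list(D = unname(res$statistic),
       p = res$p.value,
       method = if (exact) "exact" else "asymptotic")
}

#' Congruence of replica crosses
#'
#' Replica crosses of the same construct should yield congruent
#' mutation-count distributions. This computes the two-sample KS p-value for
#' every unordered pair of crosses and reports the minimum (the "P (min)"
#' summary), without pooling and without any multiple-testing adjustment;
#' a minimum below 0.05 is flagged in a log message only.
#'
#' @param crosses list (length >= 1) of numeric vectors of per-spore totals,
#'   one per replica cross; names are used as cross labels.
#' @return `list(pMin, applicable, pairs)`. With a single cross the result
#'   is flagged not applicable (`pMin = NA`) rather than an error. `pairs`
#'   is a data.frame of each pair's D, p and method.
#' @export
replicaCongruence <- function(crosses) {
  stopifnot(is.list(crosses), length(crosses) >= 1)
  labels <- names(crosses)
  if (is.null(labels)) labels <- as.character(seq_along(crosses))
  if (length(crosses) < 2) {
    return(list(pMin = NA_real_, applicable = FALSE,
                pairs = data.frame(a = character(0), b = character(0),
                                   D = numeric(0), p = numeric(0),
                                   method = character(0))))
  }
  idx <- utils::combn(length(crosses), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- ksCompare(crosses[[i]], crosses[[j]])
    data.frame(a = labels[i], b = labels[j], D = r$D, p = r$p,
               method = r$method, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  pMin <- min(pairs$p)
  if (pMin < 0.05) {
    message("replica congruence: minimum pairwise KS p = ",
            signif(pMin, 3), " (< 0.05)")
  }
  list(pMin = pMin, applicable = TRUE, pairs = pairs)
}

#' Pearson correlation of two per-site mutation profiles
#'
#' Correlates the per-site mutated-spore counts of two constructs over a
#' region, the base-pair-level comparison used to ask whether the same sites
#' are mutated regardless of the homology pattern. Counts and percents give
#' identical r (Pearson correlation is scale-invariant), so profiles with
#' different spore numbers are directly comparable.
#'
#' @param p1,p2 [SiteProfile-class] objects (or plain numeric vectors) that
#'   cover `region`.
#' @param region optional `c(start, end)`, 1-based inclusive; default is the
#'   full common length.
#' @return Pearson r, or `NA` (with a warning) when either profile has zero
#'   variance over the region.
#' @export
profileCorrelation <- function(p1, p2, region = NULL) {
  x <- if (is(p1, "SiteProfile")) as.numeric(p1@siteCounts) else as.numeric(p1)
  y <- if (is(p2, "SiteProfile")) as.numeric(p2@siteCounts) else as.numeric(p2)
  if (is.null(region)) region <- c(1L, min(length(x), length(y)))
  if (region[1] < 1 || region[2] > length(x) || region[2] > length(y)) {
    stop("both profiles must cover the region [", region[1], ", ",
         region[2], "]", call. = FALSE)
  }
  sites <- region[1]:region[2]
  if (length(sites) < 3) {
    stop("region must contain at least 3 sites", call. = FALSE)
  }
  x <- x[sites]; y <- y[sites]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("profile correlation undefined: zero variance over the region",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)
}
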