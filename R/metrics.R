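# Agreement statistics: FAC2, MAPE, Spearman, fractional bias, Wilcoxon
# signed-rank, and agreement-category summaries.

.checkPaired <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (!all(is.finite(predicted)) || !all(is.finite(observed)))
    stop("paired series must be finite")
  if (any(predicted < 0) || any(observed < 0))
    stop("paired series must be non-negative")
  invisible(NULL)
}

#' Fraction of predictions within a factor of two
#'
#' FAC2: the fraction of pairs satisfying
#' `0.5 <= predicted / observed <= 2` (both boundaries included).  Pairs
#' with `observed = 0` have no defined ratio and are excluded; their number
#' is reported.
#'
#' @param predicted,observed non-negative numeric vectors of equal length.
#' @return list: `fac2` (fraction, `NA` when no usable pair), `n_used`,
#'   `n_excluded_zero_observed`.
#' @examples
#' fac2(c(1, 2, 10), c(2, 2, 2))  # ratios 0.5, 1, 5 -> 2/3
#' @export
fac2 <- function(predicted, observed) {
  .checkPaired(predicted, observed)
  use <- observed > 0
  ratio <- predicted[use] / observed[use]
  list(fac2 = if (any(use)) mean(ratio >= 0.5 & ratio <= 2) else NA_real_,
       n_used = sum(use), n_excluded_zero_observed = sum(!use))
}

#' Mean absolute percentage error
#'
#' Mean of `|predicted - observed| / observed`, with zero predictions
#' removed and, necessarily, zero observations removed as well (no defined
#' percentage error).  Both exclusion counts are reported so the effect of
#' each rule is visible.
#'
#' @inheritParams fac2
#' @return list: `mape` (`NA` when no usable pair), `n_used`,
#'   `n_excluded_zero_predicted`, `n_excluded_zero_observed`.
#' @examples
#' mape(c(2, 0, 3), c(4, 5, 3))  # keeps (2,4) and (3,3): (0.5 + 0)/2
#' @export
mape <- function(predicted, observed) {
  .checkPaired(predicted, observed)
  zp <- predicted == 0
  zo <- observed == 0
  use <- !zp & !zo
  list(mape = if (any(use))
         mean(abs(predicted[use] - observed[use]) / observed[use])
       else NA_real_,
       n_used = sum(use), n_excluded_zero_predicted = sum(zp),
       n_excluded_zero_observed = sum(zo & !zp))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), via
#' [stats::cor()].
#'
#' @inheritParams fac2
#' @return list: `rho` (`NA` with `constant = TRUE` when either series is
#'   constant), `n`, `constant`.
#' @export
spearmanRho <- function(predicted, observed) {
  .checkPaired(predicted, observed)
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    return(list(rho = NA_real_, n = length(predicted), constant = TRUE))
  list(rho = stats::cor(predicted, observed, method = "spearman"),
       n = length(predicted), constant = FALSE)
}

#' Fractional bias between two paired estimators
#'
#' `FB = (1/n) * sum(a - b) / sum((a + b) / 2)` - note the leading `1/n`,
#' which this implementation keeps because it is the definition the
#' downstream tables use; the conventional fractional bias (without `1/n`)
#' is available with `standard = TRUE`.  Antisymmetric under swapping the
#' two series.
#'
#' @param a,b paired non-negative estimates (e.g. ABODE and PPA per well).
#' @param standard drop the leading `1/n` (conventional FB).
#' @return list: `fb` (`NA` with `undefined = TRUE` when `sum(a + b) = 0`),
#'   `n`, `undefined`.
#' @examples
#' fractionalBias(c(4, 2), c(2, 2))  # (1/2) * (2 / 5) = 0.2
#' @export
fractionalBias <- function(a, b, standard = FALSE) {
  .checkPaired(a, b)
  n <- length(a)
  denom <- sum((a + b) / 2)
  if (denom == 0)
    return(list(fb = NA_real_, n = n, undefined = TRUE))
  fb <- sum(a - b) / denom
  if (!standard) fb <- fb / n
  list(fb = fb, n = n, undefined = FALSE)
}

.wilcoxonExactP <- function(ranks, wObs) {
  # exhaustive 2^n sign enumeration of the signed-rank statistic
  n <- length(ranks)
  w <- 0
  for (r in ranks) w <- c(w, w + r)  # distribution of sum over subsets
  mu <- sum(ranks) / 2
  pGe <- mean(w >= wObs - 1e-12)
  pLe <- mean(w <= wObs + 1e-12)
  min(1, 2 * min(pGe, pLe))
}

#' Wilcoxon signed-rank test for paired estimates
#'
#' Zero differences are dropped (Wilcoxon's original rule; `zeroes =
#' "pratt"` ranks them first and then discards, shifting the null mean and
#' variance).  Ties among the absolute differences get mid-ranks and a
#' tie-corrected variance.  The z statistic uses the normal approximation
#' with a continuity correction and is positive when `a` tends to exceed
#' `b`.  With 12 or fewer nonzero differences the two-sided p-value is
#' computed by exhaustive sign enumeration instead of the approximation.
#'
#' @param a,b paired numeric vectors.
#' @param zeroes `"drop"` (default) or `"pratt"`.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when the nonzero count is at most 12.
#' @return list: `z`, `p`, `n` (input pairs), `n_nonzero`, `method`
#'   (`"exact"` or `"normal"`), `degenerate` (`TRUE` when all differences
#'   are zero, with `z = 0`, `p = 1`).
#' @export
wilcoxonSignedRank <- function(a, b, zeroes = c("drop", "pratt"),
                               exact = NULL) {
  zeroes <- match.arg(zeroes)
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  if (!all(is.finite(d))) stop("differences must be finite")
  nz <- d != 0
  nNonzero <- sum(nz)
  if (nNonzero == 0L)
    return(list(z = 0, p = 1, n = length(d), n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  if (zeroes == "drop") {
    dd <- d[nz]
    r <- rank(abs(dd))
    w <- sum(r[dd > 0])
    n <- length(dd)
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  } else {
    r <- rank(abs(d))  # zeros included in the ranking (Pratt)
    w <- sum(r[d > 0])
    n <- length(d)
    n0 <- sum(!nz)
    mu <- (n * (n + 1) - n0 * (n0 + 1)) / 4
    ties <- table(r[nz])
    sigma2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
    r <- r[nz]
    dd <- d[nz]
  }
  if (sigma2 <= 0)
    return(list(z = 0, p = 1, n = length(d), n_nonzero = nNonzero,
                method = "degenerate", degenerate = TRUE))
  cc <- min(0.5, abs(w - mu))  # continuity correction toward the mean
  z <- (w - mu - sign(w - mu) * cc) / sqrt(sigma2)
  useExact <- if (is.null(exact)) nNonzero <= 12L else isTRUE(exact)
  p <- if (useExact) {
    if (zeroes == "drop") .wilcoxonExactP(r, w)
    else .wilcoxonExactP(r, w)  # Pratt: same enumeration over nonzero ranks
  } else 2 * stats::pnorm(-abs(z))
  list(z = z, p = min(1, p), n = length(d), n_nonzero = nNonzero,
       method = if (useExact) "exact" else "normal", degenerate = FALSE)
}

#' Agreement-category counts per stratum
#'
#' Tabulates [classifyAgreement()] classes, optionally split by a stratum
#' such as state.  All five categories appear in the output even when
#' empty, and counts sum to the number of records.
#'
#' @param classes character vector of agreement classes.
#' @param stratum optional parallel vector (e.g. state).
#' @return a table: categories, or categories x stratum when supplied.
#' @export
agreementSummary <- function(classes, stratum = NULL) {
  lev <- c("both_positive", "both_zero", "fp_low", "fp_high", "other")
  f <- factor(classes, levels = lev)
  if (is.null(stratum)) table(f, dnn = "agreement")
  else table(agreement = f, stratum = stratum)
}

#' Bundle evaluation metrics into a report
#'
#' Computes the full metric set for a pair of series (e.g. candidate RHU
#' counts vs census housing units, or ABODE vs PPA per well).
#'
#' @param predicted,observed paired non-negative series.
#' @param agreement optional character vector of agreement classes to count.
#' @return a [MetricsReport-class].
#' @export
metricsReport <- function(predicted, observed, agreement = NULL) {
  f <- fac2(predicted, observed)
  m <- mape(predicted, observed)
  s <- spearmanRho(predicted, observed)
  fb <- fractionalBias(predicted, observed)
  w <- wilcoxonSignedRank(predicted, observed)
  ac <- if (is.null(agreement)) integer(0) else {
    t <- agreementSummary(agreement)
    stats::setNames(as.integer(t), names(t))
  }
  new("MetricsReport", fac2 = f$fac2, mape = m$mape, spearmanRho = s$rho,
      fractionalBias = fb$fb, wilcoxonZ = w$z, wilcoxonP = w$p,
      nUsed = c(fac2 = f$n_used, mape = m$n_used, spearman = s$n,
                fb = fb$n, wilcoxon = w$n_nonzero),
      agreementCounts = ac)
}

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  FAC2            %.4f  (n = %d)\n", object@fac2,
              object@nUsed[["fac2"]]))
  cat(sprintf("  MAPE            %.4f  (n = %d)\n", object@mape,
              object@nUsed[["mape"]]))
  cat(sprintf("  Spearman rho    %.4f  (n = %d)\n", object@spearmanRho,
              object@nUsed[["spearman"]]))
  cat(sprintf("  Fractional bias %.4f  (n = %d)\n", object@fractionalBias,
              object@nUsed[["fb"]]))
  cat(sprintf("  Wilcoxon        z = %.3f, p = %.4g  (nonzero n = %d)\n",
              object@wilcoxonZ, object@wilcoxonP,
              object@nUsed[["wilcoxon"]]))
  if (length(object@agreementCounts)) {
    cat("  Agreement:",
        paste(names(object@agreementCounts), object@agreementCounts,
              sep = "=", collapse = ", "), "\n")
  }
})
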