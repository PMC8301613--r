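#' Read a per-amplicon coverage table
#'
#' Expects a TSV with columns `amplicon_id`, `chrom`, `start`, `end`
#' (1-based inclusive) and `mean_coverage`, as exported by coverage tools
#' run on targeted amplicon panels.
#'
#' @param path TSV file.
#' @return data.frame with the five columns, types coerced.
#' @export
readAmpliconCoverage <- function(path) {
  if (!file.exists(path)) stop("coverage table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon_id", "chrom", "start", "end", "mean_coverage")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("coverage table lacks column(s): ", paste(missing, collapse = ", "))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$mean_coverage <- as.numeric(df$mean_coverage)
  if (any(df$start > df$end)) stop("amplicon start must be <= end")
  if (any(df$mean_coverage < 0)) stop("mean_coverage must be >= 0")
  df[, need]
}

#' Coverage summary: median, uniformity, normalized per-amplicon coverage
#'
#' Uniformity is the fraction of amplicons whose mean coverage exceeds
#' 20% of the median amplicon coverage (strictly greater, per the "more
#' than 20% of median" definition); normalized coverage divides each
#' amplicon by the median. Both are scale-free: multiplying all
#' coverages by a constant changes neither.
#'
#' @param x numeric vector of per-amplicon mean coverages, or a
#'   data.frame with a `mean_coverage` column (as from
#'   [readAmpliconCoverage()]).
#' @param uniformityFraction the "20%-of-median" factor.
#' @return list with `median`, `uniformity`, and `normalized` (numeric
#'   vector aligned with the input).
#' @examples
#' coverageSummary(c(10, 100, 100, 100, 15))  # uniformity 0.6
#' @export
coverageSummary <- function(x, uniformityFraction = 0.2) {
  cov <- if (is.data.frame(x)) x$mean_coverage else as.numeric(x)
  if (length(cov) == 0) stop("no amplicons supplied")
  if (any(is.na(cov)) || any(cov < 0))
    stop("coverages must be non-negative and non-missing")
  med <- stats::median(cov)
  if (med == 0) stop("median coverage is 0: normalized coverage undefined")
  list(median = med,
       uniformity = mean(cov > uniformityFraction * med),
       normalized = cov / med)
}

.rankSumTail <- function(ranks, nA) {
  ## distribution of the group-A rank sum over all C(n, nA) assignments
  n <- length(ranks)
  sums <- utils::combn(n, nA, FUN = function(idx) sum(ranks[idx]))
  sums
}

#' Exact two-sided Mann-Whitney U test
#'
#' For small samples (`n_a + n_b <= 14`) the null distribution of the
#' rank sum is enumerated over all assignments of the pooled midranks to
#' the two groups, so ties are handled exactly; the two-sided p-value is
#' twice the smaller tail (including the observed statistic), capped at
#' 1. Larger samples use the normal approximation with tie correction
#' and continuity correction.
#'
#' Complete separation of two groups of five yields p = 2/252, which
#' prints as 0.0079 -- the familiar floor of a 5-vs-5 exact rank test.
#'
#' @param groupA,groupB numeric vectors, both non-empty.
#' @return two-sided p-value in (0, 1].
#' @examples
#' mwuExact(1:5, 6:10)  # 2/252
#' @export
mwuExact <- function(groupA, groupB) {
  a <- as.numeric(groupA)
  b <- as.numeric(groupB)
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty")
  nA <- length(a)
  n <- nA + length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)            # midranks under ties
  ra <- sum(ranks[seq_len(nA)])
  if (n <= 14) {
    sums <- .rankSumTail(ranks, nA)
    p_lo <- mean(sums <= ra + 1e-9)
    p_hi <- mean(sums >= ra - 1e-9)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  nB <- n - nA
  u <- ra - nA * (nA + 1) / 2
  mu <- nA * nB / 2
  tie_tab <- table(pooled)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nA * nB / 12 * (n + 1 - tie_corr)
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-max(z, 0)))
}
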