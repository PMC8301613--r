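#' Estimate the smear-noise VAF boundary from paired call sets
#'
#' Smear-specific artifacts accumulate below a characteristic VAF in
#' degraded slide-derived DNA, while genuine variants shared with the
#' paired fresh cells span higher frequencies. Visual inspection of the
#' VAF distribution of smear-unique calls is commonly used to pick the
#' noise threshold; this estimator replaces the visual call with a
#' reproducible rule.
#'
#' The VAF axis is binned into half-open intervals
#' `[0, gridStep), [gridStep, 2 gridStep), ...` up to `vafMax`. For each
#' bin the enrichment ratio
#' \deqn{r_b = \frac{\#\,\mathrm{smear\ unique\ in\ } b}{\#\,\mathrm{shared\ in\ } b + 1}}
#' is computed; the `+1` regularizes bins with no shared variants so an
#' empty denominator cannot create a spurious run. The boundary is the
#' upper edge of the last bin of the maximal initial contiguous run with
#' `r_b >= rho`; if the first bin already fails, no boundary is returned.
#' Because the rule is ratio-based, duplicating every input VAF leaves
#' the estimate unchanged up to the `+1` regularizer.
#'
#' @param smearUniqueVafs VAF fractions of smear-unique calls (after
#'   panel-of-normals subtraction).
#' @param sharedVafs VAF fractions of calls shared with the paired BMC
#'   sample.
#' @param gridStep bin width as a VAF fraction (default 0.5%).
#' @param vafMax search ceiling (default 10%).
#' @param rho minimum enrichment of smear-unique over shared calls for a
#'   bin to count as noise-dominated.
#' @return a [BoundaryEstimate-class]; the boundary is `NA` when the
#'   smear-unique input is empty or the first bin is not enriched.
#' @examples
#' set.seed(1)
#' art <- runif(400, 0.001, 0.025)
#' som <- runif(60, 0.05, 0.5)
#' noiseBoundary(estimateNoiseBoundary(art, som))  # 0.025
#' @export
estimateNoiseBoundary <- function(smearUniqueVafs, sharedVafs,
                                  gridStep = 0.005, vafMax = 0.10,
                                  rho = 2.0) {
  if (gridStep <= 0) stop("gridStep must be positive")
  if (vafMax > 1 || vafMax <= 0) stop("vafMax must lie in (0, 1]")
  smearUniqueVafs <- smearUniqueVafs[!is.na(smearUniqueVafs)]
  sharedVafs <- sharedVafs[!is.na(sharedVafs)]
  nbin <- ceiling(vafMax / gridStep - 1e-9)
  lo <- (seq_len(nbin) - 1) * gridStep
  hi <- lo + gridStep
  count_bins <- function(v) {
    idx <- floor(v / gridStep) + 1
    idx <- idx[idx >= 1 & idx <= nbin]
    tabulate(idx, nbins = nbin)
  }
  n_su <- count_bins(smearUniqueVafs)
  n_sh <- count_bins(sharedVafs)
  ratio <- n_su / (n_sh + 1)
  ok <- ratio >= rho
  run_len <- if (length(ok) == 0 || !ok[1]) 0 else {
    r <- rle(ok)
    r$lengths[1]
  }
  boundary <- if (run_len == 0 || length(smearUniqueVafs) == 0) NA_real_
              else hi[run_len]
  new("BoundaryEstimate", boundary = boundary, gridStep = gridStep,
      ratios = data.frame(bin_lo = lo, bin_hi = hi, n_smear_unique = n_su,
                          n_shared = n_sh, ratio = ratio),
      params = list(rho = rho, vafMax = vafMax))
}
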