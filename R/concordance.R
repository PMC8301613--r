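#' Partition a paired smear/BMC sample into shared and unique variants
#'
#' Matches the calls of a smear [CallSet-class] against its paired fresh
#' bone marrow cell (BMC) CallSet by normalized variant key and returns
#' the three-way partition: variants detected in both members, only in
#' the smear, or only in the BMC. Swapping the inputs swaps the two
#' unique sets and leaves the shared set unchanged.
#'
#' @param smear,bmc CallSets of the same caller class for the two members
#'   of the pair.
#' @param pairId identifier for the pair; defaults to the smear sample id.
#' @return a [PairedComparison-class].
#' @examples
#' mk <- function(pos, vaf, tis) CallSet(
#'   data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
#'              vaf = vaf, depth = 100, filter = "PASS"),
#'   "P1", tis, "somatic")
#' cmp <- classifyPaired(mk(1:3, 0.3, "smear"), mk(2:4, 0.32, "bmc"))
#' concordanceFractions(cmp)
#' @export
classifyPaired <- function(smear, bmc, pairId = sampleId(smear)) {
  stopifnot(is(smear, "CallSet"), is(bmc, "CallSet"))
  if (tissue(smear) != "smear" || tissue(bmc) != "bmc")
    stop("classifyPaired expects a smear CallSet and a bmc CallSet")
  if (callerClass(smear) != callerClass(bmc))
    stop("caller class mismatch: ", callerClass(smear), " vs ",
         callerClass(bmc))
  sv <- variants(smear)
  bv <- variants(bmc)
  sk <- variantKey(sv)
  bk <- variantKey(bv)
  in_both <- sk %in% bk
  sh_s <- sv[in_both, , drop = FALSE]
  sh_b <- bv[match(sk[in_both], bk), , drop = FALSE]
  shared <- if (nrow(sh_s) > 0)
    data.frame(key = variantKey(sh_s), chrom = sh_s$chrom, pos = sh_s$pos,
               ref = sh_s$ref, alt = sh_s$alt,
               smear_vaf = sh_s$vaf, bmc_vaf = sh_b$vaf,
               smear_depth = sh_s$depth, bmc_depth = sh_b$depth,
               gene = sh_s$gene, known_snp = sh_s$known_snp,
               region = sh_s$region, stringsAsFactors = FALSE)
  else
    data.frame(key = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), smear_vaf = numeric(),
               bmc_vaf = numeric(), smear_depth = numeric(),
               bmc_depth = numeric(), gene = character(),
               known_snp = logical(), region = character(),
               stringsAsFactors = FALSE)
  new("PairedComparison", pairId = as.character(pairId),
      callerClass = callerClass(smear), shared = shared,
      smearUnique = sv[!in_both, , drop = FALSE],
      bmcUnique = bv[!(bk %in% sk), , drop = FALSE])
}

.partitionCounts <- function(cmp) {
  c(shared = nrow(cmp@shared), smear_unique = nrow(cmp@smearUnique),
    bmc_unique = nrow(cmp@bmcUnique))
}

#' Fractions of shared and sample-unique variants
#'
#' Computes, over the distinct keys in the union of a pair (shared keys
#' counted once), the fraction of variants that are shared, smear-unique
#' and BMC-unique. A list of comparisons is pooled by concatenating the
#' per-pair partitions before computing (per-pair duplicates across
#' patients are not re-deduplicated, matching a combined multi-pair
#' summary).
#'
#' @param x a [PairedComparison-class] or a list of them.
#' @return named numeric vector `shared`, `smear_unique`, `bmc_unique`
#'   summing to 1.
#' @export
concordanceFractions <- function(x) {
  if (is(x, "PairedComparison")) x <- list(x)
  stopifnot(length(x) > 0, all(vapply(x, is, TRUE, "PairedComparison")))
  counts <- Reduce(`+`, lapply(x, .partitionCounts))
  total <- sum(counts)
  if (total == 0) stop("empty union: no variants in any pair")
  counts / total
}

#' VAF agreement of shared variants between smear and BMC
#'
#' For every shared variant of a pair, tabulates the VAF observed in the
#' BMC and in the smear, and summarises the agreement by the maximum
#' absolute difference and (when at least three points with variance are
#' available) the Pearson correlation.
#'
#' @param cmp a [PairedComparison-class] with a non-empty shared set.
#' @return list with `table` (columns `key`, `bmc_vaf`, `smear_vaf`),
#'   `max_abs_diff`, and `correlation` (`NA` when undefined).
#' @export
vafConcordance <- function(cmp) {
  stopifnot(is(cmp, "PairedComparison"))
  sh <- cmp@shared
  if (nrow(sh) == 0) stop("no shared variants: VAF concordance undefined")
  tab <- data.frame(key = sh$key, bmc_vaf = sh$bmc_vaf,
                    smear_vaf = sh$smear_vaf, stringsAsFactors = FALSE)
  corr <- NA_real_
  if (nrow(tab) >= 3 && stats::sd(tab$bmc_vaf) > 0 &&
      stats::sd(tab$smear_vaf) > 0)
    corr <- stats::cor(tab$bmc_vaf, tab$smear_vaf)
  list(table = tab, max_abs_diff = max(abs(tab$smear_vaf - tab$bmc_vaf)),
       correlation = corr)
}

#' Long-format VAF-by-depth table for plotting variant distributions
#'
#' Flattens a CallSet or a paired comparison into one row per variant
#' occurrence with its class label, the layout used to plot VAF against
#' read depth colour-coded by shared/unique status. For a
#' [PairedComparison-class], shared variants contribute one row per
#' tissue (they were observed twice); unique variants contribute one row.
#'
#' @param x a [CallSet-class] or [PairedComparison-class].
#' @param pairId label for the `pair_id` column when `x` is a CallSet.
#' @return data.frame with columns `pair_id`, `class`, `tissue`, `chrom`,
#'   `pos`, `ref`, `alt`, `vaf_percent`, `depth`.
#' @export
vafDepthTable <- function(x, pairId = NULL) {
  row_of <- function(v, cls, tis, pid)
    data.frame(pair_id = rep(pid, nrow(v)), class = rep(cls, nrow(v)),
               tissue = rep(tis, nrow(v)), chrom = v$chrom, pos = v$pos,
               ref = v$ref, alt = v$alt, vaf_percent = 100 * v$vaf,
               depth = v$depth, stringsAsFactors = FALSE)
  empty <- data.frame(pair_id = character(), class = character(),
                      tissue = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      vaf_percent = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE)
  if (is(x, "CallSet")) {
    if (length(x) == 0) return(empty)
    pid <- if (is.null(pairId)) sampleId(x) else pairId
    return(row_of(variants(x), "all", tissue(x), pid))
  }
  stopifnot(is(x, "PairedComparison"))
  sh <- x@shared
  pieces <- list(empty)
  if (nrow(sh) > 0) {
    sm <- data.frame(chrom = sh$chrom, pos = sh$pos, ref = sh$ref,
                     alt = sh$alt, vaf = sh$smear_vaf, depth = sh$smear_depth)
    bm <- data.frame(chrom = sh$chrom, pos = sh$pos, ref = sh$ref,
                     alt = sh$alt, vaf = sh$bmc_vaf, depth = sh$bmc_depth)
    pieces <- c(pieces, list(row_of(sm, "shared", "smear", x@pairId),
                             row_of(bm, "shared", "bmc", x@pairId)))
  }
  if (nrow(x@smearUnique) > 0)
    pieces <- c(pieces, list(row_of(x@smearUnique, "smear_unique", "smear",
                                    x@pairId)))
  if (nrow(x@bmcUnique) > 0)
    pieces <- c(pieces, list(row_of(x@bmcUnique, "bmc_unique", "bmc",
                                    x@pairId)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
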