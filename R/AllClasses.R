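#' @include AllGenerics.R
NULL

## Central S4 containers. Variant tables are plain data.frames inside the
## objects: one row per normalized allele with the columns produced by
## normalizeVariant() plus per-call evidence and annotation.

.VARIANT_COLS <- c("chrom", "pos", "ref", "alt", "vaf", "depth", "filter")
.ANNOT_COLS <- c("gene", "hgvs_c", "hgvs_p", "population_af", "region",
                 "known_snp", "exon_distance", "qd", "mq", "fs")

#' Key string for a normalized variant
#'
#' Builds the `chrom:pos:ref:alt` identity used throughout the package to
#' match calls between samples, callers and the panel of normals.
#'
#' @param x data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return character vector of keys, one per row.
#' @export
variantKey <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

.emptyVariantTable <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), vaf = numeric(), depth = numeric(),
             filter = character(), gene = character(), hgvs_c = character(),
             hgvs_p = character(), population_af = numeric(),
             region = character(), known_snp = logical(),
             exon_distance = numeric(), qd = numeric(), mq = numeric(),
             fs = numeric(), stringsAsFactors = FALSE)
}

.completeVariantTable <- function(df) {
  if (nrow(df) == 0 && length(setdiff(.VARIANT_COLS, names(df))) > 0)
    return(.emptyVariantTable())
  missing <- setdiff(.VARIANT_COLS, names(df))
  if (length(missing) > 0)
    stop("variant table lacks required column(s): ",
         paste(missing, collapse = ", "))
  defaults <- list(gene = "", hgvs_c = "", hgvs_p = "",
                   population_af = NA_real_, region = "unknown",
                   known_snp = FALSE, exon_distance = NA_real_,
                   qd = NA_real_, mq = NA_real_, fs = NA_real_)
  for (nm in names(defaults))
    if (is.null(df[[nm]])) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  df$pos <- as.integer(df$pos)
  rownames(df) <- NULL
  df[, c(.VARIANT_COLS, .ANNOT_COLS)]
}

#' CallSet: all calls for one sample, tissue and caller class
#'
#' A `CallSet` holds the normalized variant calls of one sequencing sample
#' (a bone marrow smear or its paired fresh bone marrow cell, BMC, sample)
#' produced by one caller class: `"germline"` for a germline-style caller
#' tuned to high-frequency variants, `"somatic"` for a somatic-style caller
#' sensitive to low allele fractions. Variant identity is the normalized
#' `(chrom, pos, ref, alt)` key; a `CallSet` never contains two rows with
#' the same key.
#'
#' The constructor collapses duplicate keys to the record with the greater
#' read depth, so callers that emit a locus twice do not violate the
#' uniqueness invariant.
#'
#' @param variants data.frame of normalized calls. Required columns:
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `vaf` (fraction in \[0,1\]),
#'   `depth`, `filter` (caller filter labels, `;`-separated, `"PASS"` when
#'   clean). Optional annotation columns (`gene`, `hgvs_c`, `hgvs_p`,
#'   `population_af`, `region`, `known_snp`, `exon_distance`, `qd`, `mq`,
#'   `fs`) are filled with neutral defaults when absent.
#' @param sampleId sample identifier.
#' @param tissue `"smear"` or `"bmc"`.
#' @param callerClass `"germline"` or `"somatic"`.
#' @param x a `CallSet`.
#' @param ... unused.
#'
#' @return `CallSet()` returns a validated object; `variants()` its variant
#'   data.frame, `variantKeys()` the normalized keys, and the remaining
#'   accessors the corresponding slots.
#'
#' @examples
#' v <- data.frame(chrom = "FLT3", pos = c(100L, 200L), ref = "A",
#'                 alt = c("T", "G"), vaf = c(0.45, 0.02),
#'                 depth = c(500, 60), filter = "PASS")
#' cs <- CallSet(v, sampleId = "P1", tissue = "smear", callerClass = "somatic")
#' length(cs)
#' variantKeys(cs)
#' @aliases variants sampleId tissue callerClass variantKeys
#' @export
setClass("CallSet",
         representation(sampleId = "character", tissue = "character",
                        callerClass = "character", variants = "data.frame"))

setValidity("CallSet", function(object) {
  msg <- character()
  if (length(object@tissue) != 1 || !object@tissue %in% c("smear", "bmc"))
    msg <- c(msg, "tissue must be 'smear' or 'bmc'")
  if (length(object@callerClass) != 1 ||
      !object@callerClass %in% c("germline", "somatic"))
    msg <- c(msg, "callerClass must be 'germline' or 'somatic'")
  v <- object@variants
  if (nrow(v) > 0) {
    if (anyDuplicated(variantKey(v)))
      msg <- c(msg, "duplicate normalized variant keys")
    if (any(v$pos < 1)) msg <- c(msg, "pos must be >= 1")
    if (any(v$ref == v$alt)) msg <- c(msg, "ref must differ from alt")
    if (any(!nzchar(v$ref)) || any(!nzchar(v$alt)))
      msg <- c(msg, "ref and alt must be non-empty")
    if (any(v$vaf < 0 | v$vaf > 1)) msg <- c(msg, "vaf must lie in [0, 1]")
    if (any(v$depth < 0)) msg <- c(msg, "depth must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname CallSet-class
#' @export
CallSet <- function(variants, sampleId, tissue, callerClass) {
  variants <- as.data.frame(variants)
  if (!is.null(variants$caller_class)) {
    if (!all(variants$caller_class == callerClass))
      stop("records with mixed or conflicting caller_class")
    variants$caller_class <- NULL
  }
  v <- .completeVariantTable(variants)
  if (nrow(v) > 0) {
    key <- variantKey(v)
    if (anyDuplicated(key)) {
      ## keep, per key, the record with the greater depth (first on ties)
      ord <- order(match(key, unique(key)), -v$depth)
      v <- v[ord, , drop = FALSE]
      v <- v[!duplicated(variantKey(v)), , drop = FALSE]
      rownames(v) <- NULL
    }
  }
  new("CallSet", sampleId = as.character(sampleId), tissue = tissue,
      callerClass = callerClass, variants = v)
}

#' @rdname CallSet-class
#' @export
setMethod("variants", "CallSet", function(x, ...) x@variants)

#' @rdname CallSet-class
#' @export
setMethod("sampleId", "CallSet", function(x) x@sampleId)

#' @rdname CallSet-class
#' @export
setMethod("tissue", "CallSet", function(x) x@tissue)

#' @rdname CallSet-class
#' @export
setMethod("callerClass", "CallSet", function(x) x@callerClass)

#' @rdname CallSet-class
#' @export
setMethod("variantKeys", "CallSet", function(x) variantKey(x@variants))

#' @rdname CallSet-class
#' @export
setMethod("length", "CallSet", function(x) nrow(x@variants))

setMethod("show", "CallSet", function(object) {
  cat("CallSet for sample", object@sampleId,
      sprintf("(%s, %s caller)\n", object@tissue, object@callerClass))
  cat("  ", nrow(object@variants), "normalized variant calls\n")
  if (nrow(object@variants) > 0) {
    vafp <- 100 * object@variants$vaf
    cat(sprintf("   VAF range %.2f%%-%.2f%%, median depth %.0f\n",
                min(vafp), max(vafp), stats::median(object@variants$depth)))
  }
})

#' PanelOfNormals: recurrent assay artifacts from tumor-free samples
#'
#' A multiset of normalized variant keys observed across sequencing data
#' from patients without myeloid malignancies. Keys observed in at least
#' `minSamples` of the `nSamples` merged normals are considered assay
#' artifacts and are removed by [subtractPanel()].
#'
#' @param x a `PanelOfNormals`.
#' @return `panelEntries()` returns the named integer vector of per-key
#'   member counts.
#' @seealso [buildPanelOfNormals()], [subtractPanel()]
#' @aliases panelEntries
#' @export
setClass("PanelOfNormals",
         representation(entries = "integer", nSamples = "integer",
                        minSamples = "integer"))

setValidity("PanelOfNormals", function(object) {
  msg <- character()
  if (object@nSamples < 1) msg <- c(msg, "nSamples must be >= 1")
  if (object@minSamples < 1) msg <- c(msg, "minSamples must be >= 1")
  if (length(object@entries) > 0) {
    if (is.null(names(object@entries)) || any(!nzchar(names(object@entries))))
      msg <- c(msg, "entries must be named by variant key")
    if (any(object@entries < 1 | object@entries > object@nSamples))
      msg <- c(msg, "entry counts must lie in [1, nSamples]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PanelOfNormals-class
#' @export
setMethod("panelEntries", "PanelOfNormals", function(x) x@entries)

#' @rdname PanelOfNormals-class
#' @export
setMethod("length", "PanelOfNormals", function(x) length(x@entries))

setMethod("show", "PanelOfNormals", function(object) {
  cat("PanelOfNormals merged from", object@nSamples, "normal samples\n")
  cat("  ", length(object@entries), "distinct keys;",
      sum(object@entries >= object@minSamples),
      sprintf("subtractable at minSamples=%d\n", object@minSamples))
})

#' PairedComparison: smear vs BMC partition of one sample pair
#'
#' The three-way partition of the calls of a paired smear/BMC sample by
#' normalized key: variants detected in both members (`shared`), only in
#' the smear (`smearUnique`), or only in the fresh cells (`bmcUnique`).
#' Shared rows carry the per-tissue evidence side by side (`smear_vaf`,
#' `bmc_vaf`, `smear_depth`, `bmc_depth`).
#'
#' @param x a `PairedComparison`.
#' @seealso [classifyPaired()], [concordanceFractions()], [vafConcordance()]
#' @aliases sharedVariants smearUnique bmcUnique
#' @export
setClass("PairedComparison",
         representation(pairId = "character", callerClass = "character",
                        shared = "data.frame", smearUnique = "data.frame",
                        bmcUnique = "data.frame"))

setValidity("PairedComparison", function(object) {
  keys <- list(object@shared$key, variantKey(object@smearUnique),
               variantKey(object@bmcUnique))
  all_keys <- unlist(keys)
  if (anyDuplicated(all_keys))
    return("shared, smear-unique and BMC-unique key sets must be disjoint")
  TRUE
})

#' @rdname PairedComparison-class
#' @export
setMethod("sharedVariants", "PairedComparison", function(x) x@shared)

#' @rdname PairedComparison-class
#' @export
setMethod("smearUnique", "PairedComparison", function(x) x@smearUnique)

#' @rdname PairedComparison-class
#' @export
setMethod("bmcUnique", "PairedComparison", function(x) x@bmcUnique)

setMethod("show", "PairedComparison", function(object) {
  n_sh <- nrow(object@shared)
  n_su <- nrow(object@smearUnique)
  n_bu <- nrow(object@bmcUnique)
  tot <- n_sh + n_su + n_bu
  cat("PairedComparison", object@pairId,
      sprintf("(%s caller)\n", object@callerClass))
  if (tot > 0)
    cat(sprintf("   shared %d (%.1f%%), smear-unique %d, BMC-unique %d\n",
                n_sh, 100 * n_sh / tot, n_su, n_bu))
  else cat("   no variants\n")
})

#' FilterReport: per-stage accounting of the noise-reduction cascade
#'
#' Records, for each filtering stage in the order applied, how many calls
#' entered, were removed, and were retained. Counts are conserved: the
#' retained count of one stage is the input count of the next.
#'
#' @param x a `FilterReport`.
#' @return `filterStages()` returns the data.frame with columns `stage`,
#'   `n_in`, `removed`, `retained`.
#' @seealso [runCascade()]
#' @aliases filterStages
#' @export
setClass("FilterReport", representation(stages = "data.frame"))

setValidity("FilterReport", function(object) {
  s <- object@stages
  msg <- character()
  if (!all(c("stage", "n_in", "removed", "retained") %in% names(s)))
    return("stages must have columns stage, n_in, removed, retained")
  if (nrow(s) > 0) {
    if (any(s$retained != s$n_in - s$removed))
      msg <- c(msg, "retained must equal n_in - removed at every stage")
    if (nrow(s) > 1 && any(s$n_in[-1] != s$retained[-nrow(s)]))
      msg <- c(msg, "stage k+1 input must equal stage k retained")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FilterReport-class
#' @export
setMethod("filterStages", "FilterReport", function(x) x@stages)

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport,", nrow(object@stages), "stages\n")
  print(object@stages, row.names = FALSE)
})

#' BoundaryEstimate: algorithmic smear-noise VAF boundary
#'
#' Result of [estimateNoiseBoundary()]: the selected boundary (a multiple
#' of the grid step, or `NA` when no enriched low-VAF run exists), the
#' per-bin smear-unique/shared enrichment table, and the parameters used.
#'
#' @param x a `BoundaryEstimate`.
#' @return `noiseBoundary()` returns the boundary as a VAF fraction (or
#'   `NA`); `enrichmentRatios()` the per-bin table.
#' @aliases noiseBoundary enrichmentRatios
#' @export
setClass("BoundaryEstimate",
         representation(boundary = "numeric", gridStep = "numeric",
                        ratios = "data.frame", params = "list"))

setValidity("BoundaryEstimate", function(object) {
  b <- object@boundary
  if (length(b) != 1) return("boundary must be a single value (possibly NA)")
  if (!is.na(b)) {
    k <- b / object@gridStep
    if (abs(k - round(k)) > 1e-8)
      return("boundary must be a multiple of gridStep")
    if (b > object@params$vafMax + 1e-12)
      return("boundary must not exceed the search ceiling")
  }
  TRUE
})

#' @rdname BoundaryEstimate-class
#' @export
setMethod("noiseBoundary", "BoundaryEstimate", function(x) x@boundary)

#' @rdname BoundaryEstimate-class
#' @export
setMethod("enrichmentRatios", "BoundaryEstimate", function(x) x@ratios)

setMethod("show", "BoundaryEstimate", function(object) {
  if (is.na(object@boundary)) {
    cat("BoundaryEstimate: no enriched low-VAF run found\n")
  } else {
    cat(sprintf("BoundaryEstimate: noise boundary at %.2f%% VAF",
                100 * object@boundary),
        sprintf("(grid %.2f%%, rho %.1f)\n", 100 * object@gridStep,
                object@params$rho))
  }
})
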