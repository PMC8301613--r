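## The noise-reduction cascade. Each single filter takes a CallSet and
## returns list(callset = retained CallSet, removed = data.frame of the
## removed calls); runCascade() chains them in the fixed order
##   caller-flag filter (somatic) / hard filters (germline)
##   -> panel-of-normals subtraction -> VAF threshold -> population-AF
## and accounts for every input call exactly once.

.splitByKeep <- function(cs, keep) {
  v <- variants(cs)
  kept <- new("CallSet", sampleId = sampleId(cs), tissue = tissue(cs),
              callerClass = callerClass(cs),
              variants = {
                k <- v[keep, , drop = FALSE]; rownames(k) <- NULL; k
              })
  removed <- v[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  list(callset = kept, removed = removed)
}

#' Keep only calls that pass the caller's own filters
#'
#' Retains exactly the records whose filter flag set is `{PASS}`; any
#' failure label emitted by the upstream somatic caller's filtering stage
#' (consumed from the VCF FILTER column, never recomputed) removes the
#' call.
#'
#' @param cs a [CallSet-class].
#' @return list with `callset` (retained) and `removed` (data.frame).
#' @export
applyFlagFilter <- function(cs) {
  stopifnot(is(cs, "CallSet"))
  .splitByKeep(cs, variants(cs)$filter == "PASS")
}

#' Hard-filter germline-style calls on quality-by-depth, mapping quality
#' and strand bias
#'
#' Keeps records with `QD >= qdMin`, `MQ >= mqMin` and `FS <= fsMax`
#' (inclusive comparisons). A missing annotation is treated as passing,
#' so calls from files without these INFO keys are never discarded for
#' lack of metadata.
#'
#' @param cs a germline-class [CallSet-class].
#' @param qdMin,mqMin,fsMax non-negative thresholds; the defaults follow
#'   common practice for germline-caller hard filtering.
#' @return list with `callset` and `removed`.
#' @export
applyHardFilters <- function(cs, qdMin = 2.0, mqMin = 40.0, fsMax = 60.0) {
  stopifnot(is(cs, "CallSet"))
  if (callerClass(cs) != "germline")
    stop("hard filters apply to germline-class call sets")
  if (qdMin < 0 || mqMin < 0 || fsMax < 0)
    stop("hard-filter thresholds must be non-negative")
  v <- variants(cs)
  pass <- function(x, ok) ifelse(is.na(x), TRUE, ok)
  keep <- pass(v$qd, v$qd >= qdMin) & pass(v$mq, v$mq >= mqMin) &
    pass(v$fs, v$fs <= fsMax)
  .splitByKeep(cs, keep)
}

#' Build a panel of normals from tumor-free call sets
#'
#' Merges the call sets of samples without myeloid malignancies into a
#' multiset of normalized variant keys with per-key member counts. Keys
#' present in at least `minSamples` normals are treated as recurrent
#' assay artifacts and become subtractable. Requiring two members (the
#' default) protects private germline variants of a single normal donor
#' from entering the panel.
#'
#' @param normals non-empty list of [CallSet-class] objects.
#' @param minSamples membership threshold for subtraction, >= 1.
#' @return a [PanelOfNormals-class].
#' @export
buildPanelOfNormals <- function(normals, minSamples = 2) {
  if (length(normals) == 0) stop("no normal samples supplied")
  stopifnot(all(vapply(normals, is, TRUE, "CallSet")), minSamples >= 1)
  keys <- unlist(lapply(normals, variantKeys))
  entries <- if (length(keys) > 0) {
    tb <- table(keys)
    stats::setNames(as.integer(tb), names(tb))
  } else {
    stats::setNames(integer(0), character(0))
  }
  new("PanelOfNormals", entries = entries,
      nSamples = as.integer(length(normals)),
      minSamples = as.integer(minSamples))
}

#' Subtract panel-of-normals artifacts from a call set
#'
#' Removes every call whose normalized key is present in at least
#' `minSamples` members of the panel.
#'
#' @param cs a [CallSet-class].
#' @param pon a [PanelOfNormals-class].
#' @return list with `callset` and `removed`.
#' @export
subtractPanel <- function(cs, pon) {
  stopifnot(is(cs, "CallSet"), is(pon, "PanelOfNormals"))
  subtractable <- names(pon@entries)[pon@entries >= pon@minSamples]
  .splitByKeep(cs, !(variantKeys(cs) %in% subtractable))
}

#' Remove calls below the VAF noise boundary
#'
#' Keeps records with `vaf >= threshold`; calls strictly below the
#' boundary are removed as smear degradation noise. The default 2.5%
#' boundary is the package-wide noise threshold (see
#' [estimateNoiseBoundary()] for selecting it from data); real low-burden
#' mutations just above it, e.g. a 3.04% frameshift, survive.
#'
#' @param cs a [CallSet-class].
#' @param threshold VAF fraction in \[0, 1\].
#' @return list with `callset` and `removed`.
#' @export
filterVaf <- function(cs, threshold = 0.025) {
  stopifnot(is(cs, "CallSet"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("VAF threshold must be a single value in [0, 1]")
  .splitByKeep(cs, variants(cs)$vaf >= threshold)
}

#' Exclude common population variants
#'
#' Removes calls whose annotated population allele frequency is strictly
#' greater than `maxAf` (default 1%): such variants are prevalent
#' inherited polymorphisms, not candidate somatic mutations. A missing
#' annotation keeps the call; a frequency of exactly `maxAf` is kept.
#'
#' @param cs a [CallSet-class].
#' @param maxAf population-frequency ceiling as a fraction.
#' @return list with `callset` and `removed`.
#' @export
filterPopulationAf <- function(cs, maxAf = 0.01) {
  stopifnot(is(cs, "CallSet"))
  v <- variants(cs)
  keep <- is.na(v$population_af) | v$population_af <= maxAf
  .splitByKeep(cs, keep)
}

#' Classify variants as known SNPs, exonic/splice-site, or intronic
#'
#' The known-SNP flag dominates; otherwise a variant annotated in an exon
#' or a splice site, or lying within 2 bases of an exon boundary, is
#' `"exon+splice"`; everything else is `"intron"`. A call with no region
#' annotation at all is classified `"intron"` with a warning.
#'
#' @param x a [CallSet-class] or a variant data.frame.
#' @return character vector with values `"SNP"`, `"exon+splice"`,
#'   `"intron"`.
#' @export
classifyRegion <- function(x) {
  v <- if (is(x, "CallSet")) variants(x) else .completeVariantTable(x)
  if (nrow(v) == 0) return(character(0))
  unannotated <- !v$known_snp & (is.na(v$region) | v$region == "unknown") &
    is.na(v$exon_distance)
  if (any(unannotated))
    warning(sum(unannotated),
            " variant(s) without region annotation classified as intron")
  near_exon <- !is.na(v$exon_distance) & v$exon_distance <= 2
  ifelse(v$known_snp, "SNP",
         ifelse(v$region %in% c("exon", "splice") | near_exon,
                "exon+splice", "intron"))
}

#' Cascade configuration
#'
#' Collects the tunable thresholds of [runCascade()]. All values are
#' fractions or caller-annotation units; see the individual filters for
#' semantics and defaults.
#'
#' @param qdMin,mqMin,fsMax hard-filter thresholds for germline-class
#'   call sets.
#' @param vafThreshold VAF noise boundary (fraction).
#' @param maxPopAf population-frequency ceiling (fraction).
#' @return a named list of class `cascadeConfig`.
#' @export
cascadeConfig <- function(qdMin = 2.0, mqMin = 40.0, fsMax = 60.0,
                          vafThreshold = 0.025, maxPopAf = 0.01) {
  structure(list(qdMin = qdMin, mqMin = mqMin, fsMax = fsMax,
                 vafThreshold = vafThreshold, maxPopAf = maxPopAf),
            class = "cascadeConfig")
}

#' Run the full noise-reduction cascade
#'
#' Applies, in fixed order: the caller-flag filter (somatic class) or the
#' hard filters (germline class), panel-of-normals subtraction, the VAF
#' noise threshold, and the population-frequency exclusion. Counts are
#' conserved at every stage and each input call is dispositioned exactly
#' once: retained, or removed with the name of the stage that removed it.
#'
#' @param cs a [CallSet-class].
#' @param pon a [PanelOfNormals-class], or `NULL` to skip subtraction
#'   (the stage is still reported, removing nothing).
#' @param config a [cascadeConfig()].
#' @return list with `callset` (retained calls), `report`
#'   ([FilterReport-class]), and `disposition` (data.frame `key`,
#'   `stage`, where stage is `"retained"` or the removing stage's name).
#' @export
runCascade <- function(cs, pon = NULL, config = cascadeConfig()) {
  stopifnot(is(cs, "CallSet"))
  stages <- list()
  dispo <- stats::setNames(rep("retained", length(cs)), variantKeys(cs))
  current <- cs

  step <- function(name, res) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, n_in = length(current), removed = nrow(res$removed),
      retained = length(res$callset), stringsAsFactors = FALSE)
    if (nrow(res$removed) > 0) dispo[variantKey(res$removed)] <<- name
    current <<- res$callset
  }

  if (callerClass(cs) == "somatic") {
    step("flag_filter", applyFlagFilter(current))
  } else {
    step("hard_filters", applyHardFilters(current, config$qdMin,
                                          config$mqMin, config$fsMax))
  }
  step("pon_subtraction",
       if (is.null(pon)) list(callset = current,
                              removed = variants(current)[0, , drop = FALSE])
       else subtractPanel(current, pon))
  step("vaf_threshold", filterVaf(current, config$vafThreshold))
  step("population_af", filterPopulationAf(current, config$maxPopAf))

  report <- new("FilterReport", stages = do.call(rbind, stages))
  list(callset = current, report = report,
       disposition = data.frame(key = names(dispo), stage = unname(dispo),
                                stringsAsFactors = FALSE))
}
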