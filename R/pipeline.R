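#' Run configuration for the DNA and RNA workflows
#'
#' Bundles inputs and parameters for [runDnaPipeline()] and
#' [runRnaPipeline()]. Inputs may be in-memory objects produced by the
#' synthetic generator (`pairs = "simulate"`) or file paths to the VCF
#' and TSV dialects the package reads.
#'
#' @param pairs `"simulate"`, or a list of `list(smear=, bmc=)` entries
#'   whose members are [CallSet-class] objects or VCF paths.
#' @param normals `"simulate"`, or a list of CallSets / VCF paths.
#' @param synthetic a [syntheticConfig()] used when simulating.
#' @param cascade a [cascadeConfig()].
#' @param thresholdMode `"fixed"` (use `cascade$vafThreshold`) or
#'   `"auto"` (select the VAF threshold with
#'   [estimateNoiseBoundary()] on the panel-subtracted paired calls;
#'   requires paired smear/BMC inputs).
#' @param minSamples panel-of-normals membership threshold.
#' @param rpmMin fusion consensus expression threshold.
#' @param fusion `"simulate"`, or a list with `callerA`, `callerB`
#'   (paths or standardized evidence data.frames) and `manifest` (path
#'   or data.frame).
#' @param outputDir directory for TSV/JSON report files, or `NULL` to
#'   keep the report in memory only.
#' @param seed integer seed recorded in the report; simulation inputs
#'   derive from `synthetic$seed`.
#' @return a named list of class `runConfig`.
#' @export
runConfig <- function(pairs = "simulate", normals = "simulate",
                      synthetic = syntheticConfig(),
                      cascade = cascadeConfig(),
                      thresholdMode = c("fixed", "auto"), minSamples = 2,
                      rpmMin = 1000, fusion = "simulate", outputDir = NULL,
                      seed = synthetic$seed) {
  thresholdMode <- match.arg(thresholdMode)
  if (thresholdMode == "auto" && !identical(pairs, "simulate") &&
      (!is.list(pairs) || length(pairs) == 0))
    stop("threshold mode 'auto' requires paired smear/BMC inputs")
  structure(list(pairs = pairs, normals = normals, synthetic = synthetic,
                 cascade = cascade, thresholdMode = thresholdMode,
                 minSamples = minSamples, rpmMin = rpmMin, fusion = fusion,
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "runConfig")
}

.asCallSet <- function(x, sampleId, tissue, callerClass) {
  if (is(x, "CallSet")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("input file not found: ", x)
    return(readVariantVcf(x, sampleId, tissue, callerClass))
  }
  stop("pair inputs must be CallSet objects or VCF paths")
}

.resolvePairs <- function(cfg) {
  if (identical(cfg$pairs, "simulate")) {
    lapply(seq_len(cfg$synthetic$nPairs), function(i)
      simulatePairedCallsets(cfg$synthetic, i))
  } else {
    cc <- cfg$synthetic$callerClass
    ## verify all files exist before any computation starts
    for (p in cfg$pairs) for (m in c("smear", "bmc"))
      if (is.character(p[[m]]) && !file.exists(p[[m]]))
        stop("input file not found: ", p[[m]])
    lapply(seq_along(cfg$pairs), function(i) {
      p <- cfg$pairs[[i]]
      list(smear = .asCallSet(p$smear, sprintf("PAIR%02d", i), "smear", cc),
           bmc = .asCallSet(p$bmc, sprintf("PAIR%02d", i), "bmc", cc),
           truth = NULL)
    })
  }
}

.resolveNormals <- function(cfg) {
  if (identical(cfg$normals, "simulate"))
    return(simulateNormalPanel(cfg$synthetic))
  cc <- cfg$synthetic$callerClass
  lapply(seq_along(cfg$normals), function(i)
    .asCallSet(cfg$normals[[i]], sprintf("NORM%02d", i), "bmc", cc))
}

#' Run the paired smear/BMC DNA noise-reduction workflow
#'
#' End-to-end orchestration: resolve the paired call sets and the normal
#' panel, build the panel of normals, optionally select the VAF noise
#' boundary from the data, run the filter cascade on every member, and
#' summarise concordance before and after filtering, the per-stage
#' filter accounting, the region-class composition of the retained
#' smear calls, and (on synthetic inputs) recall/removal against the
#' truth labels.
#'
#' @param cfg a [runConfig()].
#' @return report list with elements `vaf_threshold`, `boundary`
#'   (a [BoundaryEstimate-class] or `NULL`), `pon`, `comparisons`,
#'   `fractions_before`, `fractions_after`, `filter_reports`,
#'   `dispositions`, `region_classes`, `mutation_summary`, `truth_metrics`
#'   (`NULL` without truth labels), and `seed`. With `outputDir` set,
#'   TSV/JSON files for each section are also written.
#' @export
runDnaPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  pairs <- .resolvePairs(cfg)
  normals <- .resolveNormals(cfg)
  pon <- buildPanelOfNormals(normals, minSamples = cfg$minSamples)

  boundary <- NULL
  cascade <- cfg$cascade
  if (cfg$thresholdMode == "auto") {
    su <- numeric(0); sh <- numeric(0)
    for (p in pairs) {
      s2 <- subtractPanel(p$smear, pon)$callset
      b2 <- subtractPanel(p$bmc, pon)$callset
      cmp <- classifyPaired(s2, b2)
      su <- c(su, smearUnique(cmp)$vaf)
      sh <- c(sh, sharedVariants(cmp)$bmc_vaf)
    }
    boundary <- estimateNoiseBoundary(su, sh)
    if (!is.na(noiseBoundary(boundary)))
      cascade$vafThreshold <- noiseBoundary(boundary)
  }

  comparisons_before <- lapply(pairs, function(p)
    classifyPaired(p$smear, p$bmc))
  results <- lapply(pairs, function(p) {
    sm <- runCascade(p$smear, pon, cascade)
    bm <- runCascade(p$bmc, pon, cascade)
    list(smear = sm, bmc = bm,
         cmp_after = classifyPaired(sm$callset, bm$callset))
  })

  frac_before <- concordanceFractions(comparisons_before)
  after_cmps <- lapply(results, `[[`, "cmp_after")
  total_after <- sum(vapply(after_cmps, function(x)
    sum(.partitionCounts(x)), 0))
  frac_after <- if (total_after > 0) concordanceFractions(after_cmps)
                else c(shared = NA_real_, smear_unique = NA_real_,
                       bmc_unique = NA_real_)

  retained_smear <- do.call(rbind, lapply(results, function(r)
    variants(r$smear$callset)))
  region_classes <- if (nrow(retained_smear) > 0)
    table(factor(classifyRegion(retained_smear),
                 levels = c("SNP", "exon+splice", "intron")))
  else table(factor(character(), levels = c("SNP", "exon+splice", "intron")))

  ## mutation summary: retained exonic/splice smear calls with gene labels
  mut <- do.call(rbind, lapply(seq_along(results), function(i) {
    v <- variants(results[[i]]$smear$callset)
    if (nrow(v) == 0) return(NULL)
    cls <- suppressWarnings(classifyRegion(v))
    v <- v[cls == "exon+splice", , drop = FALSE]
    if (nrow(v) == 0) return(NULL)
    data.frame(patient = sampleId(results[[i]]$smear$callset),
               gene = v$gene, hgvs_c = v$hgvs_c, hgvs_p = v$hgvs_p,
               vaf_percent = round(100 * v$vaf, 2),
               stringsAsFactors = FALSE)
  }))
  mutation_summary <- summarizePathogenic(
    if (is.null(mut)) data.frame(patient = character(), gene = character(),
                                 vaf_percent = numeric()) else mut)

  truth_metrics <- NULL
  if (!is.null(pairs[[1]]$truth)) {
    per_pair <- lapply(seq_along(pairs), function(i) {
      tr <- pairs[[i]]$truth
      keep_keys <- variantKeys(results[[i]]$smear$callset)
      smear_keys <- variantKeys(pairs[[i]]$smear)
      som <- tr$key[tr$class == "somatic"]
      art <- tr$key[tr$class %in% c("smear_artifact", "assay_artifact") &
                      tr$key %in% smear_keys]
      c(som_total = length(som), som_kept = sum(som %in% keep_keys),
        art_total = length(art), art_removed = sum(!(art %in% keep_keys)))
    })
    agg <- Reduce(`+`, per_pair)
    truth_metrics <- list(
      somatic_recall = unname(agg["som_kept"] / agg["som_total"]),
      artifact_removal = unname(agg["art_removed"] / agg["art_total"]))
  }

  report <- list(vaf_threshold = cascade$vafThreshold, boundary = boundary,
                 pon = pon, comparisons = comparisons_before,
                 comparisons_after = after_cmps,
                 fractions_before = frac_before,
                 fractions_after = frac_after,
                 filter_reports = lapply(results, function(r)
                   list(smear = r$smear$report, bmc = r$bmc$report)),
                 dispositions = lapply(results, function(r)
                   list(smear = r$smear$disposition,
                        bmc = r$bmc$disposition)),
                 region_classes = region_classes,
                 mutation_summary = mutation_summary,
                 truth_metrics = truth_metrics, seed = cfg$seed)
  if (!is.null(cfg$outputDir)) .writeDnaReport(report, cfg$outputDir)
  report
}

.writeDnaReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file)
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  fr <- rbind(before = report$fractions_before,
              after = report$fractions_after)
  wt(data.frame(stage = rownames(fr), fr), "concordance_fractions.tsv")
  stages <- do.call(rbind, lapply(seq_along(report$filter_reports),
                                  function(i) {
    s <- filterStages(report$filter_reports[[i]]$smear)
    s$pair <- i
    s
  }))
  wt(stages, "filter_report.tsv")
  wt(do.call(rbind, lapply(report$comparisons, vafDepthTable)),
     "vaf_depth.tsv")
  wt(data.frame(class = names(report$region_classes),
                count = as.integer(report$region_classes)),
     "region_classes.tsv")
  wt(report$mutation_summary$table, "mutation_summary.tsv")
  summary <- list(seed = report$seed, vaf_threshold = report$vaf_threshold,
                  fractions_before = as.list(report$fractions_before),
                  fractions_after = as.list(report$fractions_after),
                  n_patients_with_mutation =
                    report$mutation_summary$nPatientsWithMutation,
                  truth_metrics = report$truth_metrics)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the targeted RNA fusion workflow
#'
#' Merges the two fusion detectors' evidence into consensus calls and
#' checks every positive call against the sample's ISCN karyotype,
#' producing one row per sample in the layout of a clinical fusion
#' report (karyotype, mapped reads, detected fusion, RPM, concordance).
#'
#' @param cfg a [runConfig()].
#' @return list with `table` (one row per manifest sample: `sample_id`,
#'   `karyotype`, `mapped_reads`, `fusion`, `rpm`,
#'   `karyotype_concordant`), `calls` (all consensus rows incl.
#'   negatives), and `truth` (simulation only).
#' @export
runRnaPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  if (identical(cfg$fusion, "simulate")) {
    sim <- simulateFusionEvidence(cfg$synthetic)
    evA <- sim$callerA; evB <- sim$callerB; manifest <- sim$manifest
    truth <- sim$truth
  } else {
    evA <- if (is.character(cfg$fusion$callerA))
      readFusionCallerA(cfg$fusion$callerA) else cfg$fusion$callerA
    evB <- if (is.character(cfg$fusion$callerB))
      readFusionCallerB(cfg$fusion$callerB) else cfg$fusion$callerB
    manifest <- if (is.character(cfg$fusion$manifest))
      readSampleManifest(cfg$fusion$manifest) else cfg$fusion$manifest
    truth <- NULL
  }
  evidence <- rbind(evA, evB)
  extra <- setdiff(unique(evidence$sample_id), manifest$sample_id)
  if (length(extra) > 0)
    stop("sample(s) present in caller output but absent from manifest: ",
         paste(extra, collapse = ", "))
  calls <- if (is.null(evidence) || nrow(evidence) == 0)
    consensusCall(data.frame(sample_id = character(),
                             caller_id = character(), gene5 = character(),
                             gene3 = character(),
                             supporting_reads = integer()),
                  manifest, rpmMin = cfg$rpmMin)
  else consensusCall(evidence, manifest, rpmMin = cfg$rpmMin)

  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    sid <- manifest$sample_id[i]
    pos <- calls[calls$sample_id == sid & calls$positive, , drop = FALSE]
    if (nrow(pos) == 0) {
      data.frame(sample_id = sid, karyotype = manifest$karyotype[i],
                 mapped_reads = manifest$mapped_reads[i], fusion = "-",
                 rpm = NA_real_, karyotype_concordant = NA,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = sid, karyotype = manifest$karyotype[i],
                 mapped_reads = manifest$mapped_reads[i],
                 fusion = paste0(pos$gene5, "-", pos$gene3),
                 rpm = round(pos$rpm),
                 karyotype_concordant = vapply(seq_len(nrow(pos)),
                   function(j) karyotypeConcordance(pos$gene5[j],
                                                    pos$gene3[j],
                                                    manifest$karyotype[i]),
                   NA),
                 stringsAsFactors = FALSE)
    }
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  out <- list(table = table, calls = calls, truth = truth)
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(table, file.path(cfg$outputDir, "fusion_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
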