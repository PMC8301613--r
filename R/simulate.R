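## Seeded generators for paired smear/BMC call sets, normal panels,
## fusion evidence and amplicon coverage, with truth labels. The
## generators emulate the structure of smear-degradation noise: germline
## SNP peaks near 50%/100% VAF, shared somatic variants at intermediate
## VAF, a pile of smear-only low-VAF artifacts below a noise boundary,
## sporadic low-depth BMC errors, and panel-shared assay artifacts that
## recur in tumor-free normals.

## disjoint position ranges per truth class keep generated keys unique
.CLASS_OFFSET <- c(germline_snp = 1e6, somatic = 2e6, smear_artifact = 3e6,
                   bmc_error = 4e6, assay_artifact = 5e6,
                   population_snp = 6e6)
.RANGE_WIDTH <- 9e5

.mixSeed <- function(seed, tag) {
  ## deterministic 32-bit sub-stream seed from (seed, tag)
  as.integer((as.numeric(seed) * 48271 + as.numeric(tag) * 16807 + 11) %%
               2147483629)
}

.BASES <- c("A", "C", "G", "T")

.drawSites <- function(n, class, contigs) {
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), gene = character(),
                      stringsAsFactors = FALSE))
  pos <- sample.int(.RANGE_WIDTH, n) + .CLASS_OFFSET[[class]]
  gene <- sample(contigs, n, replace = TRUE)
  ref <- sample(.BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), "")
  data.frame(chrom = gene, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, stringsAsFactors = FALSE)
}

.clip01 <- function(x, lo = 1e-4, hi = 1) pmin(pmax(x, lo), hi)

#' Configuration of the synthetic smear/BMC data generator
#'
#' Defaults describe a realistic targeted myeloid panel study: five
#' smear/BMC pairs; per pair ~200 germline SNPs peaking at 50% and 100%
#' VAF with population frequencies above 1%; 60 shared somatic variants
#' with VAF uniform on 5-50% jittered ±2% between the tissues; a
#' Poisson(400) load of smear-only artifacts with VAF uniform below the
#' 2.5% noise boundary; 20 low-depth BMC-only errors; 10 assay artifacts
#' shared by both members and recurring in the 13-sample normal panel.
#' Real variants draw negative-binomial depths around 500x, artifacts
#' around 60x, and 30% of artifact records are pre-flagged non-PASS to
#' emulate the upstream somatic caller's own filtering stage.
#'
#' @param seed integer master seed; all generator functions derive their
#'   sub-streams from it, so identical configurations reproduce
#'   byte-identical outputs.
#' @param nPairs number of smear/BMC pairs.
#' @param nGermlineHet,nGermlineHom germline SNP counts per pair
#'   (heterozygous ~50% VAF, homozygous ~100%).
#' @param nSomatic shared somatic variants per pair.
#' @param somaticVafRange VAF range of somatic variants (fractions).
#' @param smearArtifactLambda Poisson mean of smear-only artifacts.
#' @param artifactVafDist `"uniform"` or `"beta"` shape of artifact VAFs
#'   below the boundary.
#' @param artifactVafMin lower VAF bound of artifacts.
#' @param noiseBoundary upper VAF bound of smear artifacts, in (0, 0.10].
#' @param artifactBeta shape parameters used when
#'   `artifactVafDist = "beta"`.
#' @param nBmcErrors BMC-only low-depth error count per pair.
#' @param nAssayArtifacts panel-shared artifact count (identical keys in
#'   every sample and in the normals).
#' @param assayVafRange VAF range of assay artifacts.
#' @param depthMeanReal,depthMeanArtifact negative-binomial depth means.
#' @param depthSize negative-binomial size (dispersion) parameter.
#' @param fractionNonPass fraction of artifact/error records pre-flagged
#'   with a non-PASS caller filter label.
#' @param nNormals normal panel size (>= 2).
#' @param callerClass caller class of the generated call sets.
#' @param nFusionSamples,nTrueFusions,fusionRpmRange,nDecoysPerCaller,
#'   mappedReadRange fusion-evidence block: samples, how many carry a
#'   true fusion, the RPM range the true supporting reads are drawn to
#'   achieve, decoy fusions private to one caller, and the mapped-read
#'   totals.
#' @param nAmplicons,ampliconMeanlog,ampliconSdlog amplicon coverage
#'   block (log-normal).
#' @return validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L, nPairs = 5L,
                            nGermlineHet = 150L, nGermlineHom = 50L,
                            nSomatic = 60L, somaticVafRange = c(0.05, 0.5),
                            smearArtifactLambda = 400,
                            artifactVafDist = c("uniform", "beta"),
                            artifactVafMin = 0.001, noiseBoundary = 0.025,
                            artifactBeta = c(1, 3), nBmcErrors = 20L,
                            nAssayArtifacts = 10L,
                            assayVafRange = c(0.005, 0.10),
                            depthMeanReal = 500, depthMeanArtifact = 60,
                            depthSize = 8, fractionNonPass = 0.3,
                            nNormals = 13L,
                            callerClass = c("somatic", "germline"),
                            nFusionSamples = 8L, nTrueFusions = 3L,
                            fusionRpmRange = c(1500, 20000),
                            nDecoysPerCaller = 3L,
                            mappedReadRange = c(20000, 90000),
                            nAmplicons = 568L,
                            ampliconMeanlog = log(1000),
                            ampliconSdlog = 0.5) {
  cfg <- list(seed = as.integer(seed), nPairs = as.integer(nPairs),
              nGermlineHet = as.integer(nGermlineHet),
              nGermlineHom = as.integer(nGermlineHom),
              nSomatic = as.integer(nSomatic),
              somaticVafRange = somaticVafRange,
              smearArtifactLambda = smearArtifactLambda,
              artifactVafDist = match.arg(artifactVafDist),
              artifactVafMin = artifactVafMin,
              noiseBoundary = noiseBoundary, artifactBeta = artifactBeta,
              nBmcErrors = as.integer(nBmcErrors),
              nAssayArtifacts = as.integer(nAssayArtifacts),
              assayVafRange = assayVafRange,
              depthMeanReal = depthMeanReal,
              depthMeanArtifact = depthMeanArtifact, depthSize = depthSize,
              fractionNonPass = fractionNonPass,
              nNormals = as.integer(nNormals),
              callerClass = match.arg(callerClass),
              nFusionSamples = as.integer(nFusionSamples),
              nTrueFusions = as.integer(nTrueFusions),
              fusionRpmRange = fusionRpmRange,
              nDecoysPerCaller = as.integer(nDecoysPerCaller),
              mappedReadRange = mappedReadRange,
              nAmplicons = as.integer(nAmplicons),
              ampliconMeanlog = ampliconMeanlog,
              ampliconSdlog = ampliconSdlog)
  counts <- c(cfg$nPairs, cfg$nGermlineHet, cfg$nGermlineHom, cfg$nSomatic,
              cfg$smearArtifactLambda, cfg$nBmcErrors, cfg$nAssayArtifacts,
              cfg$nFusionSamples, cfg$nTrueFusions, cfg$nDecoysPerCaller,
              cfg$nAmplicons)
  if (any(is.na(counts)) || any(counts < 0))
    stop("all counts must be non-negative")
  ranges <- c(cfg$somaticVafRange, cfg$assayVafRange, cfg$artifactVafMin)
  if (any(ranges < 0) || any(ranges > 1))
    stop("VAF ranges must lie within [0, 1]")
  if (cfg$noiseBoundary <= 0 || cfg$noiseBoundary > 0.10)
    stop("noiseBoundary must lie in (0, 0.10]")
  if (cfg$fractionNonPass < 0 || cfg$fractionNonPass > 1)
    stop("fractionNonPass must lie in [0, 1]")
  structure(cfg, class = "syntheticConfig")
}

.contigGenes <- function() {
  c("FLT3", "NPM1", "DNMT3A", "TET2", "ASXL1", "TP53", "NRAS", "KRAS",
    "RUNX1", "CEBPA", "IDH1", "IDH2", "SRSF2", "U2AF1", "WT1", "GATA2",
    "EZH2", "STAG2", "DDX41", "ATM")
}

.depths <- function(n, mu, size) pmax(1, stats::rnbinom(n, mu = mu, size = size))

.artifactVafs <- function(n, cfg) {
  if (cfg$artifactVafDist == "uniform") {
    stats::runif(n, cfg$artifactVafMin, cfg$noiseBoundary)
  } else {
    cfg$artifactVafMin + stats::rbeta(n, cfg$artifactBeta[1],
                                      cfg$artifactBeta[2]) *
      (cfg$noiseBoundary - cfg$artifactVafMin)
  }
}

.nonPassFlags <- function(n, fraction) {
  flags <- rep("PASS", n)
  n_bad <- stats::rbinom(1, n, fraction)
  if (n_bad > 0) {
    bad <- sample.int(n, n_bad)
    flags[bad] <- sample(c("weak_evidence", "strand_bias", "base_qual",
                           "low_depth"), n_bad, replace = TRUE)
  }
  flags
}

## assay artifacts are a property of the assay, not of one pair: derive
## them once from the master seed so pairs and normals agree on the keys
.assayArtifactSites <- function(cfg) {
  if (cfg$nAssayArtifacts == 0) {
    sites <- .drawSites(0, "assay_artifact", .contigGenes())
    sites$base_vaf <- numeric(0)
    return(sites)
  }
  set.seed(.mixSeed(cfg$seed, 999983))
  sites <- .drawSites(cfg$nAssayArtifacts, "assay_artifact", .contigGenes())
  sites$base_vaf <- stats::runif(cfg$nAssayArtifacts, cfg$assayVafRange[1],
                                 cfg$assayVafRange[2])
  sites
}

.variantRow <- function(sites, vaf, depth, filter, population_af = NA_real_,
                        region = "unknown", known_snp = FALSE, qd = NA_real_,
                        mq = NA_real_, fs = NA_real_) {
  n <- nrow(sites)
  data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, vaf = rep_len(vaf, n),
             depth = rep_len(depth, n), filter = rep_len(filter, n),
             gene = sites$gene, hgvs_c = rep_len("", n),
             hgvs_p = rep_len("", n),
             population_af = rep_len(population_af, n),
             region = rep_len(region, n),
             known_snp = rep_len(known_snp, n),
             exon_distance = rep_len(NA_real_, n), qd = rep_len(qd, n),
             mq = rep_len(mq, n), fs = rep_len(fs, n),
             stringsAsFactors = FALSE)
}

#' Simulate one paired smear/BMC call set with truth labels
#'
#' Generates the smear and BMC [CallSet-class] of one synthetic patient
#' pair plus a truth table labelling every emitted key as
#' `germline_snp`, `somatic`, `smear_artifact`, `bmc_error` or
#' `assay_artifact`. Germline SNPs and somatic variants appear in both
#' members (somatic VAF drawn once, then jittered ±2% per tissue);
#' smear artifacts appear only in the smear with Poisson-distributed
#' count and VAF below the configured noise boundary; assay artifacts
#' appear in both members with keys shared across all pairs and the
#' normal panel. Deterministic given `(seed, pairIndex)`.
#'
#' @param config a [syntheticConfig()].
#' @param pairIndex which pair to generate (1-based).
#' @return list with `smear`, `bmc` (CallSets) and `truth` (data.frame
#'   `key`, `class`).
#' @export
simulatePairedCallsets <- function(config, pairIndex = 1L) {
  stopifnot(inherits(config, "syntheticConfig"), pairIndex >= 1)
  assay <- .assayArtifactSites(config)
  set.seed(.mixSeed(config$seed, pairIndex))
  contigs <- .contigGenes()
  cc <- config$callerClass
  sid <- sprintf("PAIR%02d", as.integer(pairIndex))

  real_qd <- function(n) stats::runif(n, 10, 35)
  real_mq <- function(n) stats::runif(n, 55, 60)
  real_fs <- function(n) stats::runif(n, 0, 15)

  ## germline SNPs: both members, VAF peaks at 50% / 100%
  n_het <- config$nGermlineHet
  n_hom <- config$nGermlineHom
  germ <- .drawSites(n_het + n_hom, "germline_snp", contigs)
  germ_vaf_s <- .clip01(c(stats::rnorm(n_het, 0.5, 0.03),
                          stats::rnorm(n_hom, 0.99, 0.01)))
  germ_vaf_b <- .clip01(germ_vaf_s + stats::rnorm(n_het + n_hom, 0, 0.01))
  germ_pop <- stats::runif(n_het + n_hom, 0.02, 0.5)
  germ_region <- sample(c("exon", "intron"), n_het + n_hom, replace = TRUE,
                        prob = c(0.3, 0.7))
  germ_s <- .variantRow(germ, germ_vaf_s,
                        .depths(n_het + n_hom, config$depthMeanReal,
                                config$depthSize),
                        "PASS", population_af = germ_pop,
                        region = germ_region, known_snp = TRUE,
                        qd = real_qd(n_het + n_hom),
                        mq = real_mq(n_het + n_hom),
                        fs = real_fs(n_het + n_hom))
  germ_b <- germ_s
  germ_b$vaf <- germ_vaf_b
  germ_b$depth <- .depths(n_het + n_hom, config$depthMeanReal,
                          config$depthSize)

  ## shared somatic variants
  n_som <- config$nSomatic
  som <- .drawSites(n_som, "somatic", contigs)
  som_base <- stats::runif(n_som, config$somaticVafRange[1],
                           config$somaticVafRange[2])
  som_region <- sample(c("exon", "splice", "intron"), n_som, replace = TRUE,
                       prob = c(0.6, 0.05, 0.35))
  som_s <- .variantRow(som,
                       .clip01(som_base + stats::runif(n_som, -0.02, 0.02)),
                       .depths(n_som, config$depthMeanReal, config$depthSize),
                       "PASS", region = som_region, qd = real_qd(n_som),
                       mq = real_mq(n_som), fs = real_fs(n_som))
  som_b <- som_s
  som_b$vaf <- .clip01(som_base + stats::runif(n_som, -0.02, 0.02))
  som_b$depth <- .depths(n_som, config$depthMeanReal, config$depthSize)

  ## smear-only artifacts below the noise boundary
  n_art <- stats::rpois(1, config$smearArtifactLambda)
  art <- .drawSites(n_art, "smear_artifact", contigs)
  art_s <- .variantRow(art, .clip01(.artifactVafs(n_art, config),
                                    lo = config$artifactVafMin / 2),
                       .depths(n_art, config$depthMeanArtifact,
                               config$depthSize),
                       .nonPassFlags(n_art, config$fractionNonPass),
                       region = "intron",
                       qd = stats::runif(n_art, 0.2, 6),
                       mq = stats::runif(n_art, 20, 60),
                       fs = stats::runif(n_art, 0, 90))

  ## BMC-only low-depth errors
  n_err <- config$nBmcErrors
  err <- .drawSites(n_err, "bmc_error", contigs)
  err_b <- .variantRow(err, stats::runif(n_err, 0.001, 0.05),
                       .depths(n_err, config$depthMeanArtifact,
                               config$depthSize),
                       .nonPassFlags(n_err, config$fractionNonPass),
                       region = "intron",
                       qd = stats::runif(n_err, 0.2, 6),
                       mq = stats::runif(n_err, 20, 60),
                       fs = stats::runif(n_err, 0, 90))

  ## panel-shared assay artifacts: same keys in both members
  n_asy <- nrow(assay)
  jitter_asy <- function() .clip01(assay$base_vaf *
                                     stats::runif(n_asy, 0.7, 1.3))
  asy_s <- .variantRow(assay[, 1:5], jitter_asy(),
                       .depths(n_asy, config$depthMeanReal, config$depthSize),
                       "PASS", region = "intron",
                       qd = real_qd(n_asy), mq = real_mq(n_asy),
                       fs = real_fs(n_asy))
  asy_b <- asy_s
  asy_b$vaf <- jitter_asy()
  asy_b$depth <- .depths(n_asy, config$depthMeanReal, config$depthSize)

  smear <- CallSet(rbind(germ_s, som_s, asy_s, art_s), sid, "smear", cc)
  bmc <- CallSet(rbind(germ_b, som_b, asy_b, err_b), sid, "bmc", cc)
  truth <- data.frame(
    key = c(variantKey(germ_s), variantKey(som_s), variantKey(asy_s),
            variantKey(art_s), variantKey(err_b)),
    class = c(rep("germline_snp", n_het + n_hom), rep("somatic", n_som),
              rep("assay_artifact", n_asy), rep("smear_artifact", n_art),
              rep("bmc_error", n_err)),
    stringsAsFactors = FALSE)
  list(smear = smear, bmc = bmc, truth = truth)
}

#' Simulate the tumor-free normal panel
#'
#' Generates `nNormals` BMC call sets from patients without myeloid
#' malignancies: each carries a private draw from a shared pool of
#' population SNPs plus the assay artifacts (every artifact present in
#' at least two members, membership randomized per artifact), and never
#' any somatic or smear-artifact key.
#'
#' @param config a [syntheticConfig()].
#' @return list of `nNormals` [CallSet-class] objects.
#' @export
simulateNormalPanel <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (config$nNormals < 2) stop("at least 2 normal samples are required")
  assay <- .assayArtifactSites(config)
  set.seed(.mixSeed(config$seed, 424243))
  contigs <- .contigGenes()
  n_norm <- config$nNormals

  ## shared population-SNP pool; each normal samples its own genotypes
  pool <- .drawSites(300, "population_snp", contigs)
  ## per-artifact membership: each assay artifact recurs in >= 2 normals
  membership <- lapply(seq_len(nrow(assay)), function(i) {
    k <- sample(2:n_norm, 1)
    sample.int(n_norm, k)
  })

  lapply(seq_len(n_norm), function(j) {
    n_snp <- 100
    take <- pool[sample.int(nrow(pool), n_snp), , drop = FALSE]
    snp <- .variantRow(take,
                       .clip01(stats::rnorm(n_snp,
                                            sample(c(0.5, 1), n_snp,
                                                   replace = TRUE,
                                                   prob = c(0.7, 0.3)),
                                            0.02)),
                       .depths(n_snp, config$depthMeanReal, config$depthSize),
                       "PASS",
                       population_af = stats::runif(n_snp, 0.02, 0.5),
                       known_snp = TRUE)
    carry <- vapply(membership, function(m) j %in% m, TRUE)
    asy <- assay[carry, , drop = FALSE]
    rows <- snp
    if (nrow(asy) > 0) {
      asy_rows <- .variantRow(asy[, 1:5],
                              .clip01(asy$base_vaf *
                                        stats::runif(nrow(asy), 0.7, 1.3)),
                              .depths(nrow(asy), config$depthMeanReal,
                                      config$depthSize),
                              "PASS", region = "intron")
      rows <- rbind(rows, asy_rows)
    }
    CallSet(rows, sprintf("NORM%02d", j), "bmc", config$callerClass)
  })
}

.FUSION_PAIRS <- matrix(c(
  "RUNX1", "RUNX1T1",
  "CBFB", "MYH11",
  "KMT2A", "MLLT10",
  "ETV6", "CHIC2",
  "NUP214", "ABL1",
  "BCR", "ABL1",
  "PML", "RARA"), ncol = 2, byrow = TRUE)

#' Simulate two-caller fusion evidence with decoys
#'
#' Builds the evidence tables of the two fusion detectors, the sample
#' manifest (mapped reads and an ISCN karyotype consistent with each
#' true fusion's cytobands), and the truth table. True fusions appear
#' in both callers with supporting reads drawn to reach the configured
#' RPM range; decoys appear in exactly one caller with low read counts.
#'
#' @param config a [syntheticConfig()].
#' @return list with `callerA`, `callerB` (standardized evidence
#'   data.frames), `manifest`, and `truth` (`sample_id`, `gene5`,
#'   `gene3`).
#' @export
simulateFusionEvidence <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(.mixSeed(config$seed, 717171))
  n <- config$nFusionSamples
  ids <- sprintf("FS%02d", seq_len(n))
  mapped <- round(stats::runif(n, config$mappedReadRange[1],
                               config$mappedReadRange[2]))
  loci <- geneCytobands()

  n_true <- min(config$nTrueFusions, n)
  true_samples <- sort(sample.int(n, n_true))
  pair_idx <- sample.int(nrow(.FUSION_PAIRS), n_true, replace = TRUE)

  karyo <- rep("46,XY[20]", n)
  evA <- list(); evB <- list(); truth <- list()
  for (k in seq_len(n_true)) {
    s <- true_samples[k]
    g5 <- .FUSION_PAIRS[pair_idx[k], 1]
    g3 <- .FUSION_PAIRS[pair_idx[k], 2]
    rpm_target <- stats::runif(1, config$fusionRpmRange[1],
                               config$fusionRpmRange[2])
    readsA <- max(1, round(mapped[s] * rpm_target / 1e6))
    readsB <- max(1, round(readsA * stats::runif(1, 0.6, 1.0)))
    evA[[k]] <- data.frame(sample_id = ids[s], caller_id = "A", gene5 = g5,
                           gene3 = g3, supporting_reads = readsA,
                           stringsAsFactors = FALSE)
    ## caller B reports the partners in the opposite orientation
    evB[[k]] <- data.frame(sample_id = ids[s], caller_id = "B", gene5 = g3,
                           gene3 = g5, supporting_reads = readsB,
                           stringsAsFactors = FALSE)
    truth[[k]] <- data.frame(sample_id = ids[s], gene5 = g5, gene3 = g3,
                             stringsAsFactors = FALSE)
    l5 <- loci[match(g5, loci$gene), ]
    l3 <- loci[match(g3, loci$gene), ]
    karyo[s] <- if (l5$chrom == l3$chrom) {
      sprintf("46,XY,inv(%s)(%s%s)[20]", l5$chrom,
              min(l5$band, l3$band), max(l5$band, l3$band))
    } else {
      sprintf("46,XY,t(%s;%s)(%s;%s)[20]", l5$chrom, l3$chrom,
              l5$band, l3$band)
    }
  }

  mk_decoys <- function(caller) {
    n_d <- config$nDecoysPerCaller
    if (n_d == 0) return(NULL)
    s <- sample.int(n, n_d, replace = TRUE)
    g <- replicate(n_d, sample(loci$gene[loci$gene != "ABL"], 2))
    data.frame(sample_id = ids[s], caller_id = caller, gene5 = g[1, ],
               gene3 = g[2, ],
               supporting_reads = stats::rpois(n_d, 5) + 1,
               stringsAsFactors = FALSE)
  }
  callerA <- do.call(rbind, c(evA, list(mk_decoys("A"))))
  callerB <- do.call(rbind, c(evB, list(mk_decoys("B"))))
  manifest <- data.frame(sample_id = ids, mapped_reads = mapped,
                         karyotype = karyo, stringsAsFactors = FALSE)
  list(callerA = callerA, callerB = callerB, manifest = manifest,
       truth = do.call(rbind, truth))
}

#' Simulate per-amplicon coverage
#'
#' Log-normal mean coverages over `nAmplicons` synthetic amplicons laid
#' end to end on the panel's pseudo-contigs; `ampliconSdlog = 0` gives
#' perfectly uniform coverage.
#'
#' @param config a [syntheticConfig()].
#' @return data.frame in the [readAmpliconCoverage()] layout.
#' @export
simulateAmpliconCoverage <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(.mixSeed(config$seed, 515151))
  n <- config$nAmplicons
  if (n < 1) stop("at least one amplicon is required")
  contigs <- .contigGenes()
  chrom <- sample(contigs, n, replace = TRUE)
  start <- as.integer(seq_len(n) * 200L)
  data.frame(amplicon_id = sprintf("AMP%04d", seq_len(n)), chrom = chrom,
             start = start, end = start + 180L,
             mean_coverage = stats::rlnorm(n, config$ampliconMeanlog,
                                           config$ampliconSdlog),
             stringsAsFactors = FALSE)
}

#' Write truth labels as a sidecar TSV
#'
#' @param truth data.frame with columns `key`, `class`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTruthLabels <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
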