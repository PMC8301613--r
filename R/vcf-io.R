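## VCF ingestion and export.
##
## Reading goes through VariantAnnotation::readVcf; a light pre-scan of the
## text supplies line-numbered errors for malformed records, which the
## generic parser cannot attribute to a line. Writing emits the package's
## flat single-allele dialect (all evidence in INFO) directly.

.INFO_HEADER <- c(
  '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele fraction">',
  '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth at the site">',
  '##INFO=<ID=POP_AF,Number=A,Type=Float,Description="Population allele frequency">',
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
  '##INFO=<ID=HGVSC,Number=1,Type=String,Description="HGVS coding annotation">',
  '##INFO=<ID=HGVSP,Number=1,Type=String,Description="HGVS protein annotation">',
  '##INFO=<ID=REGION,Number=1,Type=String,Description="Genic region (exon/splice/intron/unknown)">',
  '##INFO=<ID=EXDIST,Number=1,Type=Integer,Description="Distance in bases to the nearest exon boundary">',
  '##INFO=<ID=SNP,Number=0,Type=Flag,Description="Known inherited germline variant">',
  '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
  '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
  '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias (phred)">')

.prescanVcf <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("malformed VCF record at line ", i, ": expected >= 8 fields, got ",
           length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF record at line ", i, ": POS '", f[2],
           "' is not an integer")
    if (!nzchar(f[4]) || !nzchar(f[5]) || f[4] == "." || f[5] == ".")
      stop("malformed VCF record at line ", i, ": missing REF or ALT")
  }
  invisible(length(body))
}

.infoField <- function(info, key, i, default = NA) {
  if (!key %in% names(info)) return(default)
  v <- info[[key]][[i]]
  if (length(v) == 0 || all(is.na(v))) default else v
}

#' Read a VCF file into a CallSet
#'
#' Parses a VCF v4.x file, decomposes multiallelic records into one call
#' per alternate allele, normalizes alleles with [normalizeVariant()], and
#' assembles a [CallSet-class]. The allele fraction and depth are taken
#' from the FORMAT `AD`/`DP` fields of the named sample when present
#' (closest to the read evidence), otherwise from the INFO `AF`/`DP`
#' fields. A missing FILTER (`"."`) maps to `PASS`. Optional INFO keys
#' `POP_AF`, `GENE`, `HGVSC`, `HGVSP`, `REGION`, `EXDIST`, `SNP`, `QD`,
#' `MQ`, `FS` populate the annotation columns.
#'
#' @param path VCF file.
#' @param sampleId sample identifier; also selects the FORMAT column when
#'   the file is multi-sample.
#' @param tissue `"smear"` or `"bmc"`.
#' @param callerClass `"germline"` or `"somatic"`.
#' @return a [CallSet-class] with one row per alternate allele.
#' @export
readVariantVcf <- function(path, sampleId, tissue, callerClass) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  .prescanVcf(path)
  vcf <- VariantAnnotation::readVcf(path)
  nrec <- length(vcf)
  if (nrec == 0)
    return(CallSet(.emptyVariantTable(), sampleId, tissue, callerClass))

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  filt <- VariantAnnotation::filt(vcf)
  info <- VariantAnnotation::info(vcf)

  smp <- colnames(vcf)
  sample_col <- if (length(smp) == 0) NA_integer_
                else if (sampleId %in% smp) match(sampleId, smp)
                else if (length(smp) == 1) 1L
                else stop("sample '", sampleId, "' not found in VCF columns: ",
                          paste(smp, collapse = ", "))
  geno <- if (!is.na(sample_col)) VariantAnnotation::geno(vcf) else NULL

  rows <- vector("list", nrec)
  for (i in seq_len(nrec)) {
    alt_i <- as.character(alts[[i]])
    n_alt <- length(alt_i)
    ad <- NULL
    dp_fmt <- NA_real_
    if (!is.null(geno) && "AD" %in% names(geno)) {
      ad_i <- geno$AD[[i, sample_col]]
      if (!is.null(ad_i) && length(ad_i) == n_alt + 1 && !anyNA(ad_i))
        ad <- as.numeric(ad_i)
    }
    if (!is.null(geno) && "DP" %in% names(geno)) {
      d <- geno$DP[i, sample_col]
      if (length(d) == 1 && !is.na(d)) dp_fmt <- as.numeric(d)
    }
    af_info <- .infoField(info, "AF", i, default = rep(NA_real_, n_alt))
    af_info <- rep_len(as.numeric(af_info), n_alt)
    dp_info <- as.numeric(.infoField(info, "DP", i, NA_real_))[1]

    depth <- if (!is.na(dp_fmt)) dp_fmt
             else if (!is.null(ad)) sum(ad)
             else dp_info
    vaf <- if (!is.null(ad) && !is.na(depth) && depth > 0) ad[-1] / depth
           else af_info
    if (anyNA(vaf))
      stop("VAF not derivable (no usable FORMAT AD/DP or INFO AF) for record ",
           chrom[i], ":", pos[i], " ", refs[i], ">",
           paste(alt_i, collapse = ","))
    if (is.na(depth)) depth <- 0

    flags <- filt[i]
    if (is.na(flags) || flags == ".") flags <- "PASS"
    pop <- .infoField(info, "POP_AF", i, default = rep(NA_real_, n_alt))
    pop <- rep_len(as.numeric(pop), n_alt)

    norm <- normalizeVariant(chrom[i], pos[i], refs[i], alt_i)
    rows[[i]] <- data.frame(
      chrom = norm$chrom, pos = norm$pos, ref = norm$ref, alt = norm$alt,
      vaf = pmin(pmax(vaf, 0), 1), depth = depth, filter = flags,
      gene = as.character(.infoField(info, "GENE", i, ""))[1],
      hgvs_c = as.character(.infoField(info, "HGVSC", i, ""))[1],
      hgvs_p = as.character(.infoField(info, "HGVSP", i, ""))[1],
      population_af = pop,
      region = as.character(.infoField(info, "REGION", i, "unknown"))[1],
      known_snp = isTRUE(.infoField(info, "SNP", i, FALSE)),
      exon_distance = as.numeric(.infoField(info, "EXDIST", i, NA_real_))[1],
      qd = as.numeric(.infoField(info, "QD", i, NA_real_))[1],
      mq = as.numeric(.infoField(info, "MQ", i, NA_real_))[1],
      fs = as.numeric(.infoField(info, "FS", i, NA_real_))[1],
      stringsAsFactors = FALSE)
  }
  CallSet(do.call(rbind, rows), sampleId, tissue, callerClass)
}

.fmtNum <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))

#' Write a CallSet as a VCF v4.2 file
#'
#' Emits one record per call with all evidence in INFO (`AF`, `DP`,
#' annotations), suitable for re-ingestion with [readVariantVcf()]. The
#' parse-write-parse round trip preserves the normalized key, the VAF to
#' at least four decimals, the depth, and the filter flags.
#'
#' @param cs a [CallSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(cs, path) {
  stopifnot(is(cs, "CallSet"))
  v <- variants(cs)
  contigs <- unique(v$chrom)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=smearseq;sample=%s;tissue=%s;caller=%s",
                      sampleId(cs), tissue(cs), callerClass(cs)),
              .INFO_HEADER,
              sprintf("##contig=<ID=%s>", contigs),
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", sep = "\t"))
  recs <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- c(sprintf("AF=%s", .fmtNum(v$vaf[i])),
              sprintf("DP=%d", as.integer(round(v$depth[i]))))
    if (!is.na(v$population_af[i]))
      info <- c(info, sprintf("POP_AF=%s", .fmtNum(v$population_af[i])))
    if (nzchar(v$gene[i])) info <- c(info, paste0("GENE=", v$gene[i]))
    if (nzchar(v$hgvs_c[i])) info <- c(info, paste0("HGVSC=", v$hgvs_c[i]))
    if (nzchar(v$hgvs_p[i])) info <- c(info, paste0("HGVSP=", v$hgvs_p[i]))
    if (v$region[i] != "unknown") info <- c(info, paste0("REGION=", v$region[i]))
    if (!is.na(v$exon_distance[i]))
      info <- c(info, sprintf("EXDIST=%d", as.integer(v$exon_distance[i])))
    if (isTRUE(v$known_snp[i])) info <- c(info, "SNP")
    if (!is.na(v$qd[i])) info <- c(info, sprintf("QD=%s", .fmtNum(v$qd[i])))
    if (!is.na(v$mq[i])) info <- c(info, sprintf("MQ=%s", .fmtNum(v$mq[i])))
    if (!is.na(v$fs[i])) info <- c(info, sprintf("FS=%s", .fmtNum(v$fs[i])))
    recs[i] <- paste(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".",
                     v$filter[i], paste(info, collapse = ";"), sep = "\t")
  }
  writeLines(c(header, recs), path)
  invisible(path)
}
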