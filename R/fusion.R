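#' Built-in gene-to-cytoband table for fusion driver loci
#'
#' Chromosome and chromosome-band locations of the fusion driver genes
#' covered by the targeted RNA panel, used to test whether a consensus
#' fusion call is concordant with the reported ISCN karyotype. `ABL` is
#' kept as an alias of `ABL1` because fusion reports abbreviate it.
#'
#' @return data.frame with columns `gene`, `chrom`, `band`.
#' @export
geneCytobands <- function() {
  tab <- c(
    "RUNX1",   "21", "q22",
    "RUNX1T1", "8",  "q22",
    "CBFB",    "16", "q22",
    "MYH11",   "16", "p13",
    "KMT2A",   "11", "q23",
    "MLLT10",  "10", "p12",
    "MLLT3",   "9",  "p21",
    "ETV6",    "12", "p13",
    "CHIC2",   "4",  "q12",
    "NUP214",  "9",  "q34",
    "ABL1",    "9",  "q34",
    "ABL",     "9",  "q34",
    "BCR",     "22", "q11",
    "PML",     "15", "q24",
    "RARA",    "17", "q21",
    "AFF1",    "4",  "q21",
    "DEK",     "6",  "p22",
    "NUP98",   "11", "p15",
    "FIP1L1",  "4",  "q12",
    "PDGFRA",  "4",  "q12",
    "PDGFRB",  "5",  "q32",
    "FGFR1",   "8",  "p11",
    "JAK2",    "9",  "p24",
    "MECOM",   "3",  "q26",
    "GATA2",   "3",  "q21",
    "TCF3",    "19", "p13",
    "KAT6A",   "8",  "p11",
    "CREBBP",  "16", "p13")
  m <- matrix(tab, ncol = 3, byrow = TRUE)
  data.frame(gene = m[, 1], chrom = m[, 2], band = m[, 3],
             stringsAsFactors = FALSE)
}

#' Fusion-supporting reads per million mapped reads
#'
#' The expression proxy used for consensus positivity:
#' `rpm = supportingReads / mappedReads * 1e6`.
#'
#' @param supportingReads reads spanning the fusion junction, >= 0.
#' @param mappedReads total mapped reads of the sample, > 0.
#' @return RPM value(s).
#' @export
computeRpm <- function(supportingReads, mappedReads) {
  if (any(mappedReads <= 0)) stop("mappedReads must be > 0")
  if (any(supportingReads < 0)) stop("supportingReads must be >= 0")
  supportingReads / mappedReads * 1e6
}

#' Read fusion evidence in the caller-A table dialect
#'
#' Caller A reports one row per fusion with columns `sample_id`,
#' `fusion_genes` (`"GENE5:GENE3"`), and `spanning_reads`.
#'
#' @param path TSV file.
#' @return standardized evidence data.frame with columns `sample_id`,
#'   `caller_id`, `gene5`, `gene3`, `supporting_reads`.
#' @export
readFusionCallerA <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "fusion_genes", "spanning_reads")
  if (length(setdiff(need, names(df))) > 0)
    stop("caller-A table needs columns: ", paste(need, collapse = ", "))
  parts <- strsplit(df$fusion_genes, ":", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("fusion_genes must be 'GENE5:GENE3'")
  data.frame(sample_id = df$sample_id, caller_id = "A",
             gene5 = vapply(parts, `[`, "", 1),
             gene3 = vapply(parts, `[`, "", 2),
             supporting_reads = as.integer(df$spanning_reads),
             stringsAsFactors = FALSE)
}

#' Read fusion evidence in the caller-B table dialect
#'
#' Caller B reports columns `sample_id`, `left_gene`, `right_gene`,
#' `junction_reads`.
#'
#' @param path TSV file.
#' @return standardized evidence data.frame (see [readFusionCallerA()]).
#' @export
readFusionCallerB <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "left_gene", "right_gene", "junction_reads")
  if (length(setdiff(need, names(df))) > 0)
    stop("caller-B table needs columns: ", paste(need, collapse = ", "))
  data.frame(sample_id = df$sample_id, caller_id = "B",
             gene5 = df$left_gene, gene3 = df$right_gene,
             supporting_reads = as.integer(df$junction_reads),
             stringsAsFactors = FALSE)
}

#' Read the sample manifest (mapped reads and karyotype)
#'
#' @param path TSV with columns `sample_id`, `mapped_reads`, `karyotype`.
#' @return data.frame.
#' @export
readSampleManifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "mapped_reads", "karyotype")
  if (length(setdiff(need, names(df))) > 0)
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  df$mapped_reads <- as.numeric(df$mapped_reads)
  df
}

.pairKey <- function(g5, g3) {
  vapply(seq_along(g5), function(i)
    paste(sort(c(g5[i], g3[i])), collapse = "|"), "")
}

#' Two-caller consensus fusion calling
#'
#' Merges the evidence of two fusion detectors for one or more samples.
#' Gene pairs are matched order-insensitively between callers (caller
#' conventions for 5'/3' orientation differ). A fusion is called
#' positive only when (i) both callers detected the pair and (ii) its
#' expression, computed as RPM from the larger supporting-read count of
#' the two callers, reaches `rpmMin`. Fusions seen by a single caller
#' are retained in the output as negatives for review.
#'
#' @param evidence standardized evidence data.frame (rows from
#'   [readFusionCallerA()] / [readFusionCallerB()], possibly
#'   concatenated).
#' @param mappedReads named numeric vector (names = sample ids) or a
#'   manifest data.frame with `sample_id` and `mapped_reads`.
#' @param rpmMin expression threshold for positivity. The default 1000
#'   sits with margin below the RPM of bona fide highly expressed
#'   fusions in targeted panels (typically >= ~1500) and above
#'   single-caller background.
#' @return data.frame with one row per (sample, gene pair): `sample_id`,
#'   `gene5`, `gene3`, `supporting_reads`, `rpm`, `callers`,
#'   `n_callers`, `positive`.
#' @export
consensusCall <- function(evidence, mappedReads, rpmMin = 1000) {
  if (is.data.frame(mappedReads))
    mappedReads <- stats::setNames(mappedReads$mapped_reads,
                                   mappedReads$sample_id)
  need <- c("sample_id", "caller_id", "gene5", "gene3", "supporting_reads")
  if (length(setdiff(need, names(evidence))) > 0)
    stop("evidence needs columns: ", paste(need, collapse = ", "))
  if (nrow(evidence) == 0)
    return(data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character(), supporting_reads = integer(),
                      rpm = numeric(), callers = character(),
                      n_callers = integer(), positive = logical(),
                      stringsAsFactors = FALSE))
  if (any(evidence$gene5 == evidence$gene3))
    stop("fusion partners must differ")
  missing_mr <- setdiff(unique(evidence$sample_id), names(mappedReads))
  if (length(missing_mr) > 0)
    stop("no mapped-read total for sample(s): ",
         paste(missing_mr, collapse = ", "))
  grp <- paste(evidence$sample_id, .pairKey(evidence$gene5, evidence$gene3),
               sep = "\r")
  out <- lapply(split(seq_len(nrow(evidence)), grp), function(idx) {
    e <- evidence[idx, , drop = FALSE]
    best <- which.max(e$supporting_reads)
    callers <- sort(unique(e$caller_id))
    mr <- mappedReads[[e$sample_id[1]]]
    rpm <- computeRpm(max(e$supporting_reads), mr)
    data.frame(sample_id = e$sample_id[1], gene5 = e$gene5[best],
               gene3 = e$gene3[best],
               supporting_reads = max(e$supporting_reads), rpm = rpm,
               callers = paste(callers, collapse = ","),
               n_callers = length(callers),
               positive = length(callers) >= 2 && rpm >= rpmMin,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$sample_id, -res$rpm), , drop = FALSE]
  rownames(res) <- NULL
  res
}
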