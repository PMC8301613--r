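#' Parse a coding HGVS span (SNV, dup, del, ins)
#'
#' Supports the HGVS-c subset produced by targeted myeloid panels:
#' single-nucleotide substitutions (`c.181C>A`, including intron-offset
#' positions like `c.802-2A>T`), duplications and deletions over a
#' position or a range with an optional stated sequence
#' (`c.1747_1794dup`, `c.350dupG`, `c.917_934delGCAACGTGGAGACGCAGC`),
#' and insertions with a stated sequence (`c.912_913insTTG`). When a
#' sequence is stated for a dup/del its length must equal the span
#' length. The nucleotide length determines the frame: an event of
#' length divisible by three is in frame and its amino-acid length is
#' `ntLength / 3` -- e.g. a 48-nt internal tandem duplication is a
#' 16-amino-acid ITD.
#'
#' @param hgvsC HGVS coding string (single value).
#' @return object of class `HgvsSpan`: a list with `kind` (`"snv"`,
#'   `"dup"`, `"del"`, `"ins"`), `start`, `end`, `offset` (intron offset
#'   of an SNV, 0 otherwise), `ref`/`alt` (SNV bases or `""`),
#'   `sequence` (stated sequence or `""`), `ntLength`, `inFrame`,
#'   `aaLength` (`NA` when out of frame).
#' @examples
#' parseHgvsSpan("c.1747_1794dup")$aaLength   # 16
#' parseHgvsSpan("c.912_913insTTG")$ntLength  # 3
#' @export
parseHgvsSpan <- function(hgvsC) {
  stopifnot(is.character(hgvsC), length(hgvsC) == 1)
  x <- trimws(hgvsC)

  finish <- function(kind, start, end, offset = 0L, ref = "", alt = "",
                     sequence = "") {
    nt <- switch(kind,
                 snv = 1L,
                 ins = nchar(sequence),
                 dup = ,
                 del = end - start + 1L)
    if (kind %in% c("dup", "del") && nzchar(sequence) &&
        nchar(sequence) != nt)
      stop("stated sequence length (", nchar(sequence),
           ") does not match span length (", nt, ") in ", x)
    in_frame <- nt %% 3L == 0L
    structure(list(kind = kind, start = start, end = end,
                   offset = as.integer(offset), ref = ref, alt = alt,
                   sequence = sequence, ntLength = as.integer(nt),
                   inFrame = in_frame,
                   aaLength = if (in_frame) nt %/% 3L else NA_integer_),
              class = "HgvsSpan")
  }

  m <- regmatches(x, regexec(
    "^c\\.([0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$", x))[[1]]
  if (length(m) == 5) {
    pos <- as.integer(m[2])
    off <- if (nzchar(m[3])) as.integer(m[3]) else 0L
    return(finish("snv", pos, pos, offset = off, ref = m[4], alt = m[5]))
  }

  m <- regmatches(x, regexec(
    "^c\\.([0-9]+)(?:_([0-9]+))?(dup|del|ins)([ACGT]*)$", x))[[1]]
  if (length(m) == 5) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    kind <- m[4]
    seqn <- m[5]
    if (end < start) stop("span end before start in ", x)
    if (kind == "ins") {
      if (!nzchar(seqn))
        stop("insertion without a stated sequence is unsupported: ", x)
      if (end != start + 1L)
        stop("insertion positions must be adjacent (N_N+1) in ", x)
    }
    return(finish(kind, start, end, sequence = seqn))
  }

  stop("unsupported HGVS-c syntax: ", x)
}

#' Regenerate the HGVS string from a parsed span
#'
#' Inverse of [parseHgvsSpan()]: reconstructs the input notation from
#' the parsed fields, used to verify lossless parsing.
#'
#' @param span an `HgvsSpan`.
#' @return HGVS-c string.
#' @export
formatHgvsSpan <- function(span) {
  stopifnot(inherits(span, "HgvsSpan"))
  if (span$kind == "snv") {
    off <- if (span$offset != 0) sprintf("%+d", span$offset) else ""
    return(sprintf("c.%d%s%s>%s", span$start, off, span$ref, span$alt))
  }
  range <- if (span$end > span$start || span$kind == "ins")
    sprintf("%d_%d", span$start, span$end) else sprintf("%d", span$start)
  sprintf("c.%s%s%s", range, span$kind, span$sequence)
}

#' @export
print.HgvsSpan <- function(x, ...) {
  cat(sprintf("HgvsSpan %s: %s, %d nt", formatHgvsSpan(x), x$kind,
              x$ntLength))
  if (x$inFrame) cat(sprintf(", in frame (%d aa)", x$aaLength))
  cat("\n")
  invisible(x)
}

#' Summarise pathogenic mutations per patient
#'
#' Collapses a per-patient mutation table (one row per curated
#' pathogenic call; patients without any mutation carry a single row
#' with gene `"-"` or an empty gene field) into a sorted summary and the
#' count of patients carrying at least one pathogenic mutation.
#'
#' @param calls data.frame with columns `patient`, `gene`, and
#'   `vaf_percent`; additional columns (diagnosis, staining,
#'   `hgvs_c`, `hgvs_p`, ...) are carried through.
#' @return list with `table` (mutation rows sorted by patient, then
#'   descending VAF) and `nPatientsWithMutation`.
#' @export
summarizePathogenic <- function(calls) {
  if (nrow(calls) == 0)
    return(list(table = calls, nPatientsWithMutation = 0L))
  stopifnot(all(c("patient", "gene") %in% names(calls)))
  has_mut <- !is.na(calls$gene) & nzchar(calls$gene) & calls$gene != "-"
  tab <- calls[has_mut, , drop = FALSE]
  if (nrow(tab) > 0) {
    vaf <- if ("vaf_percent" %in% names(tab)) as.numeric(tab$vaf_percent)
           else rep(0, nrow(tab))
    tab <- tab[order(tab$patient, -vaf), , drop = FALSE]
    rownames(tab) <- NULL
  }
  list(table = tab,
       nPatientsWithMutation = length(unique(tab$patient)))
}
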