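#' Parse an ISCN karyotype string into structural rearrangements
#'
#' Extracts two-way translocation tokens `t(a;b)(band1;band2)` and
#' inversion tokens `inv(c)(band1band2)` from every clone of a
#' slash-separated ISCN karyotype. Clone sizes in brackets, gains and
#' losses (`+8`, `-Y`), and `add`/`del`/`i`/`mar`/`idem` tokens are
#' ignored; a token that looks like a translocation or inversion but
#' cannot be parsed is skipped with a warning, never an error. Duplicate
#' rearrangements across clones are reported once.
#'
#' @param iscn karyotype string, e.g.
#'   `"46,XY,t(8;21)(q22;q22)[17]/46,XY[3]"`.
#' @return data.frame with columns `kind` (`"translocation"` or
#'   `"inversion"`), `chrom1`, `chrom2` (equal to `chrom1` for
#'   inversions), `band1`, `band2`; zero rows for a normal karyotype.
#' @examples
#' parseKaryotype("46,XX,inv(16)(p13.1q22)[20]")
#' parseKaryotype("46,XX[20]")
#' @export
parseKaryotype <- function(iscn) {
  stopifnot(is.character(iscn), length(iscn) == 1)
  empty <- data.frame(kind = character(), chrom1 = character(),
                      chrom2 = character(), band1 = character(),
                      band2 = character(), stringsAsFactors = FALSE)
  if (is.na(iscn) || !nzchar(iscn)) return(empty)
  s <- gsub("\\[[^]]*\\]", "", iscn)       # strip clone sizes
  s <- gsub("\\s", "", s)
  clones <- strsplit(s, "/", fixed = TRUE)[[1]]
  ## tokens are comma separated; band lists inside parentheses use ';'
  tokens <- unlist(strsplit(clones, ",", fixed = TRUE))
  rows <- list()
  for (tok in tokens) {
    if (!nzchar(tok)) next
    if (grepl("^t\\(", tok)) {
      m <- regmatches(tok, regexec(
        "^t\\((\\w+);(\\w+)\\)\\(([pq][0-9.]+);([pq][0-9.]+)\\)$", tok))[[1]]
      if (length(m) == 5) {
        rows[[length(rows) + 1]] <- data.frame(
          kind = "translocation", chrom1 = m[2], chrom2 = m[3],
          band1 = m[4], band2 = m[5], stringsAsFactors = FALSE)
      } else {
        warning("unparseable translocation token skipped: ", tok)
      }
    } else if (grepl("^inv\\(", tok)) {
      m <- regmatches(tok, regexec(
        "^inv\\((\\w+)\\)\\(([pq][0-9.]+)([pq][0-9.]+)\\)$", tok))[[1]]
      if (length(m) == 4) {
        rows[[length(rows) + 1]] <- data.frame(
          kind = "inversion", chrom1 = m[2], chrom2 = m[2],
          band1 = m[3], band2 = m[4], stringsAsFactors = FALSE)
      } else {
        warning("unparseable inversion token skipped: ", tok)
      }
    }
    ## everything else (modal number, sex chromosomes, +/-, add, del,
    ## i, mar, idem, ...) is outside the recognized rearrangement scope
  }
  if (length(rows) == 0) return(empty)
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

.bandMatches <- function(stated, locusBand) {
  ## arm + major-band prefix comparison: q22 matches q22.1
  parse_band <- function(b) {
    m <- regmatches(b, regexec("^([pq])([0-9]+)", b))[[1]]
    if (length(m) != 3) return(NULL)
    c(arm = m[2], major = m[3])
  }
  a <- parse_band(stated)
  b <- parse_band(locusBand)
  if (is.null(a) || is.null(b)) return(FALSE)
  a["arm"] == b["arm"] && a["major"] == b["major"]
}

#' Is a consensus fusion concordant with the reported karyotype?
#'
#' A fusion of genes at loci `c5 b5` and `c3 b3` is concordant when some
#' parsed rearrangement involves exactly the chromosomes of the two
#' partners and each stated breakpoint band matches the partner's
#' cytoband at arm plus major-band resolution (so `q22` and `q22.1`
#' agree; ISCN resolution varies between laboratories). A normal
#' karyotype, or one without a matching token, is discordant (`FALSE`) --
#' the situation of a cryptic fusion detected by sequencing only. A
#' partner gene absent from the locus table yields `NA` (undetermined).
#'
#' @param gene5,gene3 fusion partner symbols.
#' @param karyotype ISCN string, or a parsed rearrangement data.frame
#'   from [parseKaryotype()].
#' @param locusTable gene-to-cytoband table (default [geneCytobands()]).
#' @return `TRUE`, `FALSE`, or `NA`.
#' @examples
#' karyotypeConcordance("RUNX1", "RUNX1T1", "46,XY,t(8;21)(q22;q22)[17]/46,XY[3]")
#' karyotypeConcordance("KMT2A", "MLLT10", "46,XX[20]")
#' @export
karyotypeConcordance <- function(gene5, gene3, karyotype,
                                 locusTable = geneCytobands()) {
  rearrs <- if (is.data.frame(karyotype)) karyotype
            else parseKaryotype(karyotype)
  i5 <- match(gene5, locusTable$gene)
  i3 <- match(gene3, locusTable$gene)
  if (is.na(i5) || is.na(i3)) return(NA)
  c5 <- locusTable$chrom[i5]; b5 <- locusTable$band[i5]
  c3 <- locusTable$chrom[i3]; b3 <- locusTable$band[i3]
  if (nrow(rearrs) == 0) return(FALSE)
  for (i in seq_len(nrow(rearrs))) {
    r <- rearrs[i, ]
    chrom_ok <- identical(sort(c(r$chrom1, r$chrom2)), sort(c(c5, c3)))
    if (!chrom_ok) next
    ## match each gene band against the stated band on its chromosome;
    ## for same-chromosome events try both band assignments
    direct <- (r$chrom1 == c5 && .bandMatches(r$band1, b5) &&
               r$chrom2 == c3 && .bandMatches(r$band2, b3))
    swapped <- (r$chrom1 == c3 && .bandMatches(r$band1, b3) &&
                r$chrom2 == c5 && .bandMatches(r$band2, b5))
    if (direct || swapped) return(TRUE)
  }
  FALSE
}
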