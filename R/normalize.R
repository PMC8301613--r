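#' Normalize an allele substitution or indel to its minimal representation
#'
#' Trims the longest shared suffix of `ref` and `alt`, then the longest
#' shared prefix, always keeping at least one base in each allele, and
#' advances `pos` by the number of prefix bases trimmed. Normalized keys
#' make calls from different callers and samples comparable. The operation
#' is idempotent. No reference-genome left-alignment is performed, so two
#' representations of the same indel inside a homopolymer that differ by
#' placement are not unified (documented limitation).
#'
#' @param chrom chromosome / contig name(s).
#' @param pos 1-based position(s).
#' @param ref,alt allele strings; `ref != alt`, both non-empty.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalizeVariant("chr1", 100, "TC", "TA")   # -> pos 101, C>A
#' normalizeVariant("chr1", 100, "CTT", "CT")  # -> pos 100, CT>C
#' @export
normalizeVariant <- function(chrom, pos, ref, alt) {
  n <- max(length(chrom), length(pos), length(ref), length(alt))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("ref and alt must be non-empty")
  if (any(ref == alt))
    stop("not a variant: ref equals alt")
  for (i in seq_len(n)) {
    r <- strsplit(ref[i], "", fixed = TRUE)[[1]]
    a <- strsplit(alt[i], "", fixed = TRUE)[[1]]
    ## shared suffix, keep >= 1 base each
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    ## shared prefix, keep >= 1 base each (the indel anchor), advance pos
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- paste(r, collapse = "")
    alt[i] <- paste(a, collapse = "")
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
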