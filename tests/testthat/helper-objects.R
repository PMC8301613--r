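# compact builders for hand-crafted call sets used across the tests

makeVariants <- function(pos, vaf = 0.3, depth = 100, filter = "PASS",
                         chrom = "chr1", ref = "A", alt = "T", ...) {
  n <- length(pos)
  extra <- lapply(list(...), rep_len, n)
  do.call(data.frame,
          c(list(chrom = rep_len(chrom, n), pos = as.integer(pos),
                 ref = rep_len(ref, n), alt = rep_len(alt, n),
                 vaf = rep_len(vaf, n), depth = rep_len(depth, n),
                 filter = rep_len(filter, n)),
            extra, list(stringsAsFactors = FALSE)))
}

makeCallSet <- function(pos, vaf = 0.3, tissue = "smear",
                        callerClass = "somatic", sampleId = "S1", ...) {
  CallSet(makeVariants(pos, vaf = vaf, ...), sampleId = sampleId,
          tissue = tissue, callerClass = callerClass)
}

randomCallSet <- function(n, tissue, poolSize = 50, callerClass = "somatic") {
  pos <- sample.int(poolSize, n)
  makeCallSet(pos, vaf = runif(n), tissue = tissue,
              callerClass = callerClass)
}
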