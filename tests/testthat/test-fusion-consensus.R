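evidenceRow <- function(sample, caller, g5, g3, reads) {
  data.frame(sample_id = sample, caller_id = caller, gene5 = g5, gene3 = g3,
             supporting_reads = reads, stringsAsFactors = FALSE)
}

test_that("RPM is supporting reads per million mapped reads", {
  expect_equal(computeRpm(0, 123456), 0)
  expect_equal(computeRpm(1551, 1e6), 1551)
  expect_equal(computeRpm(500, 48261), 10360.3, tolerance = 1e-4)
  expect_error(computeRpm(10, 0), "mappedReads")
  expect_error(computeRpm(-1, 100), "supportingReads")
})

test_that("consensus requires both callers and sufficient expression", {
  mapped <- c(S1 = 50000)
  both_high <- rbind(evidenceRow("S1", "A", "CBFB", "MYH11", 200),
                     evidenceRow("S1", "B", "MYH11", "CBFB", 150))
  res <- consensusCall(both_high, mapped)
  expect_true(res$positive)
  expect_equal(res$n_callers, 2)
  ## RPM uses the larger supporting-read count
  expect_equal(res$rpm, 200 / 50000 * 1e6)

  one_caller <- evidenceRow("S1", "A", "CBFB", "MYH11", 5000)
  expect_false(consensusCall(one_caller, mapped)$positive)

  both_low <- rbind(evidenceRow("S1", "A", "CBFB", "MYH11", 10),
                    evidenceRow("S1", "B", "CBFB", "MYH11", 12))
  expect_false(consensusCall(both_low, mapped)$positive)

  expect_error(consensusCall(both_high, c(S2 = 100)), "no mapped-read")
})

test_that("consensus positivity is monotone in reads and anti-monotone in rpmMin", {
  mapped <- c(S1 = 1e6)
  pos_at <- function(reads, rpmMin = 1000) {
    ev <- rbind(evidenceRow("S1", "A", "ETV6", "CHIC2", reads),
                evidenceRow("S1", "B", "ETV6", "CHIC2", reads))
    consensusCall(ev, mapped, rpmMin = rpmMin)$positive
  }
  flags <- vapply(c(10, 999, 1000, 5000), pos_at, TRUE)
  expect_equal(flags, c(FALSE, FALSE, TRUE, TRUE))  # monotone in reads
  expect_true(pos_at(2000, rpmMin = 500))
  expect_false(pos_at(2000, rpmMin = 5000))         # anti-monotone in rpmMin
})

test_that("ISCN parsing extracts translocations and inversions, skips the rest", {
  t1 <- parseKaryotype("46,XY,t(8;21)(q22;q22)[17]/46,XY[3]")
  expect_equal(nrow(t1), 1)
  expect_equal(t1$kind, "translocation")
  expect_equal(c(t1$chrom1, t1$chrom2), c("8", "21"))

  expect_equal(nrow(parseKaryotype("46,XX[20]")), 0)

  inv <- parseKaryotype("46,XX,inv(16)(p13.1q22)[20]")
  expect_equal(inv$kind, "inversion")
  expect_equal(inv$chrom1, "16")
  expect_equal(c(inv$band1, inv$band2), c("p13.1", "q22"))

  ## aneuploidies, markers, add/del/idem tokens are ignored, never fatal
  messy <- parseKaryotype(
    "46,XY,t(8;21)(q22;q22.1)[3]/46,idem,-Y[14]/46,idem,del(9)(q?)[2]/46,XY[1]")
  expect_equal(nrow(messy), 1)
  expect_warning(parseKaryotype("46,XY,t(8;21;3)(q22;q22;p1)[5]"),
                 "skipped")
})

test_that("karyotype concordance matches chromosomes and band prefixes", {
  expect_true(karyotypeConcordance("RUNX1", "RUNX1T1",
                                   "46,XY,t(8;21)(q22;q22)[17]/46,XY[3]"))
  ## band prefix level: q22 in the locus table matches q22.1 in the report
  expect_true(karyotypeConcordance("RUNX1", "RUNX1T1",
                                   "46,XY,t(8;21)(q22;q22.1)[3]/46,XY[1]"))
  expect_false(karyotypeConcordance("KMT2A", "MLLT10", "46,XX[20]"))
  expect_true(karyotypeConcordance("CBFB", "MYH11",
                                   "46,XX,inv(16)(p13.1q22)[20]"))
  ## wrong chromosomes
  expect_false(karyotypeConcordance("KMT2A", "MLLT10",
                                    "46,XY,t(8;21)(q22;q22)[17]"))
  ## gene missing from the locus table: undetermined, not discordant
  expect_true(is.na(karyotypeConcordance("NOSUCHGENE", "RUNX1",
                                         "46,XX[20]")))
})

test_that("the bundled cohort table yields five karyotype-concordant fusions", {
  tab <- read.delim(system.file("extdata", "fusion_karyotype_cohort.tsv",
                                package = "smearseq"),
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 15)
  ## every karyotype string parses without error
  for (k in tab$karyotype) expect_no_error(parseKaryotype(k))
  with_fusion <- tab[tab$fusion != "-", ]
  conc <- vapply(seq_len(nrow(with_fusion)), function(i) {
    genes <- strsplit(with_fusion$fusion[i], "-", fixed = TRUE)[[1]]
    isTRUE(karyotypeConcordance(genes[1], genes[2],
                                with_fusion$karyotype[i]))
  }, TRUE)
  expect_equal(sum(conc), 5)
  ## the cryptic fusions are the sequencing-only findings
  expect_setequal(with_fusion$sample_id[!conc], c("#152", "#231"))
})

test_that("fusion caller table dialects read into standardized evidence", {
  fa <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tfusion_genes\tspanning_reads",
               "S1\tCBFB:MYH11\t120"), fa)
  a <- readFusionCallerA(fa)
  expect_equal(a$gene5, "CBFB")
  expect_equal(a$caller_id, "A")

  fb <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tleft_gene\tright_gene\tjunction_reads",
               "S1\tMYH11\tCBFB\t90"), fb)
  b <- readFusionCallerB(fb)
  expect_equal(b$supporting_reads, 90L)

  res <- consensusCall(rbind(a, b), c(S1 = 1e5))
  expect_equal(nrow(res), 1)   # order-insensitive pair matching
  expect_true(res$positive)
})
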