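test_that("allele normalization trims suffix then prefix and is idempotent", {
  expect_equal(normalizeVariant("chr1", 100, "TC", "TA"),
               data.frame(chrom = "chr1", pos = 101L, ref = "C", alt = "A"))
  expect_equal(normalizeVariant("chr1", 100, "A", "T"),
               data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T"))
  expect_equal(normalizeVariant("chr1", 100, "CTT", "CT"),
               data.frame(chrom = "chr1", pos = 100L, ref = "CT", alt = "C"))
  expect_error(normalizeVariant("chr1", 1, "A", "A"), "not a variant")
  expect_error(normalizeVariant("chr1", 1, "", "T"), "non-empty")

  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    alt <- paste(sample(bases, sample(1:6, 1), replace = TRUE), collapse = "")
    if (ref == alt) next
    once <- normalizeVariant("c", 50, ref, alt)
    twice <- normalizeVariant(once$chrom, once$pos, once$ref, once$alt)
    expect_identical(twice, once)
  }
})

test_that("VCF records map to calls: decomposition, flags, AD precedence", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="af">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="dp">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="ad">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="dp">',
    "##contig=<ID=1>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\tDP=50;AF=0.4\t.\t.",
    "1\t200\t.\tG\tT,C\t.\t.\tDP=100;AF=0.1,0.2\t.\t.",
    "1\t300\t.\tC\tG\t.\tweak_evidence;panel_of_normals\tDP=30;AF=0.5\t.\t.",
    "1\t400\t.\tA\tG\t.\tPASS\tAF=0.9\tAD:DP\t75,25:100")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  cs <- readVariantVcf(f, "S1", "smear", "somatic")
  v <- variants(cs)
  expect_equal(nrow(v), 5)  # multiallelic decomposed into one per allele
  expect_equal(v[v$pos == 100, c("vaf", "depth", "filter")],
               data.frame(vaf = 0.4, depth = 50, filter = "PASS"),
               ignore_attr = TRUE)
  ## missing FILTER maps to PASS; per-allele AF entries preserved
  multi <- v[v$pos == 200, ]
  expect_setequal(multi$alt, c("T", "C"))
  expect_setequal(multi$vaf, c(0.1, 0.2))
  expect_true(all(multi$filter == "PASS"))
  ## failure labels kept verbatim as the flag set
  expect_equal(v$filter[v$pos == 300], "weak_evidence;panel_of_normals")
  ## FORMAT AD/DP wins over INFO AF
  expect_equal(v$vaf[v$pos == 400], 0.25)
})

test_that("malformed records and underivable VAF raise informative errors", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "1\t100\t.\tA\tT\t.\tPASS\t.",
               "1\tXYZ\t.\tA"), f)
  expect_error(readVariantVcf(f, "S1", "smear", "somatic"), "line 4")

  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=DP,Number=1,Type=Integer,Description="dp">',
               "##contig=<ID=1>",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t"),
               "1\t100\t.\tA\tT\t.\tPASS\tDP=50"), f)
  expect_error(readVariantVcf(f, "S1", "smear", "somatic"),
               "VAF not derivable.*1:100")
})

test_that("CallSet construction deduplicates by depth and validates", {
  dup <- rbind(makeVariants(5, depth = 30), makeVariants(5, depth = 60),
               makeVariants(7, depth = 10))
  cs <- CallSet(dup, "S1", "smear", "somatic")
  expect_equal(length(cs), 2)
  expect_equal(variants(cs)$depth[variants(cs)$pos == 5], 60)

  expect_equal(length(CallSet(makeVariants(integer(0)), "S1", "smear",
                              "somatic")), 0)
  expect_equal(length(makeCallSet(1:3)), 3)

  bad <- makeVariants(1:2, caller_class = c("somatic", "germline"))
  expect_error(CallSet(bad, "S1", "smear", "somatic"), "caller_class")
  expect_error(makeCallSet(1, vaf = 1.5), "vaf")
  expect_error(makeCallSet(0), "pos")
  expect_error(CallSet(makeVariants(1), "S1", "slide", "somatic"), "tissue")
})

test_that("parse-write-parse round trip preserves key, VAF, depth, flags", {
  pair <- simulatePairedCallsets(syntheticConfig(seed = 5), 1)
  f <- tempfile(fileext = ".vcf")
  writeVariantVcf(pair$smear, f)
  back <- readVariantVcf(f, sampleId(pair$smear), "smear", "somatic")
  v1 <- variants(pair$smear)
  v2 <- variants(back)
  expect_identical(variantKeys(back), variantKeys(pair$smear))
  expect_lt(max(abs(v1$vaf - v2$vaf)), 1e-4)
  expect_equal(round(v1$depth), round(v2$depth))
  expect_identical(v1$filter, v2$filter)
  expect_identical(v1$known_snp, v2$known_snp)
})
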