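test_that("caller flag filter keeps exactly the PASS records", {
  cs <- CallSet(makeVariants(1:3, filter = c("PASS", "weak_evidence",
                                             "strand_bias;base_qual")),
                "S1", "smear", "somatic")
  res <- applyFlagFilter(cs)
  expect_equal(variants(res$callset)$pos, 1L)
  expect_equal(nrow(res$removed), 2)
  empty <- applyFlagFilter(makeCallSet(integer(0)))
  expect_equal(length(empty$callset), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("hard filters use inclusive thresholds and pass missing annotations", {
  cs <- CallSet(makeVariants(1:4,
                             qd = c(1.5, 2.0, NA, 30),
                             mq = c(60, 60, NA, 10),
                             fs = c(5, 60, NA, 5)),
                "S1", "smear", "germline")
  res <- applyHardFilters(cs, qdMin = 2.0, mqMin = 40, fsMax = 60)
  ## QD below threshold removed; exact boundary kept; all-missing kept;
  ## low MQ removed
  expect_equal(variants(res$callset)$pos, c(2L, 3L))
  expect_error(applyHardFilters(cs, qdMin = -1), "non-negative")
  expect_error(applyHardFilters(makeCallSet(1, callerClass = "somatic")),
               "germline")
})

test_that("panel of normals counts membership and subtracts at the threshold", {
  norm <- function(pos, id) makeCallSet(pos, tissue = "bmc", sampleId = id)
  normals <- list(norm(c(1, 2), "N1"), norm(c(1, 3), "N2"),
                  norm(c(1, 2), "N3"))
  pon <- buildPanelOfNormals(normals, minSamples = 2)
  entries <- panelEntries(pon)
  expect_equal(unname(entries[order(names(entries))]),
               c(3L, 2L, 1L))  # keys at pos 1, 2, 3
  expect_error(buildPanelOfNormals(list()), "no normal samples")

  cs <- makeCallSet(1:5)
  res <- subtractPanel(cs, pon)           # pos 1 and 2 subtractable
  expect_equal(variants(res$callset)$pos, 3:5)
  expect_equal(nrow(res$removed) + length(res$callset), length(cs))

  pon1 <- buildPanelOfNormals(normals, minSamples = 1)
  expect_equal(variants(subtractPanel(cs, pon1)$callset)$pos, 4:5)

  ## min_samples above the panel size: identity
  pon99 <- buildPanelOfNormals(normals, minSamples = 99)
  expect_equal(length(subtractPanel(cs, pon99)$callset), length(cs))

  empty_pon <- buildPanelOfNormals(list(norm(integer(0), "N1"),
                                        norm(integer(0), "N2")))
  expect_equal(length(subtractPanel(cs, empty_pon)$callset), length(cs))

  all_in <- makeCallSet(1:2)
  expect_equal(length(subtractPanel(all_in, pon)$callset), 0)
})

test_that("VAF threshold removes strictly-below calls only", {
  cs <- makeCallSet(1:3, vaf = c(0.0304, 0.024, 0.5))
  res <- filterVaf(cs, 0.025)
  ## a 3.04% call survives the 2.5% boundary; 2.4% does not
  expect_equal(variants(res$callset)$vaf, c(0.0304, 0.5))
  expect_equal(length(filterVaf(cs, 0)$callset), 3)
  expect_error(filterVaf(cs, 1.5), "\\[0, 1\\]")
  expect_error(filterVaf(cs, -0.1), "\\[0, 1\\]")
})

test_that("population-frequency filter excludes prevalence strictly above 1%", {
  cs <- CallSet(makeVariants(1:3, population_af = c(0.02, 0.01, NA)),
                "S1", "smear", "somatic")
  res <- filterPopulationAf(cs)
  expect_equal(variants(res$callset)$pos, 2:3)
  expect_equal(res$removed$population_af, 0.02)
})

test_that("region classification: SNP flag dominates, splice window is 2 bases", {
  v <- makeVariants(1:6,
                    known_snp = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                    region = c("exon", "exon", "splice", "intron", "intron",
                               "intron"),
                    exon_distance = c(NA, NA, NA, 2, 3, NA))
  expect_equal(classifyRegion(v),
               c("SNP", "exon+splice", "exon+splice", "exon+splice",
                 "intron", "intron"))
  expect_warning(cls <- classifyRegion(makeVariants(1)), "without region")
  expect_equal(cls, "intron")
})

test_that("the cascade runs its four stages in order and conserves counts", {
  ## all-PASS, high-VAF, no panel: identity
  cs <- makeCallSet(1:4, vaf = 0.4)
  res <- runCascade(cs, pon = NULL)
  expect_equal(filterStages(res$report)$stage,
               c("flag_filter", "pon_subtraction", "vaf_threshold",
                 "population_af"))
  expect_equal(filterStages(res$report)$removed, rep(0L, 4))
  expect_equal(length(res$callset), 4)

  ## crafted so each stage removes exactly one call
  v <- makeVariants(1:5,
                    filter = c("weak_evidence", "PASS", "PASS", "PASS", "PASS"),
                    vaf = c(0.3, 0.3, 0.01, 0.3, 0.3),
                    population_af = c(NA, NA, NA, 0.05, NA))
  cs2 <- CallSet(v, "S1", "smear", "somatic")
  pon <- buildPanelOfNormals(list(makeCallSet(2, tissue = "bmc"),
                                  makeCallSet(2, tissue = "bmc",
                                              sampleId = "N2")),
                             minSamples = 2)
  res2 <- runCascade(cs2, pon)
  st <- filterStages(res2$report)
  expect_equal(st$removed, rep(1L, 4))
  expect_equal(st$n_in[-1], st$retained[-4])
  expect_equal(variants(res2$callset)$pos, 5L)

  ## disposition covers every input key exactly once
  expect_setequal(res2$disposition$key, variantKeys(cs2))
  expect_equal(sort(unique(res2$disposition$stage)),
               sort(c("flag_filter", "pon_subtraction", "vaf_threshold",
                      "population_af", "retained")))
})

test_that("filters are idempotent, VAF/population filters commute, output is monotone", {
  set.seed(99)
  for (i in 1:20) {
    cs <- CallSet(makeVariants(1:30, vaf = runif(30),
                               population_af = ifelse(runif(30) < 0.5, NA,
                                                      runif(30, 0, 0.05)),
                               filter = sample(c("PASS", "weak_evidence"),
                                               30, TRUE)),
                  "S1", "smear", "somatic")
    thr <- runif(1)
    once <- filterVaf(cs, thr)$callset
    expect_identical(variants(filterVaf(once, thr)$callset), variants(once))
    f_once <- applyFlagFilter(cs)$callset
    expect_identical(variants(applyFlagFilter(f_once)$callset),
                     variants(f_once))
    p_once <- filterPopulationAf(cs)$callset
    expect_identical(variants(filterPopulationAf(p_once)$callset),
                     variants(p_once))

    ## commutation of the two annotation-level filters
    ab <- filterPopulationAf(filterVaf(cs, thr)$callset)$callset
    ba <- filterVaf(filterPopulationAf(cs)$callset, thr)$callset
    expect_identical(variants(ab), variants(ba))
  }

  ## retained size is non-increasing in the threshold
  cs <- CallSet(makeVariants(1:50, vaf = runif(50)), "S1", "smear", "somatic")
  sizes <- vapply(seq(0, 1, 0.1),
                  function(t) length(filterVaf(cs, t)$callset), 0L)
  expect_true(all(diff(sizes) <= 0))
})
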