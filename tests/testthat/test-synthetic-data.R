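test_that("generation is deterministic: same seed gives byte-identical VCF", {
  cfg <- syntheticConfig(seed = 31)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  writeVariantVcf(simulatePairedCallsets(cfg, 2)$smear, f1)
  writeVariantVcf(simulatePairedCallsets(syntheticConfig(seed = 31),
                                         2)$smear, f2)
  expect_identical(readLines(f1), readLines(f2))
  ## different pair index diverges
  f3 <- tempfile(fileext = ".vcf")
  writeVariantVcf(simulatePairedCallsets(cfg, 3)$smear, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("without injected noise the smear and BMC key sets are identical", {
  cfg <- syntheticConfig(seed = 32, smearArtifactLambda = 0, nBmcErrors = 0)
  pair <- simulatePairedCallsets(cfg, 1)
  expect_setequal(variantKeys(pair$smear), variantKeys(pair$bmc))
})

test_that("truth labels cover every emitted key exactly once", {
  pair <- simulatePairedCallsets(syntheticConfig(seed = 33), 1)
  truth <- pair$truth
  expect_false(anyDuplicated(truth$key) > 0)
  emitted <- union(variantKeys(pair$smear), variantKeys(pair$bmc))
  expect_setequal(emitted, truth$key)
  expect_setequal(unique(truth$class),
                  c("germline_snp", "somatic", "smear_artifact", "bmc_error",
                    "assay_artifact"))
})

test_that("smear-unique counts follow the configured Poisson load", {
  lambda <- 400
  counts <- vapply(1:50, function(i) {
    cfg <- syntheticConfig(seed = 1000 + i, smearArtifactLambda = lambda)
    sum(simulatePairedCallsets(cfg, 1)$truth$class == "smear_artifact")
  }, 0)
  ## mean of 50 replicates inside the 99% interval of Poisson(400)/sqrt(50)
  half <- qnorm(0.995) * sqrt(lambda / 50)
  expect_gt(mean(counts), lambda - half)
  expect_lt(mean(counts), lambda + half)
})

test_that("the normal panel carries SNPs and assay artifacts but no tumor keys", {
  cfg <- syntheticConfig(seed = 34)
  normals <- simulateNormalPanel(cfg)
  expect_length(normals, 13)
  pair <- simulatePairedCallsets(cfg, 1)
  truth <- pair$truth
  assay_keys <- truth$key[truth$class == "assay_artifact"]
  pon <- buildPanelOfNormals(normals, minSamples = 2)
  subtractable <- names(panelEntries(pon))[
    panelEntries(pon) >= 2]
  ## every assay artifact recurs in >= 2 normals, hence is subtractable
  expect_true(all(assay_keys %in% subtractable))
  ## no somatic or smear-artifact key ever enters a normal
  tumor_keys <- truth$key[truth$class %in% c("somatic", "smear_artifact")]
  panel_keys <- unlist(lapply(normals, variantKeys))
  expect_length(intersect(tumor_keys, panel_keys), 0)

  expect_error(simulateNormalPanel(syntheticConfig(nNormals = 1)),
               "at least 2")

  ## with no assay artifacts, subtraction is the identity on somatic truth
  cfg0 <- syntheticConfig(seed = 35, nAssayArtifacts = 0)
  pair0 <- simulatePairedCallsets(cfg0, 1)
  pon0 <- buildPanelOfNormals(simulateNormalPanel(cfg0), minSamples = 2)
  kept <- variantKeys(subtractPanel(pair0$smear, pon0)$callset)
  som0 <- pair0$truth$key[pair0$truth$class == "somatic"]
  expect_true(all(som0 %in% kept))
})

test_that("a key placed in a single normal is not subtractable at minSamples 2", {
  lone <- makeCallSet(99, tissue = "bmc", sampleId = "N1")
  others <- lapply(2:13, function(i)
    makeCallSet(i, tissue = "bmc", sampleId = sprintf("N%02d", i)))
  pon <- buildPanelOfNormals(c(list(lone), others), minSamples = 2)
  probe <- makeCallSet(99)
  expect_equal(length(subtractPanel(probe, pon)$callset), 1)
})

test_that("fusion evidence: true fusions in both callers, decoys in one", {
  cfg <- syntheticConfig(seed = 36, nDecoysPerCaller = 0, nTrueFusions = 1)
  sim <- simulateFusionEvidence(cfg)
  res <- consensusCall(rbind(sim$callerA, sim$callerB), sim$manifest)
  pos <- res[res$positive, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$sample_id, sim$truth$sample_id)
  expect_setequal(c(pos$gene5, pos$gene3),
                  c(sim$truth$gene5, sim$truth$gene3))

  cfg2 <- syntheticConfig(seed = 37, nTrueFusions = 0, nDecoysPerCaller = 4)
  sim2 <- simulateFusionEvidence(cfg2)
  res2 <- consensusCall(rbind(sim2$callerA, sim2$callerB), sim2$manifest)
  expect_false(any(res2$positive))

  ## expression just below the threshold is negative despite two callers
  ev <- rbind(
    data.frame(sample_id = "S1", caller_id = "A", gene5 = "PML",
               gene3 = "RARA", supporting_reads = 999),
    data.frame(sample_id = "S1", caller_id = "B", gene5 = "PML",
               gene3 = "RARA", supporting_reads = 800))
  expect_false(consensusCall(ev, c(S1 = 1e6), rpmMin = 1000)$positive)
})

test_that("amplicon coverage generator honors its dispersion and seed", {
  flat <- simulateAmpliconCoverage(syntheticConfig(seed = 38,
                                                   ampliconSdlog = 0))
  expect_equal(length(unique(round(flat$mean_coverage, 6))), 1)
  expect_equal(coverageSummary(flat)$uniformity, 1)

  a <- simulateAmpliconCoverage(syntheticConfig(seed = 39))
  b <- simulateAmpliconCoverage(syntheticConfig(seed = 39))
  expect_identical(a, b)

  ## forcing 5% of amplicons to a tenth of the median drops uniformity to 0.95
  cov <- rep(1000, 200)
  cov[1:10] <- 100
  expect_equal(coverageSummary(cov)$uniformity, 0.95)
})
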