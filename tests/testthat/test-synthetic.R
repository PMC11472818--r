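cfg <- simulationConfig()

test_that("simulated spectra are deterministic under a fixed seed", {
  c1 <- fx_candidates[["C14:1"]]
  s1 <- simulateSpectrum(c1, cfg, seed = 101)
  s2 <- simulateSpectrum(c1, cfg, seed = 101)
  expect_identical(spectrumPeaks(s1), spectrumPeaks(s2))
  expect_identical(precursorMz(s1), precursorMz(s2))
  s3 <- simulateSpectrum(c1, cfg, seed = 102)
  expect_false(identical(spectrumPeaks(s1), spectrumPeaks(s3)))
})

test_that("noise-free ladder peaks stay within the 3-sigma ppm bound", {
  cfgTight <- simulationConfig(dropoutProb = 0, nDecoyPeaks = 0L)
  c1 <- fx_candidates[["C14:1"]]
  lad <- fragmentLadder(c1)
  sp <- simulateSpectrum(c1, cfgTight, seed = 103)
  pk <- spectrumPeaks(sp)
  expect_equal(nrow(pk), nrow(lad))
  m <- matchPeaks(sp, lad, tolPpm = 6)  # 3 sigma at sigma = 2 ppm
  expect_gte(nrow(m), nrow(lad) - 1L)
})

test_that("full dropout leaves only decoy peaks", {
  cfgDrop <- simulationConfig(dropoutProb = 1)
  sp <- simulateSpectrum(fx_candidates[["C12:0"]], cfgDrop, seed = 104)
  expect_equal(nrow(spectrumPeaks(sp)), cfgDrop@nDecoyPeaks)
})

test_that("planted-fragment recall meets the statistical contract", {
  # sigma = 2 ppm jitter against 10 ppm matching: recall >= 0.99
  # over >= 1000 fragments
  cfgRec <- simulationConfig(dropoutProb = 0, nDecoyPeaks = 0L)
  total <- 0L
  matched <- 0L
  seed <- 200L
  while (total < 1000L) {
    seed <- seed + 1L
    for (cand in fx_candidates) {
      lad <- fragmentLadder(cand)
      sp <- simulateSpectrum(cand, cfgRec, seed = seed)
      total <- total + nrow(lad)
      matched <- matched + nrow(matchPeaks(sp, lad, tolPpm = 10))
    }
  }
  expect_gte(matched / total, 0.99)
})

test_that("simulated experiments are cross-consistent and deterministic", {
  sim <- simulateExperiment(cfg, seed = 301)
  sim2 <- simulateExperiment(cfg, seed = 301)
  expect_identical(featureIntensities(sim$featureTable),
                   featureIntensities(sim2$featureTable))
  expect_identical(lapply(sim$spectra, spectrumPeaks),
                   lapply(sim2$spectra, spectrumPeaks))
  # ids cross-reference: every truth feature is in the table exactly once
  gt <- sim$groundTruth
  ids <- rownames(featureIntensities(sim$featureTable))
  allTruth <- c(names(gt$analogFeatures), gt$backgroundFeatureIds,
                gt$decoyFeatureIds)
  expect_setequal(ids, allTruth)
  expect_equal(anyDuplicated(allTruth), 0L)
  # spectra sample ids all appear in the metadata
  expect_true(all(vapply(sim$spectra, function(s) s@sampleId, character(1))
                  %in% sim$sampleMetadata$sampleId))
})

test_that("planted analogs are exactly the differential features", {
  sim <- simulateExperiment(cfg, seed = 302)
  d <- differentialFeatures(sim$featureTable)
  expect_setequal(d$featureId, names(sim$groundTruth$analogFeatures))
  # zero planted analogs: empty differential list
  cfg0 <- simulationConfig(plantedTails = list())
  sim0 <- simulateExperiment(cfg0, seed = 303)
  expect_equal(nrow(differentialFeatures(sim0$featureTable)), 0L)
})

test_that("the four planted analogs cluster into one network family", {
  sim <- simulateExperiment(cfg, seed = 304)
  lowRep1 <- Filter(function(s) s@sampleId == "low_iron_rep1", sim$spectra)
  net <- buildNetwork(lowRep1)
  fams <- networkFamilies(net)
  analogFam <- Filter(function(f) any(grepl("analog", f)), fams)
  expect_equal(length(analogFam), 1L)
  expect_setequal(analogFam[[1]],
                  grep("analog", names(lowRep1), value = TRUE))
})

test_that("tail recovery exceeds 95% across seeds at default noise", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    for (lbl in names(fx_candidates)) {
      sp <- simulateSpectrum(fx_candidates[[lbl]], cfg,
                             seed = 1000L + 37L * seed + total)
      ann <- annotateAnalog(sp, fx_scaffold)
      total <- total + 1L
      if (ann$verdict == "annotated" && ann$tailLabel == lbl)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("metal-treatment simulations honour their scenario contract", {
  c1 <- fx_candidates[["C14:1"]]
  sim <- simulateMetalTreatment(c1, "Fe", "stable-complex", seed = 401)
  holoMz <- holoHypotheses(c1, "Fe")$theoreticalMz[1]
  expect_true(any(abs(sim$after$mz - holoMz) / holoMz < 1e-6 * 2))
  expect_false(any(abs(sim$after$mz - mhTheoretical(c1)) < 0.01))
  simNo <- simulateMetalTreatment(c1, "Cu", "no-reaction", seed = 402)
  expect_true(all(simNo$before$mz %in% simNo$after$mz))
})
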