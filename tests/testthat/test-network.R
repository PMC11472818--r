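test_that("modified cosine: self-similarity, disjoint spectra, emptiness", {
  s <- fx_spectrum("s", 500, c(100, 200, 300), c(5, 2, 9))
  mc <- modifiedCosine(s, s)
  expect_equal(mc$cosine, 1, tolerance = 1e-12)
  expect_equal(mc$nMatched, 3L)
  a <- fx_spectrum("a", 500, c(100, 200))
  b <- fx_spectrum("b", 500, c(150.5, 250.7))
  expect_equal(modifiedCosine(a, b)$cosine, 0)
  empty <- spectrum("e", 400, matrix(numeric(0), ncol = 2))
  expect_error(modifiedCosine(a, empty), "non-empty")
})

test_that("modified cosine is symmetric, bounded, and scale-invariant", {
  set.seed(13)
  for (i in 1:10) {
    a <- fx_spectrum("a", runif(1, 400, 1200), sort(runif(15, 100, 1000)),
                     rlnorm(15, 8, 1))
    b <- fx_spectrum("b", runif(1, 400, 1200), sort(runif(15, 100, 1000)),
                     rlnorm(15, 8, 1))
    ab <- modifiedCosine(a, b)
    ba <- modifiedCosine(b, a)
    expect_equal(ab$cosine, ba$cosine, tolerance = 1e-9)
    expect_equal(ab$nMatched, ba$nMatched)
    expect_gte(ab$cosine, 0)
    expect_lte(ab$cosine, 1)
    # global intensity scaling of either argument changes nothing
    pk <- spectrumPeaks(b)
    b10 <- spectrum("b10", precursorMz(b),
                    cbind(pk[, 1], pk[, 2] * 1000))
    expect_equal(modifiedCosine(a, b10)$cosine, ab$cosine, tolerance = 1e-9)
  }
})

test_that("precursor-shifted peak pairs contribute to the score", {
  # b shifted by +28.0313 relative to a, precursors shifted equally:
  # all peaks pair in the shifted channel
  mz <- c(200, 350, 500)
  a <- fx_spectrum("a", 1000, mz)
  b <- fx_spectrum("b", 1028.0313, mz + 28.0313)
  mc <- modifiedCosine(a, b)
  expect_equal(mc$cosine, 1, tolerance = 1e-9)
  expect_equal(mc$nMatched, 3L)
})

test_that("exact assignment never scores below greedy", {
  set.seed(17)
  for (i in 1:5) {
    a <- fx_spectrum("a", runif(1, 400, 800), sort(runif(6, 100, 390)),
                     rlnorm(6, 5, 1))
    b <- fx_spectrum("b", runif(1, 400, 800), sort(runif(6, 100, 390)),
                     rlnorm(6, 5, 1))
    g <- modifiedCosine(a, b, fragTol = 5)$cosine
    e <- modifiedCosine(a, b, fragTol = 5, method = "exact")$cosine
    expect_gte(e, g - 1e-12)
  }
})

test_that("synthetic analog spectra score like the published cluster", {
  cfg <- simulationConfig()
  s1 <- simulateSpectrum(fx_candidates[["C14:1"]], cfg, seed = 31, id = "c1")
  s3 <- simulateSpectrum(fx_candidates[["C12:1"]], cfg, seed = 33, id = "c3")
  mc <- modifiedCosine(s1, s3)
  expect_gte(mc$cosine, 0.55)
  expect_gte(mc$nMatched, 6L)
})

test_that("network construction applies thresholds and finds families", {
  cfg <- simulationConfig()
  analogs <- lapply(seq_along(fx_candidates), function(k)
    simulateSpectrum(fx_candidates[[k]], cfg, seed = 40 + k,
                     id = paste0("analog", k)))
  set.seed(50)
  lad <- fragmentLadder(fx_candidates[[1]])$mz
  decoys <- lapply(1:20, function(d)
    delftiMS:::.decoy_spectrum(cfg, lad, paste0("decoy", d), "s"))
  net <- buildNetwork(c(analogs, decoys))
  fams <- networkFamilies(net)
  analogFam <- Filter(function(f) any(startsWith(f, "analog")), fams)
  expect_equal(length(analogFam), 1L)
  expect_setequal(analogFam[[1]], paste0("analog", 1:4))

  # singleton input: no edges, no families
  net1 <- buildNetwork(analogs[1])
  expect_equal(nrow(networkEdges(net1)), 0L)
  expect_equal(length(networkFamilies(net1)), 0L)

  # impossible threshold: empty edge set
  net2 <- buildNetwork(analogs, cosineThreshold = 1.01)
  expect_equal(nrow(networkEdges(net2)), 0L)
})

test_that("edge set is monotone in threshold and matched-count floor", {
  cfg <- simulationConfig()
  spectra <- c(
    lapply(seq_along(fx_candidates), function(k)
      simulateSpectrum(fx_candidates[[k]], cfg, seed = 60 + k,
                       id = paste0("a", k))))
  nEdges <- function(th, mm) nrow(networkEdges(
    buildNetwork(spectra, cosineThreshold = th, minMatched = mm)))
  expect_gte(nEdges(0.3, 2), nEdges(0.55, 2))
  expect_gte(nEdges(0.55, 2), nEdges(0.9, 2))
  expect_gte(nEdges(0.55, 2), nEdges(0.55, 6))
  expect_gte(nEdges(0.55, 6), nEdges(0.55, 12))
})

test_that("family membership is invariant to spectrum order", {
  cfg <- simulationConfig()
  spectra <- lapply(seq_along(fx_candidates), function(k)
    simulateSpectrum(fx_candidates[[k]], cfg, seed = 70 + k,
                     id = paste0("a", k)))
  set.seed(71)
  extra <- lapply(1:6, function(d)
    delftiMS:::.decoy_spectrum(cfg, fragmentLadder(fx_candidates[[1]])$mz,
                               paste0("d", d), "s"))
  all <- c(spectra, extra)
  f1 <- lapply(networkFamilies(buildNetwork(all)), sort)
  f2 <- lapply(networkFamilies(buildNetwork(rev(all))), sort)
  expect_setequal(
    vapply(f1, paste, character(1), collapse = "|"),
    vapply(f2, paste, character(1), collapse = "|"))
})
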