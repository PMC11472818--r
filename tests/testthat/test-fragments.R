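# brute-force oracle: fragment m/z from residue-formula prefixes/suffixes,
# computed directly with ElementalFormula arithmetic (independent of the
# cumulative-sum path inside fragmentLadder)
oracle_ladder <- function(candidate) {
  sc <- candidate@scaffold
  n <- scaffoldLength(sc)
  p <- massConstants()$proton
  acyl <- if (is.null(candidateTail(candidate))) NULL else
    acylFormula(candidateTail(candidate))
  prefixMass <- function(i) {
    f <- Reduce(combineFormulas, sc@residueFormulas[1:i])
    if (!is.null(acyl) && i >= sc@acylationSite)
      f <- combineFormulas(f, acyl)
    monoisotopicMass(f)
  }
  M <- monoisotopicMass(neutralFormula(candidate))
  b <- vapply(1:(n - 1), function(i) prefixMass(i) + p, numeric(1))
  y <- vapply(1:(n - 1), function(j) M + 2 * p - b[n - j], numeric(1))
  list(b = b, y = y)
}

test_that("ladder m/z equals the brute-force formula-arithmetic oracle", {
  for (cand in c(fx_candidates, list(parent = fx_parent))) {
    lad <- fragmentLadder(cand)
    orc <- oracle_ladder(cand)
    expect_equal(lad$mz[lad$series == "b"][order(lad$index[lad$series == "b"])],
                 orc$b, tolerance = 1e-9)
    expect_equal(lad$mz[lad$series == "y"][order(lad$index[lad$series == "y"])],
                 orc$y, tolerance = 1e-9)
  }
})

test_that("parent y-ions reproduce the shared backbone fragments", {
  lad <- fragmentLadder(fx_parent)
  y <- lad$mz[lad$series == "y"][order(lad$index[lad$series == "y"])]
  expect_equal(y[8], 904.4119, tolerance = 1e-3)
  expect_equal(y[7], 773.3900, tolerance = 1e-3)
  expect_equal(y[6], 672.3424, tolerance = 1e-3)
  expect_equal(y[5], 615.3209, tolerance = 1e-3)
  expect_equal(y[4], 532.2838, tolerance = 1e-3)
  # y3 computes to 374.2146; the reported 374.2152 sits 1.5 ppm above it
  expect_equal(y[3], 374.2146, tolerance = 1e-3)
})

test_that("consecutive y differences equal residue masses", {
  lad <- fragmentLadder(fx_parent)
  y <- lad$mz[lad$series == "y"][order(lad$index[lad$series == "y"])]
  expect_equal(y[8] - y[7], 131.0219, tolerance = 5e-4)  # beta-OH-Asp
  expect_equal(y[7] - y[6], 101.0477, tolerance = 5e-4)  # Thr
  expect_equal(y[6] - y[5], 57.0215, tolerance = 5e-4)   # Gly
  expect_equal(y[5] - y[4], 83.0371, tolerance = 5e-4)   # Dhb
  expect_equal(y[4] - y[3], 158.0691, tolerance = 5e-4)  # fOH-Orn
})

test_that("b/y complementarity holds at every cleavage", {
  for (cand in c(fx_candidates, list(parent = fx_parent))) {
    lad <- fragmentLadder(cand)
    p <- massConstants()$proton
    mh <- monoisotopicMass(neutralFormula(cand)) + p
    for (i in 1:8) {
      b <- lad$mz[lad$series == "b" & lad$index == i]
      y <- lad$mz[lad$series == "y" & lad$index == 9 - i]
      expect_equal(b + y, mh + p, tolerance = 1e-9)
    }
  }
})

test_that("y-ions are tail-invariant and b-ions shift by the acyl mass", {
  ladP <- fragmentLadder(fx_parent)
  yP <- ladP$mz[ladP$series == "y"]
  for (lbl in names(fx_candidates)) {
    lad <- fragmentLadder(fx_candidates[[lbl]])
    expect_equal(lad$mz[lad$series == "y"], yP, tolerance = 1e-6)
    expect_false(any(lad$containsTail[lad$series == "y"]))
    acyl <- monoisotopicMass(acylFormula(fx_tails[[lbl]]))
    expect_equal(lad$mz[lad$series == "b"],
                 ladP$mz[ladP$series == "b"] + acyl, tolerance = 1e-9)
    expect_true(all(lad$containsTail[lad$series == "b"]))
  }
})

test_that("peak matching is greedy, tolerance-bounded, and one-to-one", {
  lad <- fragmentLadder(fx_parent)
  y8 <- lad$mz[lad$series == "y" & lad$index == 8]
  sp <- fx_spectrum("m", 1033.49, c(374.2152, y8))
  m <- matchPeaks(sp, lad, tolPpm = 10)
  expect_equal(nrow(m), 2L)
  expect_equal(m$ppm[m$observedMz == y8], 0, tolerance = 0.01)
  # a peak 0.02 Da off at m/z 900 is ~22 ppm away: no match
  sp2 <- fx_spectrum("m2", 1033.49, 904.4119 + 0.02)
  expect_equal(nrow(matchPeaks(sp2, lad, tolPpm = 10)), 0L)
  # empty spectrum: no matches
  sp3 <- spectrum("e", 500, matrix(numeric(0), ncol = 2))
  expect_equal(nrow(matchPeaks(sp3, lad, tolPpm = 10)), 0L)
  # two theoretical fragments cannot claim one observed peak
  dup <- lad[rep(which(lad$series == "y" & lad$index == 8), 2), ]
  m4 <- matchPeaks(fx_spectrum("m4", 1033.49, y8), dup, tolPpm = 10)
  expect_equal(nrow(m4), 1L)
})

test_that("annotation recovers planted tails and rejects random spectra", {
  cfg <- simulationConfig()
  sp <- simulateSpectrum(fx_candidates[["C14:1"]], cfg, seed = 5)
  ann <- annotateAnalog(sp, fx_scaffold)
  expect_equal(ann$verdict, "annotated")
  expect_equal(ann$tailLabel, "C14:1")
  expect_gte(ann$backboneCoverage, 0.5)
  expect_gte(ann$tailEvidenceCount, 1L)

  sp3 <- simulateSpectrum(fx_candidates[["C12:1"]], cfg, seed = 6)
  ann3 <- annotateAnalog(sp3, fx_scaffold)
  expect_equal(ann3$tailLabel, "C12:1")

  # unrelated random peak list: unannotated
  set.seed(8)
  rnd <- fx_spectrum("rnd", 987.654, sort(runif(30, 100, 980)))
  expect_equal(annotateAnalog(rnd, fx_scaffold)$verdict, "unannotated")
})

test_that("annotation report writes summary and fragment rows", {
  cfg <- simulationConfig()
  sp <- simulateSpectrum(fx_candidates[["C14:0"]], cfg, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAnnotationReport(list(annotateAnalog(sp, fx_scaffold)), path)
  lines <- readLines(path)
  expect_true(any(startsWith(lines, "#")))
  expect_true(any(grepl("C14:0", lines)))
  expect_true(any(lines == "## fragments"))
})
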