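test_that("formula parsing handles counts, duplicates, and errors", {
  f <- parseFormula("C54H92N14O19")
  expect_equal(formulaCounts(f), c(C = 54L, H = 92L, N = 14L, O = 19L))
  expect_equal(formulaCounts(parseFormula("H2O")), c(H = 2L, O = 1L))
  expect_equal(formulaString(parseFormula("")), "")
  expect_equal(monoisotopicMass(parseFormula("")), 0)
  # repeated symbols accumulate
  expect_equal(formulaCounts(parseFormula("CH3CH3")), c(C = 2L, H = 6L))
  expect_error(parseFormula("C2Xx4"), "unsupported element")
  expect_error(parseFormula("C54h92"), "malformed|unsupported")
})

test_that("serialisation round trips counts exactly", {
  for (s in c("C54H92N14O19", "H2O", "C40H68N14O18", "FeC10", "CuH2O", "")) {
    f <- parseFormula(s)
    expect_identical(formulaCounts(parseFormula(formulaString(f))),
                     formulaCounts(f))
  }
})

test_that("formula combination is elementwise and guards negatives", {
  a <- parseFormula("C40H68N14O18")
  b <- parseFormula("C14H24O")
  expect_equal(formulaString(combineFormulas(a, b)), "C54H92N14O19")
  expect_equal(formulaString(combineFormulas(parseFormula("Fe"),
                                             emptyFormula())), "Fe")
  expect_equal(formulaString(combineFormulas(parseFormula("C2H6O"),
                                             parseFormula("C2H6O"), -1L)), "")
  expect_error(combineFormulas(b, a, -1L), "negative")
})

test_that("monoisotopic masses match independently computed values", {
  # frozen from atomic-mass table sums (cross-checked against pyteomics)
  expect_equal(monoisotopicMass(parseFormula("H2O")), 18.010565,
               tolerance = 1e-6)
  expect_equal(monoisotopicMass(parseFormula("C40H68N14O18")), 1032.4836,
               tolerance = 5e-4)
  # additivity property over random formula pairs
  set.seed(11)
  els <- c("C", "H", "N", "O", "S", "P")
  for (i in 1:25) {
    a <- elementalFormula(setNames(sample(0:30, 6, TRUE), els))
    b <- elementalFormula(setNames(sample(0:30, 6, TRUE), els))
    expect_equal(monoisotopicMass(combineFormulas(a, b)),
                 monoisotopicMass(a) + monoisotopicMass(b),
                 tolerance = 1e-9)
  }
})

test_that("mass constants table is internally consistent", {
  k <- massConstants()
  expect_equal(k$proton, k$elements[["H"]] - k$electron, tolerance = 1e-12)
  expect_identical(k$elements[["Fe"]], k$isotopes[["Fe56"]])
  expect_identical(k$elements[["Cu"]], k$isotopes[["Cu63"]])
})

test_that("ion m/z reproduces high-resolution calculated values", {
  expect_equal(ionMz(parseFormula("C54H92N14O19"), "[M+H]+"), 1241.6736,
               tolerance = 5e-4)
  expect_equal(ionMz(parseFormula("C54H92N14O19"), "[M-2H+Fe]+"), 1294.5851,
               tolerance = 5e-4)
  expect_equal(ionMz(parseFormula("C52H88N14O19"), "[M+H]+"), 1213.6423,
               tolerance = 5e-4)
  # unicode minus is normalised
  expect_equal(ionMz(parseFormula("C54H92N14O19"), "[M−2H+Fe]+"),
               1294.5851, tolerance = 5e-4)
  # doubly protonated: (M + 2 H_atom - 2 e) / 2
  f <- parseFormula("C54H92N14O19")
  expect_equal(ionMz(f, "[M+2H]2+"),
               (monoisotopicMass(f) + 2 * massConstants()$proton) / 2,
               tolerance = 1e-9)
  expect_error(ionMz(parseFormula("C2"), "[M-2H+Fe]+"), "removes")
  expect_error(ionMz(f, "[M+Xyz]+"), "unknown adduct")
})

test_that("Fe-adduct shift from [M+H]+ is formula-independent", {
  set.seed(7)
  for (i in 1:10) {
    f <- elementalFormula(c(C = sample(10:60, 1), H = sample(20:90, 1),
                            N = sample(0:10, 1), O = sample(0:20, 1)))
    shift <- ionMz(f, "[M-2H+Fe]+") - ionMz(f, "[M+H]+")
    expect_equal(shift, 52.9115, tolerance = 5e-4)
  }
})

test_that("ppm error is signed and reproduces reported errors", {
  expect_equal(round(ppmError(1241.6730, 1241.6736), 1), -0.5)
  expect_equal(round(ppmError(1213.6414, 1213.6423), 1), -0.7)
  expect_equal(ppmError(500, 500), 0)
  expect_error(ppmError(1, 0))
})

test_that("RDBE follows the standard valence formula and is additive", {
  expect_equal(rdbe(parseFormula("C54H92N14O19")), 16)
  expect_equal(rdbe(parseFormula("CH4")), 0)
  expect_equal(rdbe(parseFormula("C6H6")), 4)
  set.seed(3)
  for (i in 1:20) {
    a <- elementalFormula(c(C = sample(1:30, 1), H = sample(2:40, 1),
                            N = sample(0:8, 1), O = sample(0:10, 1)))
    b <- elementalFormula(c(C = sample(1:30, 1), H = sample(2:40, 1),
                            N = sample(0:8, 1), O = sample(0:10, 1)))
    expect_equal(rdbe(combineFormulas(a, b)), rdbe(a) + rdbe(b) - 1)
  }
})

test_that("adduct registry loads and validates", {
  reg <- adductRegistry()
  expect_true(all(c("[M+H]+", "[M-2H+Fe]+", "[M-H+Cu]+", "[M-2H+Au]+")
                  %in% names(reg)))
  mh <- getAdduct("[M+H]+")
  expect_s4_class(mh, "AdductSpec")
  expect_equal(mh@charge, 1L)
  expect_equal(formulaString(mh@atomsAdded), "H")
})
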