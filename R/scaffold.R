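# residue compositions (amino acid minus water) of the delftibactin core,
# N-terminus first; the macrolactam closure cancels the terminal water so the
# residue formulas sum exactly to the neutral parent formula C40H68N14O18.
.delftibactin_residues <- data.frame(
  name = c("Ahmpa", "bOH-Asp", "Thr", "Gly", "Dhb",
           "fOH-Orn", "Ser", "Arg", "cyclo-OH-Orn"),
  formula = c("C6H11NO2", "C4H5NO4", "C4H7NO2", "C2H3NO", "C4H5NO",
              "C6H10N2O3", "C3H5NO2", "C6H12N4O", "C5H10N2O2"),
  stringsAsFactors = FALSE
)

#' Construct a Scaffold
#'
#' Builds and validates a peptide scaffold from a residue table. When
#' `expectedTotal` is given, construction fails unless the residue formulas
#' sum exactly to it (elementwise) — the guard that catches typos in residue
#' compositions.
#'
#' @param residues data.frame with columns `name` and `formula`, N-terminus
#'   first.
#' @param acylationSite Index of the residue bearing the acyl tail.
#' @param referenceMH Reference \[M+H\]+ of the unacylated parent (Da), used
#'   as the minuend in mass-difference tail inference.
#' @param expectedTotal Optional [ElementalFormula] (or Hill string) the
#'   residue sum must equal.
#' @return A [Scaffold].
#' @export
scaffold <- function(residues, acylationSite = 1L, referenceMH,
                     expectedTotal = NULL) {
  forms <- lapply(residues$formula, parseFormula)
  if (!is.null(expectedTotal)) {
    if (is.character(expectedTotal)) expectedTotal <- parseFormula(expectedTotal)
    tot <- Reduce(combineFormulas, forms)
    if (formulaString(tot) != formulaString(expectedTotal))
      stop("residue formulas sum to ", formulaString(tot),
           ", expected ", formulaString(expectedTotal))
  }
  new("Scaffold", residues = residues, residueFormulas = forms,
      acylationSite = as.integer(acylationSite),
      referenceMH = as.numeric(referenceMH))
}

#' The built-in delftibactin scaffold
#'
#' Nine residues, N to C: Ahmpa (4-amino-3-hydroxy-2-methylpentanoic acid,
#' the tail-bearing residue), beta-OH-Asp, Thr, Gly, Dhb, fOH-Orn, Ser, Arg,
#' and C-terminal cyclic N-OH-Orn (the hydroxamate macrolactam). The residue
#' formulas are fixed data validated at construction against the neutral
#' parent formula C40H68N14O18.
#'
#' The reference \[M+H\]+ defaults to the literature constant 1033.4914 Da so
#' that precursor-mass residuals reproduce published difference arithmetic
#' bit-for-bit. `useComputedReference = TRUE` switches to the self-computed
#' proton-corrected value (1033.4909) for internally consistent pipelines;
#' the two differ by roughly the electron mass.
#'
#' @param useComputedReference Use the package-computed \[M+H\]+ instead of
#'   the literature constant.
#' @return A [Scaffold].
#' @examples
#' sc <- buildDelftibactinScaffold()
#' formulaString(scaffoldFormula(sc)) # "C40H68N14O18"
#' @export
buildDelftibactinScaffold <- function(useComputedReference = FALSE) {
  sc <- scaffold(.delftibactin_residues, acylationSite = 1L,
                 referenceMH = 1033.4914,
                 expectedTotal = "C40H68N14O18")
  if (useComputedReference)
    sc@referenceMH <- ionMz(scaffoldFormula(sc), "[M+H]+")
  sc
}

#' Total neutral formula of a scaffold
#'
#' Elementwise sum of the residue formulas. For a macrolactam scaffold this
#' is the neutral parent formula directly (no terminal water).
#'
#' @param sc A [Scaffold].
#' @return An [ElementalFormula].
#' @export
scaffoldFormula <- function(sc) Reduce(combineFormulas, sc@residueFormulas)

#' @describeIn scaffoldFormula Number of residues.
#' @export
scaffoldLength <- function(sc) nrow(sc@residues)

#' Reference \[M+H\]+ of the unacylated parent
#' @param sc A [Scaffold].
#' @return m/z in Da.
#' @export
referenceMH <- function(sc) sc@referenceMH

setMethod("show", "Scaffold", function(object) {
  cat("Scaffold with", nrow(object@residues), "residues (N->C):",
      paste(object@residues$name, collapse = "-"), "\n")
  cat("  total formula:", formulaString(scaffoldFormula(object)),
      " acylation site:", object@residues$name[object@acylationSite],
      " reference [M+H]+:", format(object@referenceMH, nsmall = 4), "\n")
})

#' Construct a LipidTail
#'
#' @param nCarbons Chain length (>= 2).
#' @param nDoubleBonds Number of C=C double bonds (>= 0).
#' @return A [LipidTail].
#' @examples
#' lipidTail(14, 1) # C14:1
#' @export
lipidTail <- function(nCarbons, nDoubleBonds = 0L)
  new("LipidTail", nCarbons = as.integer(nCarbons),
      nDoubleBonds = as.integer(nDoubleBonds))

#' Shorthand Cn:d label of a tail
#' @param tail A [LipidTail] or `NULL`.
#' @return A string like `"C14:1"`, or `"none"` for `NULL`.
#' @export
tailLabel <- function(tail) {
  if (is.null(tail)) return("none")
  paste0("C", tail@nCarbons, ":", tail@nDoubleBonds)
}

setMethod("show", "LipidTail", function(object) {
  cat("LipidTail ", tailLabel(object), " (",
      formulaString(acylFormula(object)), ")\n", sep = "")
})

#' Acyl (fatty acid minus water) formula of a lipid tail
#'
#' A Cn:d fatty acid attached as an amide contributes C(n)H(2n-2-2d)O.
#'
#' @param tail A [LipidTail].
#' @return An [ElementalFormula].
#' @examples
#' formulaString(acylFormula(lipidTail(14, 1))) # "C14H24O"
#' @export
acylFormula <- function(tail) {
  h <- 2L * tail@nCarbons - 2L - 2L * tail@nDoubleBonds
  if (h <= 0L) stop("impossible hydrogen count for ", tailLabel(tail))
  elementalFormula(c(C = tail@nCarbons, H = h, O = 1L))
}

#' Build an analog candidate from a scaffold and tail
#'
#' The neutral formula is the residue sum plus the acyl formula (when a tail
#' is present); the theoretical \[M+H\]+ is computed with electron-mass
#' correction.
#'
#' @param sc A [Scaffold].
#' @param tail A [LipidTail] or `NULL` for the unacylated parent.
#' @return An [AnalogCandidate].
#' @examples
#' cand <- analogFormula(buildDelftibactinScaffold(), lipidTail(14, 1))
#' formulaString(neutralFormula(cand)) # "C54H92N14O19"
#' round(mhTheoretical(cand), 4)      # 1241.6736
#' @export
analogFormula <- function(sc, tail = NULL) {
  neutral <- scaffoldFormula(sc)
  if (!is.null(tail)) neutral <- combineFormulas(neutral, acylFormula(tail))
  new("AnalogCandidate", scaffold = sc, tail = tail,
      neutralFormula = neutral, mhTheoretical = ionMz(neutral, "[M+H]+"))
}

#' Accessors for AnalogCandidate
#' @param x An [AnalogCandidate].
#' @return `neutralFormula`: the [ElementalFormula]; `mhTheoretical`: the
#'   theoretical \[M+H\]+ m/z; `candidateTail`: the [LipidTail] or `NULL`.
#' @export
neutralFormula <- function(x) x@neutralFormula

#' @rdname neutralFormula
#' @export
mhTheoretical <- function(x) x@mhTheoretical

#' @rdname neutralFormula
#' @export
candidateTail <- function(x) x@tail

setMethod("show", "AnalogCandidate", function(object) {
  cat("AnalogCandidate: tail ", tailLabel(object@tail), ", neutral ",
      formulaString(object@neutralFormula), ", [M+H]+ ",
      format(round(object@mhTheoretical, 4), nsmall = 4), "\n", sep = "")
})

#' Infer the lipid tail from an observed precursor mass
#'
#' Implements mass-difference dereplication: the residual mass is the
#' observed precursor \[M+H\]+ minus the scaffold's reference \[M+H\]+, and
#' each Cn:d acyl hypothesis in the search grid is scored by its ppm
#' deviation from that residual (ppm on the precursor scale). Candidates
#' within `tolPpm` are ranked by absolute ppm; ties prefer fewer double
#' bonds, then fewer carbons.
#'
#' @param observedPrecursor Observed precursor m/z (\[M+H\]+, charge 1).
#' @param sc A [Scaffold].
#' @param tolPpm Match tolerance in ppm of the observed precursor.
#' @param carbonRange Integer range of chain lengths searched.
#' @param doubleBondRange Integer range of double-bond counts searched.
#' @return data.frame with columns `nCarbons`, `nDoubleBonds`, `tail`,
#'   `acylMass`, `residualMass`, `ppm`, best hypothesis first; zero rows when
#'   nothing matches (including precursors at or below the reference mass).
#' @examples
#' inferTail(1241.6730, buildDelftibactinScaffold())[1, ] # C14:1
#' @export
inferTail <- function(observedPrecursor, sc, tolPpm = 10,
                      carbonRange = 8:20, doubleBondRange = 0:3) {
  empty <- data.frame(nCarbons = integer(0), nDoubleBonds = integer(0),
                      tail = character(0), acylMass = numeric(0),
                      residualMass = numeric(0), ppm = numeric(0))
  residual <- observedPrecursor - sc@referenceMH
  if (residual <= 0) return(empty)
  grid <- expand.grid(nCarbons = carbonRange, nDoubleBonds = doubleBondRange)
  grid <- grid[2L * grid$nCarbons - 2L - 2L * grid$nDoubleBonds > 0L, ]
  acylMass <- vapply(seq_len(nrow(grid)), function(i)
    monoisotopicMass(acylFormula(lipidTail(grid$nCarbons[i],
                                           grid$nDoubleBonds[i]))),
    numeric(1))
  ppm <- (residual - acylMass) / observedPrecursor * 1e6
  keep <- abs(ppm) <= tolPpm
  if (!any(keep)) return(empty)
  out <- data.frame(
    nCarbons = grid$nCarbons[keep], nDoubleBonds = grid$nDoubleBonds[keep],
    tail = paste0("C", grid$nCarbons[keep], ":", grid$nDoubleBonds[keep]),
    acylMass = acylMass[keep], residualMass = residual, ppm = ppm[keep])
  out <- out[order(abs(out$ppm), out$nDoubleBonds, out$nCarbons), ]
  rownames(out) <- NULL
  out
}
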