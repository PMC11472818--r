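#' @import methods
NULL

#' ElementalFormula: integer element counts
#'
#' The unit of all mass arithmetic in the package. Counts are a named integer
#' vector over the supported element set (see [massConstants()]); all counts
#' are non-negative and zero-count elements are dropped.
#'
#' @slot counts Named integer vector of element counts.
#' @seealso [parseFormula()], [monoisotopicMass()], [combineFormulas()]
#' @export
setClass("ElementalFormula", representation(counts = "integer"))

setValidity("ElementalFormula", function(object) {
  cnt <- object@counts
  supported <- names(massConstants()$elements)
  if (length(cnt) && is.null(names(cnt)))
    return("counts must be named by element symbol")
  bad <- setdiff(names(cnt), supported)
  if (length(bad))
    return(paste0("unsupported element(s): ", paste(bad, collapse = ", ")))
  if (any(cnt < 0)) return("element counts must be non-negative")
  if (anyDuplicated(names(cnt))) return("duplicated element symbols")
  TRUE
})

#' AdductSpec: an ionisation hypothesis
#'
#' Describes how a neutral molecule M becomes an observed ion: atoms added,
#' hydrogens removed, and the resulting positive charge. E.g. the protonated
#' ion \[M+H\]+ adds one H; the ferric complex \[M-2H+Fe\]+ adds Fe and
#' removes two hydrogens.
#'
#' @slot name Display name, e.g. `"[M+H]+"`.
#' @slot atomsAdded [ElementalFormula] of atoms added to the neutral.
#' @slot hydrogensRemoved Non-negative integer count of hydrogens removed.
#' @slot charge Positive integer charge of the resulting cation.
#' @seealso [adductRegistry()], [ionMz()]
#' @export
setClass("AdductSpec", representation(
  name = "character", atomsAdded = "ElementalFormula",
  hydrogensRemoved = "integer", charge = "integer"
))

setValidity("AdductSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name)) return("name required")
  if (object@hydrogensRemoved < 0L) return("hydrogensRemoved must be >= 0")
  if (object@charge < 1L) return("charge must be a positive integer")
  TRUE
})

#' LipidTail: an acyl chain hypothesis
#'
#' A fatty-acyl tail with `nCarbons` carbons and `nDoubleBonds` C=C double
#' bonds, attached to the scaffold as an amide (fatty acid minus water), i.e.
#' formula C(n)H(2n-2-2d)O.
#'
#' @slot nCarbons Integer >= 2.
#' @slot nDoubleBonds Integer >= 0.
#' @seealso [acylFormula()], [inferTail()]
#' @export
setClass("LipidTail", representation(nCarbons = "integer", nDoubleBonds = "integer"))

setValidity("LipidTail", function(object) {
  if (object@nCarbons < 2L) return("nCarbons must be >= 2")
  if (object@nDoubleBonds < 0L) return("nDoubleBonds must be >= 0")
  if (2L * object@nCarbons - 2L - 2L * object@nDoubleBonds <= 0L)
    return("impossible hydrogen count for this carbon/double-bond combination")
  TRUE
})

setClassUnion("LipidTailOrNULL", c("LipidTail", "NULL"))

#' Scaffold: the peptide core of a lipopeptide analog series
#'
#' An ordered residue list (N-terminus first), the index of the residue whose
#' terminal amine carries the acyl tail, and the reference \[M+H\]+ of the
#' unacylated parent used for mass-difference tail inference.
#'
#' The built-in delftibactin scaffold (see [buildDelftibactinScaffold()]) is a
#' nine-residue macrolactam: the residue formulas sum to the neutral parent
#' formula with no terminal water.
#'
#' @slot residues data.frame with columns `name` and `formula` (Hill strings),
#'   one row per residue, N-terminus first.
#' @slot residueFormulas List of [ElementalFormula], parallel to `residues`.
#' @slot acylationSite Integer index of the tail-bearing residue.
#' @slot referenceMH Reference \[M+H\]+ (Da) of the unacylated parent.
#' @export
setClass("Scaffold", representation(
  residues = "data.frame", residueFormulas = "list",
  acylationSite = "integer", referenceMH = "numeric"
))

setValidity("Scaffold", function(object) {
  n <- nrow(object@residues)
  if (n < 2L) return("scaffold needs at least two residues")
  if (!all(c("name", "formula") %in% names(object@residues)))
    return("residues needs 'name' and 'formula' columns")
  if (anyDuplicated(object@residues$name)) return("residue names must be unique")
  if (length(object@residueFormulas) != n)
    return("residueFormulas must parallel residues")
  if (object@acylationSite < 1L || object@acylationSite > n)
    return("acylationSite out of range")
  if (length(object@referenceMH) != 1L || object@referenceMH <= 0)
    return("referenceMH must be a single positive m/z")
  for (f in object@residueFormulas)
    if (monoisotopicMass(f) <= 0) return("residue mass must be > 0")
  TRUE
})

#' AnalogCandidate: scaffold plus optional tail
#'
#' A structural hypothesis for one analog: the scaffold, an optional
#' [LipidTail], the resulting neutral formula and its theoretical \[M+H\]+.
#'
#' @slot scaffold A [Scaffold].
#' @slot tail A [LipidTail] or `NULL` for the unacylated parent.
#' @slot neutralFormula [ElementalFormula] of the neutral analog.
#' @slot mhTheoretical Theoretical \[M+H\]+ m/z.
#' @seealso [analogFormula()], [fragmentLadder()]
#' @export
setClass("AnalogCandidate", representation(
  scaffold = "Scaffold", tail = "LipidTailOrNULL",
  neutralFormula = "ElementalFormula", mhTheoretical = "numeric"
))

#' Spectrum: one MS/MS scan
#'
#' @slot id Spectrum identifier.
#' @slot precursorMz Precursor m/z.
#' @slot charge Integer precursor charge.
#' @slot retentionTime Retention time in seconds.
#' @slot sampleId Identifier of the run the spectrum came from.
#' @slot peaks Two-column numeric matrix (`mz`, `intensity`), sorted by m/z.
#' @export
setClass("Spectrum", representation(
  id = "character", precursorMz = "numeric", charge = "integer",
  retentionTime = "numeric", sampleId = "character", peaks = "matrix"
))

setValidity("Spectrum", function(object) {
  p <- object@peaks
  if (ncol(p) != 2L) return("peaks must have two columns (mz, intensity)")
  if (nrow(p)) {
    if (any(!is.finite(p))) return("peak values must be finite")
    if (any(p[, 2L] < 0)) return("intensities must be non-negative")
    if (is.unsorted(p[, 1L])) return("peaks must be sorted ascending by m/z")
  }
  if (length(object@precursorMz) != 1L || !is.finite(object@precursorMz))
    return("precursorMz must be a single finite number")
  TRUE
})

#' MolecularNetwork: modified-cosine edges over spectra
#'
#' @slot nodes data.frame: `id`, `precursorMz`, `sampleId`, `family`
#'   (integer family index or NA for singletons not in a family).
#' @slot edges data.frame: `idA`, `idB`, `cosine`, `nMatched`.
#' @slot families List of character vectors of node ids (components with
#'   at least `minClusterSize` members).
#' @slot params List of the parameters the network was built with.
#' @seealso [buildNetwork()]
#' @export
setClass("MolecularNetwork", representation(
  nodes = "data.frame", edges = "data.frame",
  families = "list", params = "list"
))

setValidity("MolecularNetwork", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$idA == e$idB)) return("self-edges are not allowed")
    if (any(e$cosine < object@params$cosineThreshold - 1e-12))
      return("edge below cosine threshold")
    if (any(e$nMatched < object@params$minMatched))
      return("edge below minimum matched-peak count")
  }
  TRUE
})

#' FeatureTable: per-feature intensities across samples
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] with one `intensity`
#' assay (features x samples), rowData columns `precursorMz` and
#' `retentionTime`, and a colData column `condition` mapping each sample to
#' its culture condition.
#'
#' @seealso [featureTable()], [labelConditions()], [differentialFeatures()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("needs an 'intensity' assay")
  if (any(SummarizedExperiment::assay(object, "intensity") < 0, na.rm = TRUE))
    return("intensities must be non-negative")
  if (!"condition" %in% names(SummarizedExperiment::colData(object)))
    return("colData needs a 'condition' column")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("precursorMz", "retentionTime") %in% names(rd)))
    return("rowData needs 'precursorMz' and 'retentionTime'")
  TRUE
})

#' MetalOutcome: verdict of a metal-treatment screen
#'
#' @slot compoundId Compound identifier.
#' @slot metal Element symbol of the metal tested.
#' @slot apoRetained Logical: is the apo \[M+H\]+ still present after
#'   treatment?
#' @slot holoDetected data.frame of detected holo hypotheses: `adduct`,
#'   `theoreticalMz`, `observedMz`, `ppm`.
#' @slot unassignedNewIons Numeric vector of new post-treatment m/z values
#'   matching neither apo nor any holo hypothesis.
#' @slot verdict One of `"stable-complex"`, `"degradation/unassigned"`,
#'   `"no-reaction"`.
#' @seealso [screenMetalReaction()]
#' @export
setClass("MetalOutcome", representation(
  compoundId = "character", metal = "character", apoRetained = "logical",
  holoDetected = "data.frame", unassignedNewIons = "numeric",
  verdict = "character"
))

setValidity("MetalOutcome", function(object) {
  v <- object@verdict
  if (!v %in% c("stable-complex", "degradation/unassigned", "no-reaction"))
    return("unknown verdict")
  ok <- switch(v,
    "stable-complex" = !object@apoRetained && nrow(object@holoDetected) > 0L,
    "degradation/unassigned" = !object@apoRetained &&
      nrow(object@holoDetected) == 0L,
    "no-reaction" = object@apoRetained
  )
  if (!ok) return("verdict inconsistent with evidence slots")
  TRUE
})

#' SimulationConfig: parameters of the synthetic LC-MS/MS generator
#'
#' Defaults emulate the study design the pipeline targets: four planted acyl
#' analogs (C14:1, C14:0, C12:1, C12:0) present only under iron limitation,
#' duplicate cultures per condition, 2 ppm m/z jitter, log-normal intensities
#' with planted fragments ~50x the decoy median, and random decoy spectra.
#'
#' @slot scaffold The [Scaffold] analogs are planted on.
#' @slot plantedTails List of [LipidTail] hypotheses planted in low-iron runs.
#' @slot conditions Named integer vector: replicates per condition.
#' @slot mzNoiseSigmaPpm Gaussian m/z jitter, ppm (multiplicative).
#' @slot intensityMeanlog,intensitySdlog Log-normal parameters for planted
#'   fragment intensities.
#' @slot decoyIntensityMeanlog Log-normal meanlog for decoy peaks (same sdlog).
#' @slot nDecoySpectra Number of unrelated decoy spectra per sample.
#' @slot nDecoyPeaks Decoy/noise peaks added per spectrum.
#' @slot nBackgroundFeatures Features shared across both conditions.
#' @slot dropoutProb Per-fragment dropout probability.
#' @export
setClass("SimulationConfig", representation(
  scaffold = "Scaffold", plantedTails = "list", conditions = "integer",
  mzNoiseSigmaPpm = "numeric", intensityMeanlog = "numeric",
  intensitySdlog = "numeric", decoyIntensityMeanlog = "numeric",
  nDecoySpectra = "integer", nDecoyPeaks = "integer",
  nBackgroundFeatures = "integer", dropoutProb = "numeric"
))

setValidity("SimulationConfig", function(object) {
  if (length(object@conditions) < 1L || any(object@conditions < 1L))
    return("need at least one replicate per condition")
  if (is.null(names(object@conditions)))
    return("conditions must be named")
  if (object@mzNoiseSigmaPpm < 0) return("mzNoiseSigmaPpm must be >= 0")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    return("dropoutProb must be in [0,1]")
  for (t in object@plantedTails)
    if (!is(t, "LipidTail")) return("plantedTails must be LipidTail objects")
  TRUE
})
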