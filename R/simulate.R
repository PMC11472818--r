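#' Default synthetic-experiment configuration
#'
#' The defaults emulate the targeted study design: four acyl analogs
#' (C14:1, C14:0, C12:1, C12:0) planted only in iron-depleted runs, duplicate
#' cultures per condition, 2 ppm Gaussian m/z jitter, log-normal fragment
#' intensities whose median is ~50x the decoy-peak median, 20 unrelated decoy
#' spectra per sample and 30 decoy peaks per spectrum, and 5% fragment
#' dropout.
#'
#' @param scaffold [Scaffold] analogs are planted on.
#' @param plantedTails List of [LipidTail] objects to plant in low-iron runs.
#' @param conditions Named integer vector of replicates per condition; must
#'   contain `low_iron` and `high_iron`.
#' @param mzNoiseSigmaPpm Gaussian jitter sigma, ppm (multiplicative).
#' @param intensityMeanlog,intensitySdlog Log-normal intensity model for
#'   planted fragments.
#' @param decoyIntensityMeanlog Log-normal meanlog for decoy peaks
#'   (`log(50)` below the planted meanlog by default).
#' @param nDecoySpectra Unrelated decoy spectra per sample.
#' @param nDecoyPeaks Noise peaks per spectrum.
#' @param nBackgroundFeatures Background features present in both conditions.
#' @param dropoutProb Per-fragment dropout probability.
#' @return A [SimulationConfig].
#' @export
simulationConfig <- function(scaffold = buildDelftibactinScaffold(),
                             plantedTails = list(lipidTail(14, 1),
                                                 lipidTail(14, 0),
                                                 lipidTail(12, 1),
                                                 lipidTail(12, 0)),
                             conditions = c(low_iron = 2L, high_iron = 2L),
                             mzNoiseSigmaPpm = 2,
                             intensityMeanlog = log(5e4),
                             intensitySdlog = 0.6,
                             decoyIntensityMeanlog = log(1e3),
                             nDecoySpectra = 20L, nDecoyPeaks = 30L,
                             nBackgroundFeatures = 6L, dropoutProb = 0.05) {
  new("SimulationConfig", scaffold = scaffold, plantedTails = plantedTails,
      conditions = stats::setNames(as.integer(conditions), names(conditions)),
      mzNoiseSigmaPpm = mzNoiseSigmaPpm,
      intensityMeanlog = intensityMeanlog, intensitySdlog = intensitySdlog,
      decoyIntensityMeanlog = decoyIntensityMeanlog,
      nDecoySpectra = as.integer(nDecoySpectra),
      nDecoyPeaks = as.integer(nDecoyPeaks),
      nBackgroundFeatures = as.integer(nBackgroundFeatures),
      dropoutProb = dropoutProb)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@plantedTails), "planted tails (",
      paste(vapply(object@plantedTails, tailLabel, character(1)),
            collapse = ", "), "),",
      paste(names(object@conditions), object@conditions, sep = " x ",
            collapse = ", "), "\n")
  cat("  jitter", object@mzNoiseSigmaPpm, "ppm, dropout",
      object@dropoutProb, ",", object@nDecoySpectra, "decoy spectra,",
      object@nDecoyPeaks, "decoy peaks/spectrum\n")
})

# multiplicative ppm-scale Gaussian jitter
.jitter <- function(mz, sigmaPpm)
  mz * (1 + stats::rnorm(length(mz), 0, sigmaPpm * 1e-6))

# random decoy peak list in [100, maxMz]
.decoy_peaks <- function(n, maxMz, meanlog, sdlog)
  cbind(mz = stats::runif(n, 100, maxMz),
        intensity = stats::rlnorm(n, meanlog, sdlog))

#' Simulate one analog MS/MS spectrum
#'
#' Draws the candidate's theoretical b/y ladder with per-peak ppm-scale
#' Gaussian m/z jitter, log-normal intensities and independent dropout, adds
#' uniform-random decoy peaks, and jitters the precursor \[M+H\]+.
#'
#' @param candidate An [AnalogCandidate].
#' @param config A [SimulationConfig].
#' @param seed Integer seed; identical (candidate, config, seed) triples
#'   reproduce identical spectra.
#' @param id,sampleId Identifiers stamped on the spectrum.
#' @return A [Spectrum].
#' @export
simulateSpectrum <- function(candidate, config, seed, id = "sim",
                             sampleId = "simrun") {
  set.seed(seed)
  .simulate_spectrum_impl(candidate, config, id, sampleId)
}

# RNG-stream version used inside larger simulations (no set.seed here)
.simulate_spectrum_impl <- function(candidate, config, id, sampleId) {
  ladder <- fragmentLadder(candidate)
  keep <- stats::runif(nrow(ladder)) >= config@dropoutProb
  mz <- .jitter(ladder$mz[keep], config@mzNoiseSigmaPpm)
  int <- stats::rlnorm(sum(keep), config@intensityMeanlog,
                       config@intensitySdlog)
  prec <- .jitter(mhTheoretical(candidate), config@mzNoiseSigmaPpm)
  noise <- .decoy_peaks(config@nDecoyPeaks, prec,
                        config@decoyIntensityMeanlog, config@intensitySdlog)
  peaks <- rbind(cbind(mz = mz, intensity = int), noise)
  spectrum(id, prec, peaks, charge = 1L,
           retentionTime = stats::runif(1, 0, 23 * 60), sampleId = sampleId)
}

# decoy spectrum whose peak spacings avoid the scaffold ladder (rejection:
# resample while >= 3 pairwise spacings coincide with ladder spacings)
.decoy_spectrum <- function(config, ladderMz, id, sampleId) {
  ladderDiffs <- as.numeric(stats::dist(ladderMz))
  repeat {
    prec <- stats::runif(1, 300, 1500)
    pk <- .decoy_peaks(config@nDecoyPeaks, prec,
                       config@decoyIntensityMeanlog, config@intensitySdlog)
    d <- as.numeric(stats::dist(pk[, 1L]))
    shared <- sum(vapply(d, function(x)
      any(abs(x - ladderDiffs) <= 0.01), logical(1)))
    if (shared < 3L) break
  }
  spectrum(id, prec, pk, charge = 1L,
           retentionTime = stats::runif(1, 0, 23 * 60), sampleId = sampleId)
}

#' Simulate a full two-condition experiment
#'
#' Generates, per sample: one MS/MS spectrum per planted analog (low-iron
#' samples only), decoy spectra, and a feature table in which planted analog
#' features appear only in low-iron samples, background features appear in
#' every sample, and decoy features are assigned to random sample subsets
#' that always span both conditions (condition-exclusive chemical noise is
#' excluded by construction, so the planted analogs are the only true
#' differential signal).
#'
#' @param config A [SimulationConfig].
#' @param seed Integer seed.
#' @return List with elements `spectra` (list of [Spectrum]), `featureTable`
#'   (a [FeatureTable]), `sampleMetadata` (data.frame `sampleId`,
#'   `condition`), and `groundTruth` (list: `analogFeatures` with true tail
#'   per feature id, `decoyFeatureIds`, `backgroundFeatureIds`,
#'   `spectrumTruth` with true candidate per planted spectrum id).
#' @export
simulateExperiment <- function(config, seed) {
  set.seed(seed)
  sc <- config@scaffold
  conds <- rep(names(config@conditions), config@conditions)
  sampleIds <- paste0(conds, "_rep",
                      unlist(lapply(config@conditions, seq_len)))
  meta <- data.frame(sampleId = sampleIds, condition = conds,
                     stringsAsFactors = FALSE)
  candidates <- lapply(config@plantedTails, function(t) analogFormula(sc, t))
  ladderMz <- if (length(candidates))
    fragmentLadder(candidates[[1L]])$mz else numeric(0)

  spectra <- list()
  spectrumTruth <- list()
  for (s in seq_along(sampleIds)) {
    sid <- sampleIds[s]
    if (conds[s] == "low_iron") {
      for (k in seq_along(candidates)) {
        id <- paste0(sid, "_analog_", tailLabel(config@plantedTails[[k]]))
        spectra[[id]] <- .simulate_spectrum_impl(candidates[[k]], config,
                                                 id, sid)
        spectrumTruth[[id]] <- tailLabel(config@plantedTails[[k]])
      }
    }
    for (d in seq_len(config@nDecoySpectra)) {
      id <- paste0(sid, "_decoy", d)
      spectra[[id]] <- .decoy_spectrum(config, ladderMz, id, sid)
    }
  }

  # feature table: analogs (low-iron only), background (everywhere),
  # decoy features (random subsets spanning both conditions)
  nS <- length(sampleIds)
  lowIdx <- which(conds == "low_iron")
  analogIds <- if (length(config@plantedTails))
    paste0("analog_", vapply(config@plantedTails, tailLabel, character(1)))
    else character(0)
  nBg <- config@nBackgroundFeatures
  nDecoyFeat <- config@nDecoySpectra
  bgIds <- if (nBg) paste0("background", seq_len(nBg)) else character(0)
  decoyIds <- if (nDecoyFeat) paste0("decoyfeat", seq_len(nDecoyFeat)) else
    character(0)
  featIds <- c(analogIds, bgIds, decoyIds)
  m <- matrix(0, length(featIds), nS, dimnames = list(featIds, sampleIds))
  intensity <- function(n) stats::rlnorm(n, config@intensityMeanlog,
                                         config@intensitySdlog)
  for (k in seq_along(analogIds))
    m[analogIds[k], lowIdx] <- intensity(length(lowIdx))
  for (b in bgIds) m[b, ] <- intensity(nS)
  for (d in decoyIds) {
    repeat {
      pres <- stats::runif(nS) < 0.6
      if (!any(pres)) next
      presentConds <- unique(conds[pres])
      # reject condition-exclusive low-iron noise
      if (!identical(sort(presentConds), "low_iron")) break
    }
    m[d, pres] <- intensity(sum(pres))
  }
  precursor <- c(vapply(candidates, mhTheoretical, numeric(1)),
                 stats::runif(nBg + nDecoyFeat, 300, 1500))
  rt <- stats::runif(length(featIds), 0, 23 * 60)
  ft <- featureTable(m, precursor, rt,
                     stats::setNames(conds, sampleIds))
  list(spectra = spectra, featureTable = ft, sampleMetadata = meta,
       groundTruth = list(
         analogFeatures = stats::setNames(
           vapply(config@plantedTails, tailLabel, character(1)), analogIds),
         decoyFeatureIds = decoyIds, backgroundFeatureIds = bgIds,
         spectrumTruth = spectrumTruth))
}

#' Simulate a metal-treatment before/after pair
#'
#' Builds feature lists bracketing an in-vitro metal incubation:
#' \itemize{
#'   \item `"stable-complex"`: the apo \[M+H\]+ is removed and the holo
#'     adduct ion is planted (<= 1 ppm jitter);
#'   \item `"degradation"`: the apo ion is removed and unassignable ions are
#'     planted;
#'   \item `"no-reaction"`: the after list repeats the before list plus
#'     unrelated noise features.
#' }
#'
#' @param compound An [AnalogCandidate].
#' @param metal Element symbol with at least one registry adduct.
#' @param scenario One of `"stable-complex"`, `"degradation"`,
#'   `"no-reaction"`.
#' @param seed Integer seed.
#' @param nBackground Background features present in both lists.
#' @param registry Adduct registry.
#' @return List with `before`, `after` (data.frames `mz`, `intensity`) and
#'   `groundTruth` (list with `verdict`).
#' @export
simulateMetalTreatment <- function(compound, metal,
                                   scenario = c("stable-complex",
                                                "degradation", "no-reaction"),
                                   seed, nBackground = 5L,
                                   registry = adductRegistry()) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  apoMz <- mhTheoretical(compound)
  bg <- data.frame(mz = stats::runif(nBackground, 300, 1100),
                   intensity = stats::rlnorm(nBackground, log(1e4), 0.5))
  before <- rbind(data.frame(mz = apoMz * (1 + stats::rnorm(1, 0, 1e-6)),
                             intensity = stats::rlnorm(1, log(1e5), 0.3)),
                  bg)
  after <- switch(scenario,
    "stable-complex" = {
      holo <- holoHypotheses(compound, metal, registry)
      rbind(data.frame(
        mz = holo$theoreticalMz[1L] * (1 + stats::rnorm(1, 0, 1e-6)),
        intensity = stats::rlnorm(1, log(8e4), 0.3)), bg)
    },
    "degradation" = {
      nNew <- 3L
      rbind(data.frame(mz = stats::runif(nNew, 400, apoMz - 60),
                       intensity = stats::rlnorm(nNew, log(2e4), 0.5)), bg)
    },
    "no-reaction" = {
      extra <- data.frame(mz = stats::runif(2L, 300, 1100),
                          intensity = stats::rlnorm(2L, log(5e3), 0.5))
      rbind(before, extra)
    })
  expected <- if (scenario == "degradation") "degradation/unassigned"
    else scenario
  list(before = before[order(before$mz), ], after = after[order(after$mz), ],
       groundTruth = list(verdict = expected, scenario = scenario,
                          metal = metal))
}
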