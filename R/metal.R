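#' Holo (metal-complex) ion hypotheses for a compound
#'
#' Applies every registry adduct that incorporates the given metal to the
#' compound's neutral formula. For Fe this yields the ferric complex
#' \[M-2H+Fe\]+; Cu and Au entries are screening hypotheses only.
#'
#' @param compound An [AnalogCandidate].
#' @param metal Element symbol (`"Fe"`, `"Cu"`, `"Au"`, ...).
#' @param registry Adduct registry from [adductRegistry()].
#' @return data.frame with columns `adduct`, `theoreticalMz`.
#' @examples
#' cand <- analogFormula(buildDelftibactinScaffold(), lipidTail(14, 1))
#' holoHypotheses(cand, "Fe") # 1294.5851
#' @export
holoHypotheses <- function(compound, metal, registry = adductRegistry()) {
  withMetal <- Filter(function(a) metal %in% names(a@atomsAdded@counts),
                      registry)
  if (!length(withMetal))
    stop("no adduct in the registry involves metal '", metal, "'")
  data.frame(
    adduct = vapply(withMetal, function(a) a@name, character(1)),
    theoreticalMz = vapply(withMetal, function(a)
      ionMz(neutralFormula(compound), a), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# does any m/z in `mzs` match `target` within tolPpm?
.mz_match <- function(target, mzs, tolPpm)
  which(abs(mzs - target) <= target * tolPpm * 1e-6)

#' Screen a before/after metal-treatment pair
#'
#' Compares feature lists acquired before and after incubating a compound
#' with a metal salt and classifies the outcome:
#' \itemize{
#'   \item `"stable-complex"`: the apo \[M+H\]+ disappears and at least one
#'     holo hypothesis appears;
#'   \item `"degradation/unassigned"`: the apo ion disappears, no holo
#'     hypothesis matches, and new unassignable ions appear;
#'   \item `"no-reaction"`: the apo ion is still present.
#' }
#' With `checkIsotopes = TRUE` a holo hit additionally requires a partner
#' peak at the metal's minor-isotope spacing (Fe: -1.9953 Da; Cu: +1.9982
#' Da) in the after list.
#'
#' @param before,after Feature lists: data.frames with columns `mz` and
#'   (optionally) `intensity`.
#' @param compound An [AnalogCandidate] (defines the apo \[M+H\]+).
#' @param metal Element symbol.
#' @param tolPpm Match tolerance, ppm.
#' @param checkIsotopes Require the minor-isotope partner peak.
#' @param registry Adduct registry.
#' @return A [MetalOutcome].
#' @export
screenMetalReaction <- function(before, after, compound, metal,
                                tolPpm = 10, checkIsotopes = FALSE,
                                registry = adductRegistry()) {
  apoMz <- mhTheoretical(compound)
  hyp <- holoHypotheses(compound, metal, registry)
  beforeMz <- before$mz
  afterMz <- after$mz
  apoRetained <- length(.mz_match(apoMz, afterMz, tolPpm)) > 0L

  isotopeSpacing <- c(Fe = -1.995327, Cu = 1.998192)
  holoRows <- list()
  holoMatchedIdx <- integer(0)
  for (k in seq_len(nrow(hyp))) {
    tmz <- hyp$theoreticalMz[k]
    idxAfter <- .mz_match(tmz, afterMz, tolPpm)
    idxBefore <- .mz_match(tmz, beforeMz, tolPpm)
    if (!length(idxAfter) || length(idxBefore)) next
    if (checkIsotopes && metal %in% names(isotopeSpacing)) {
      partner <- tmz + isotopeSpacing[[metal]]
      if (!length(.mz_match(partner, afterMz, tolPpm))) next
    }
    obs <- afterMz[idxAfter[which.min(abs(afterMz[idxAfter] - tmz))]]
    holoMatchedIdx <- c(holoMatchedIdx,
                        .mz_match(tmz, afterMz, tolPpm))
    holoRows[[length(holoRows) + 1L]] <- data.frame(
      adduct = hyp$adduct[k], theoreticalMz = tmz, observedMz = obs,
      ppm = ppmError(obs, tmz), stringsAsFactors = FALSE)
  }
  holo <- if (length(holoRows)) do.call(rbind, holoRows) else
    data.frame(adduct = character(0), theoreticalMz = numeric(0),
               observedMz = numeric(0), ppm = numeric(0))

  # new ions: present after, absent before, and not apo / holo
  isNew <- vapply(seq_along(afterMz), function(i) {
    mz <- afterMz[i]
    length(.mz_match(mz, beforeMz, tolPpm)) == 0L &&
      length(.mz_match(mz, apoMz, tolPpm)) == 0L
  }, logical(1))
  unassigned <- afterMz[isNew]
  unassigned <- unassigned[!seq_along(afterMz)[isNew] %in% holoMatchedIdx]

  verdict <- if (apoRetained) "no-reaction"
    else if (nrow(holo) > 0L) "stable-complex"
    else "degradation/unassigned"
  out <- new("MetalOutcome",
             compoundId = tailLabel(candidateTail(compound)),
             metal = metal, apoRetained = apoRetained, holoDetected = holo,
             unassignedNewIons = as.numeric(unassigned), verdict = verdict)
  out
}

setMethod("show", "MetalOutcome", function(object) {
  cat("MetalOutcome [", object@metal, " / compound ", object@compoundId,
      "]: ", object@verdict, "\n", sep = "")
  if (nrow(object@holoDetected))
    cat("  holo ions:",
        paste0(object@holoDetected$adduct, " @ ",
               round(object@holoDetected$observedMz, 4), " (",
               round(object@holoDetected$ppm, 1), " ppm)",
               collapse = "; "), "\n")
  if (length(object@unassignedNewIons))
    cat("  unassigned new ions:",
        paste(round(object@unassignedNewIons, 4), collapse = ", "), "\n")
})

#' Verdict of a MetalOutcome
#' @param x A [MetalOutcome].
#' @return One of `"stable-complex"`, `"degradation/unassigned"`,
#'   `"no-reaction"`.
#' @export
metalVerdict <- function(x) x@verdict

#' @rdname metalVerdict
#' @export
holoDetected <- function(x) x@holoDetected

#' Write a metal-screen verdict report
#'
#' One-row verdict TSV plus a detail table of all new ions with their best
#' hypothesis and ppm.
#'
#' @param outcome A [MetalOutcome].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeMetalReport <- function(outcome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader("metal screen"), con)
  writeLines("## verdict", con)
  utils::write.table(
    data.frame(compound = outcome@compoundId, metal = outcome@metal,
               apoRetained = outcome@apoRetained,
               nHolo = nrow(outcome@holoDetected),
               nUnassigned = length(outcome@unassignedNewIons),
               verdict = outcome@verdict),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("## holo_ions", con)
  if (nrow(outcome@holoDetected)) {
    d <- outcome@holoDetected
    d$theoreticalMz <- round(d$theoreticalMz, 4)
    d$observedMz <- round(d$observedMz, 4)
    d$ppm <- round(d$ppm, 1)
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines("## unassigned_new_ions", con)
  if (length(outcome@unassignedNewIons))
    writeLines(format(round(outcome@unassignedNewIons, 4), nsmall = 4), con)
  invisible(path)
}
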