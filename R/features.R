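#' Construct a FeatureTable
#'
#' @param intensities Numeric matrix, features x samples, with feature ids as
#'   rownames and sample ids as colnames.
#' @param precursorMz Numeric vector of feature precursor m/z.
#' @param retentionTime Numeric vector of retention times (seconds).
#' @param conditions Named character vector mapping sample id -> condition;
#'   every column of `intensities` must be present.
#' @return A [FeatureTable].
#' @examples
#' m <- matrix(c(10, 0, 0, 0), 1, 4,
#'             dimnames = list("f1", paste0("s", 1:4)))
#' ft <- featureTable(m, 1241.67, 600,
#'                    c(s1 = "low_iron", s2 = "low_iron",
#'                      s3 = "high_iron", s4 = "high_iron"))
#' @export
featureTable <- function(intensities, precursorMz, retentionTime, conditions) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- paste0("feature", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    stop("intensity matrix needs sample ids as colnames")
  miss <- setdiff(colnames(intensities), names(conditions))
  if (length(miss))
    stop("samples missing from the condition map: ",
         paste(miss, collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities),
    rowData = S4Vectors::DataFrame(precursorMz = precursorMz,
                                   retentionTime = retentionTime),
    colData = S4Vectors::DataFrame(
      condition = unname(conditions[colnames(intensities)]),
      row.names = colnames(intensities)))
  new("FeatureTable", se)
}

#' Intensity matrix of a FeatureTable
#' @param ft A [FeatureTable].
#' @return Numeric matrix, features x samples.
#' @export
featureIntensities <- function(ft)
  SummarizedExperiment::assay(ft, "intensity")

#' @describeIn featureIntensities Sample -> condition map.
#' @export
featureConditions <- function(ft) {
  cd <- SummarizedExperiment::colData(ft)
  stats::setNames(as.character(cd$condition), rownames(cd))
}

#' Label features by condition presence
#'
#' A feature is present in a condition iff its intensity exceeds
#' `presenceThreshold` (strictly above zero in any case) in at least one
#' replicate of that condition. Features are labelled `"low-only"`,
#' `"high-only"` or `"both"`; features absent everywhere are excluded.
#'
#' @param ft A [FeatureTable] whose condition map uses exactly the two
#'   condition names given.
#' @param presenceThreshold Intensity threshold; the default 0 counts any
#'   nonzero intensity as presence.
#' @param lowCondition,highCondition Condition names in the table.
#' @return data.frame with columns `featureId`, `label`, `maxIntensity`;
#'   one row per feature present in at least one condition.
#' @export
labelConditions <- function(ft, presenceThreshold = 0,
                            lowCondition = "low_iron",
                            highCondition = "high_iron") {
  cond <- featureConditions(ft)
  for (cn in c(lowCondition, highCondition))
    if (!any(cond == cn))
      stop("condition '", cn, "' has no samples")
  m <- featureIntensities(ft)
  present <- function(cn) {
    sub <- m[, cond == cn, drop = FALSE]
    apply(sub, 1L, function(x) any(x > 0 & x >= presenceThreshold))
  }
  lo <- present(lowCondition)
  hi <- present(highCondition)
  keep <- lo | hi
  label <- ifelse(lo & hi, "both", ifelse(lo, "low-only", "high-only"))
  data.frame(featureId = rownames(m)[keep], label = label[keep],
             maxIntensity = apply(m, 1L, max)[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Condition-exclusive (iron-limitation) features
#'
#' Returns the features present only under the low-iron condition, ranked by
#' descending maximum intensity — the differential-analysis step that
#' surfaces candidate siderophore analogs.
#'
#' @inheritParams labelConditions
#' @return data.frame (subset of [labelConditions()] output with
#'   `label == "low-only"`), best first.
#' @export
differentialFeatures <- function(ft, presenceThreshold = 0,
                                 lowCondition = "low_iron",
                                 highCondition = "high_iron") {
  lab <- labelConditions(ft, presenceThreshold, lowCondition, highCondition)
  out <- lab[lab$label == "low-only", , drop = FALSE]
  out <- out[order(-out$maxIntensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
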