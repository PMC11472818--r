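#' Provenance header lines for TSV outputs
#'
#' Every table the package writes starts with comment lines recording the
#' package version, the writing function and the timestamp-free run
#' parameters, so outputs are self-describing and re-runs are comparable.
#'
#' @param what Short description of the output.
#' @param params Optional named list echoed into the header.
#' @return Character vector of `#`-prefixed lines.
#' @export
provenanceHeader <- function(what, params = list()) {
  lines <- c(
    paste0("# delftiMS ", as.character(utils::packageVersion("delftiMS")),
           " :: ", what))
  if (length(params))
    lines <- c(lines, paste0("# ", names(params), " = ",
                             vapply(params, function(p)
                               paste(format(p), collapse = ","),
                               character(1))))
  lines
}

#' Read an MGF (Mascot Generic Format) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, `CHARGE`, `TITLE`,
#' `RTINSECONDS` and optional `SAMPLEID` headers. Peaks are sorted by m/z.
#' A block without `CHARGE` defaults to 1+ with a warning; a block without
#' `PEPMASS` is an error naming the block. An empty file yields an empty
#' list.
#'
#' @param path Path to an MGF file.
#' @return List of [Spectrum] objects.
#' @export
readMGF <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends) || any(ends < starts))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    isHeader <- grepl("=", block, fixed = TRUE)
    hdr <- block[isHeader]
    keys <- toupper(sub("=.*", "", hdr))
    vals <- sub("^[^=]*=", "", hdr)
    names(vals) <- keys
    title <- if ("TITLE" %in% keys) vals[["TITLE"]] else paste0("spectrum", k)
    if (!"PEPMASS" %in% keys)
      stop("MGF block '", title, "' (starting line ", starts[k],
           ") has no PEPMASS")
    pep <- as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "\\s+")[[1L]][1L])
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", vals[["CHARGE"]]))
    } else {
      warning("MGF block '", title, "' has no CHARGE; assuming 1+")
      1L
    }
    rt <- if ("RTINSECONDS" %in% keys) as.numeric(vals[["RTINSECONDS"]])
      else NA_real_
    sampleId <- if ("SAMPLEID" %in% keys) vals[["SAMPLEID"]] else
      NA_character_
    peakLines <- trimws(block[!isHeader])
    peakLines <- peakLines[nzchar(peakLines)]
    peaks <- if (length(peakLines)) {
      fields <- strsplit(peakLines, "[ \t]+")
      bad <- which(vapply(fields, length, integer(1)) < 2L)
      if (length(bad))
        stop("malformed peak line ", starts[k] + which(!isHeader)[bad[1L]],
             " in ", path)
      matrix(as.numeric(unlist(lapply(fields, `[`, 1:2))),
             ncol = 2, byrow = TRUE)
    } else matrix(numeric(0), ncol = 2)
    out[[k]] <- spectrum(title, pep, peaks, charge = charge,
                         retentionTime = rt, sampleId = sampleId)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [readMGF()]: round trips are semantically lossless for all the
#' fields the pipeline consumes. m/z values are written at 6 decimal places.
#'
#' @param spectra List of [Spectrum] objects (may be empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s@id), con)
    writeLines(paste0("PEPMASS=", format(s@precursorMz, nsmall = 6,
                                         scientific = FALSE)), con)
    writeLines(paste0("CHARGE=", s@charge, "+"), con)
    if (is.finite(s@retentionTime))
      writeLines(paste0("RTINSECONDS=", format(s@retentionTime,
                                               scientific = FALSE)), con)
    if (!is.na(s@sampleId))
      writeLines(paste0("SAMPLEID=", s@sampleId), con)
    if (nrow(s@peaks))
      writeLines(paste(format(s@peaks[, 1L], nsmall = 6,
                              scientific = FALSE, trim = TRUE),
                       format(s@peaks[, 2L], scientific = FALSE,
                              trim = TRUE)), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read/write a FeatureTable as TSV
#'
#' The TSV carries one row per feature (`featureId`, `precursorMz`,
#' `retentionTime`, one intensity column per sample) and `#`-prefixed header
#' lines including a `# condition:` map line. Round trips preserve
#' intensities to full precision.
#'
#' @param ft A [FeatureTable].
#' @param path TSV path.
#' @return `readFeatureTable`: a [FeatureTable]; `writeFeatureTable`:
#'   `path`, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  cond <- featureConditions(ft)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader("feature table"), con)
  writeLines(paste0("# condition: ",
                    paste(names(cond), cond, sep = "=", collapse = ";")), con)
  m <- featureIntensities(ft)
  rd <- SummarizedExperiment::rowData(ft)
  df <- data.frame(featureId = rownames(m),
                   precursorMz = rd$precursorMz,
                   retentionTime = rd$retentionTime,
                   m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  condLine <- grep("^# condition: ", lines, value = TRUE)
  if (!length(condLine)) stop("feature table has no '# condition:' header")
  pairs <- strsplit(strsplit(sub("^# condition: ", "", condLine[1L]),
                             ";")[[1L]], "=")
  cond <- stats::setNames(vapply(pairs, `[`, character(1), 2L),
                          vapply(pairs, `[`, character(1), 1L))
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE, stringsAsFactors = FALSE)
  sampleCols <- setdiff(names(df),
                        c("featureId", "precursorMz", "retentionTime"))
  m <- as.matrix(df[, sampleCols, drop = FALSE])
  rownames(m) <- df$featureId
  featureTable(m, df$precursorMz, df$retentionTime, cond)
}

#' Export a molecular network as edge and node TSVs
#'
#' Writes `<stem>_edges.tsv` (`idA`, `idB`, `cosine`, `nMatched`) and
#' `<stem>_nodes.tsv` (`id`, `precursorMz`, `sampleId`, `family`, plus a
#' `label` column when condition labels are supplied), importable by
#' standard graph viewers.
#'
#' @param net A [MolecularNetwork].
#' @param stem Output path stem.
#' @param nodeLabels Optional named character vector id -> condition label.
#' @return Character vector of the two paths written, invisibly.
#' @export
exportNetwork <- function(net, stem, nodeLabels = NULL) {
  edgePath <- paste0(stem, "_edges.tsv")
  nodePath <- paste0(stem, "_nodes.tsv")
  hdr <- provenanceHeader("molecular network", net@params)
  e <- net@edges
  e$cosine <- round(e$cosine, 4)
  con <- file(edgePath, "w"); writeLines(hdr, con)
  utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  nodes <- net@nodes
  nodes$precursorMz <- round(nodes$precursorMz, 4)
  if (!is.null(nodeLabels))
    nodes$label <- unname(nodeLabels[nodes$id])
  con <- file(nodePath, "w"); writeLines(hdr, con)
  utils::write.table(nodes, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(edgePath, nodePath))
}

#' Write a simulated experiment to disk
#'
#' Materialises the output of [simulateExperiment()]: one MGF per sample,
#' the feature table, the sample metadata and the ground truth, all as
#' plain text under `dir`.
#'
#' @param sim Result of [simulateExperiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bySample <- split(sim$spectra,
                    vapply(sim$spectra, function(s) s@sampleId, character(1)))
  for (sid in names(bySample))
    writeMGF(bySample[[sid]], file.path(dir, paste0(sid, ".mgf")))
  writeFeatureTable(sim$featureTable, file.path(dir, "features.tsv"))
  utils::write.table(sim$sampleMetadata, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- sim$groundTruth
  truthDf <- data.frame(
    featureId = c(names(gt$analogFeatures), gt$backgroundFeatureIds,
                  gt$decoyFeatureIds),
    kind = c(rep("analog", length(gt$analogFeatures)),
             rep("background", length(gt$backgroundFeatureIds)),
             rep("decoy", length(gt$decoyFeatureIds))),
    tail = c(unname(gt$analogFeatures),
             rep("none", length(gt$backgroundFeatureIds) +
                   length(gt$decoyFeatureIds))))
  utils::write.table(truthDf, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
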