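#' Construct a Spectrum
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z.
#' @param peaks Two-column matrix or data.frame (`mz`, `intensity`); sorted
#'   by m/z on construction.
#' @param charge Precursor charge (default 1).
#' @param retentionTime Retention time, seconds.
#' @param sampleId Run identifier.
#' @return A [Spectrum].
#' @export
spectrum <- function(id, precursorMz, peaks, charge = 1L,
                     retentionTime = NA_real_, sampleId = NA_character_) {
  peaks <- as.matrix(peaks)
  if (!ncol(peaks)) peaks <- matrix(numeric(0), ncol = 2)
  colnames(peaks) <- c("mz", "intensity")
  peaks <- peaks[order(peaks[, 1L]), , drop = FALSE]
  new("Spectrum", id = as.character(id), precursorMz = as.numeric(precursorMz),
      charge = as.integer(charge), retentionTime = as.numeric(retentionTime),
      sampleId = as.character(sampleId), peaks = peaks)
}

#' Peak matrix of a spectrum
#' @param spec A [Spectrum].
#' @return Two-column numeric matrix (`mz`, `intensity`).
#' @export
spectrumPeaks <- function(spec) spec@peaks

#' @describeIn spectrumPeaks Precursor m/z.
#' @export
precursorMz <- function(spec) spec@precursorMz

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum '", object@id, "': precursor ",
      format(round(object@precursorMz, 4), nsmall = 4), " (", object@charge,
      "+), ", nrow(object@peaks), " peaks, sample ", object@sampleId,
      "\n", sep = "")
})

# enumerate candidate peak pairs between two spectra: direct pairs
# (|dmz| <= tol) and pairs shifted by the precursor mass difference
.pair_candidates <- function(pa, pb, shift, fragTol) {
  out <- list()
  for (i in seq_len(nrow(pa))) {
    d0 <- abs(pb[, 1L] - pa[i, 1L])
    d1 <- abs(pb[, 1L] - pa[i, 1L] + shift)  # pb ~ pa - shift (shifted pair)
    hit <- which(d0 <= fragTol | d1 <= fragTol)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = i, j = hit)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# exhaustive best one-to-one pairing over candidate pairs (small sets only)
.exact_pairing <- function(cand, w) {
  best <- 0
  n <- nrow(cand)
  recurse <- function(k, usedI, usedJ, acc) {
    if (k > n) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    # upper bound: all remaining pairs
    if (acc + sum(w[k:n]) <= best) return(invisible())
    recurse(k + 1L, usedI, usedJ, acc)  # skip pair k
    if (!cand$i[k] %in% usedI && !cand$j[k] %in% usedJ)
      recurse(k + 1L, c(usedI, cand$i[k]), c(usedJ, cand$j[k]), acc + w[k])
  }
  recurse(1L, integer(0), integer(0), 0)
  best
}

#' Modified-cosine similarity of two MS/MS spectra
#'
#' The similarity underlying molecular networking: peaks pair either directly
#' (m/z within `fragTol`) or shifted by the precursor mass difference, so
#' that fragments displaced by a single structural modification still count.
#' Intensities are square-root weighted; each peak is used at most once. The
#' default pairing is greedy by descending pair score (a documented
#' approximation of the optimal assignment); `method = "exact"` solves the
#' assignment exhaustively and is intended for small candidate sets.
#'
#' @param a,b [Spectrum] objects (non-empty).
#' @param fragTol Fragment m/z tolerance, Da.
#' @param method `"greedy"` (default) or `"exact"`.
#' @return List with `cosine` (in \[0,1\]) and `nMatched` (number of peak
#'   pairs used).
#' @examples
#' s <- spectrum("s", 500, cbind(c(100, 200), c(1, 1)))
#' modifiedCosine(s, s)$cosine # 1
#' @export
modifiedCosine <- function(a, b, fragTol = 0.02, method = c("greedy", "exact")) {
  method <- match.arg(method)
  pa <- a@peaks; pb <- b@peaks
  if (!nrow(pa) || !nrow(pb)) stop("modifiedCosine needs non-empty spectra")
  wa <- sqrt(pa[, 2L]); wb <- sqrt(pb[, 2L])
  na2 <- sum(wa^2); nb2 <- sum(wb^2)
  if (na2 == 0 || nb2 == 0) return(list(cosine = 0, nMatched = 0L))
  shift <- a@precursorMz - b@precursorMz
  cand <- .pair_candidates(pa, pb, shift, fragTol)
  if (is.null(cand)) return(list(cosine = 0, nMatched = 0L))
  w <- wa[cand$i] * wb[cand$j]
  if (method == "exact" && nrow(cand) <= 24L) {
    # nMatched under exact scoring: recompute with greedy for the count,
    # score from the exhaustive assignment
    score <- .exact_pairing(cand, w)
  } else {
    score <- NULL
  }
  # greedy: descending pair score; symmetric tie-breaks (sum then |diff| of
  # the paired m/z) so cosine(a,b) == cosine(b,a)
  ord <- order(-w, pa[cand$i, 1L] + pb[cand$j, 1L],
               abs(pa[cand$i, 1L] - pb[cand$j, 1L]))
  usedI <- logical(nrow(pa)); usedJ <- logical(nrow(pb))
  greedy <- 0; nMatched <- 0L
  for (r in ord) {
    i <- cand$i[r]; j <- cand$j[r]
    if (usedI[i] || usedJ[j]) next
    usedI[i] <- TRUE; usedJ[j] <- TRUE
    greedy <- greedy + w[r]
    nMatched <- nMatched + 1L
  }
  if (is.null(score)) score <- greedy
  list(cosine = min(1, score / sqrt(na2 * nb2)), nMatched = nMatched)
}

#' Build a molecular network from spectra
#'
#' All-pairs [modifiedCosine()] scoring; an edge is kept iff its cosine
#' reaches `cosineThreshold` and at least `minMatched` peak pairs support it.
#' Families are connected components with at least `minClusterSize` nodes;
#' smaller components are reported as singletons (family `NA`). Defaults are
#' the study parameters 0.55 / 6 / 2.
#'
#' @param spectra List of [Spectrum] objects (at least one).
#' @param cosineThreshold Minimum cosine for an edge.
#' @param minMatched Minimum matched peak pairs for an edge.
#' @param minClusterSize Minimum component size reported as a family.
#' @param fragTol Fragment m/z tolerance, Da.
#' @return A [MolecularNetwork].
#' @export
buildNetwork <- function(spectra, cosineThreshold = 0.55, minMatched = 6L,
                         minClusterSize = 2L, fragTol = 0.02) {
  stopifnot(length(spectra) >= 1L)
  ids <- vapply(spectra, function(s) s@id, character(1))
  if (anyDuplicated(ids)) stop("spectrum ids must be unique")
  nodes <- data.frame(
    id = ids,
    precursorMz = vapply(spectra, function(s) s@precursorMz, numeric(1)),
    sampleId = vapply(spectra, function(s) s@sampleId, character(1)),
    family = NA_integer_, stringsAsFactors = FALSE)
  n <- length(spectra)
  edges <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!nrow(spectra[[i]]@peaks) || !nrow(spectra[[j]]@peaks)) next
    mc <- modifiedCosine(spectra[[i]], spectra[[j]], fragTol = fragTol)
    if (mc$cosine >= cosineThreshold && mc$nMatched >= minMatched)
      edges[[length(edges) + 1L]] <- data.frame(
        idA = ids[i], idB = ids[j], cosine = mc$cosine,
        nMatched = mc$nMatched, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(idA = character(0), idB = character(0),
               cosine = numeric(0), nMatched = integer(0))
  g <- igraph::graph_from_data_frame(
    edges[, c("idA", "idB")], directed = FALSE,
    vertices = data.frame(name = sort(ids)))
  comp <- igraph::components(g)
  memb <- comp$membership[ids]
  sizes <- comp$csize[memb]
  famComponents <- sort(unique(memb[sizes >= minClusterSize]))
  families <- lapply(famComponents, function(k) unname(ids[memb == k]))
  nodes$family <- match(memb, famComponents)
  new("MolecularNetwork", nodes = nodes, edges = edges, families = families,
      params = list(cosineThreshold = cosineThreshold,
                    minMatched = as.integer(minMatched),
                    minClusterSize = as.integer(minClusterSize),
                    fragTol = fragTol))
}

#' Accessors for MolecularNetwork
#' @param net A [MolecularNetwork].
#' @return `networkEdges`/`networkNodes`: data.frames; `networkFamilies`:
#'   list of id vectors.
#' @export
networkEdges <- function(net) net@edges

#' @rdname networkEdges
#' @export
networkNodes <- function(net) net@nodes

#' @rdname networkEdges
#' @export
networkFamilies <- function(net) net@families

setMethod("show", "MolecularNetwork", function(object) {
  cat("MolecularNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges,", length(object@families),
      "families (cosine >=", object@params$cosineThreshold,
      ", matched >=", object@params$minMatched, ")\n")
})
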