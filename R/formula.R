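#' Parse a Hill-notation formula string
#'
#' Parses strings like `"C54H92N14O19"` into an [ElementalFormula]. Element
#' symbols are one capital letter optionally followed by one lowercase letter,
#' each with an optional integer count (default 1). The empty string parses to
#' the empty formula (mass 0). Unknown element symbols and malformed input are
#' rejected with an error naming the offending token.
#'
#' @param text A single formula string.
#' @return An [ElementalFormula].
#' @examples
#' parseFormula("C54H92N14O19")
#' parseFormula("H2O")
#' @export
parseFormula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) return(emptyFormula())
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1L]]
  if (nchar(paste0(tokens, collapse = "")) != nchar(text))
    stop("malformed formula string: '", text, "'")
  supported <- names(massConstants()$elements)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    if (!sym %in% supported)
      stop("unsupported element symbol '", sym, "' in '", text, "'")
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  elementalFormula(counts)
}

#' Construct an ElementalFormula from named counts
#'
#' @param counts Named integer vector (element symbol -> count). Zero counts
#'   are dropped.
#' @return An [ElementalFormula].
#' @export
elementalFormula <- function(counts = integer(0)) {
  counts <- counts[counts != 0L]
  storage.mode(counts) <- "integer"
  if (length(counts)) {
    # canonical Hill order: C, H, then alphabetical
    ord <- c("C", "H", sort(setdiff(names(massConstants()$elements), c("C", "H"))))
    counts <- counts[order(match(names(counts), ord))]
  }
  new("ElementalFormula", counts = counts)
}

#' @rdname elementalFormula
#' @export
emptyFormula <- function() elementalFormula()

#' Element counts of a formula
#' @param f An [ElementalFormula].
#' @return Named integer vector.
#' @export
formulaCounts <- function(f) f@counts

#' Serialise a formula to a Hill-notation string
#'
#' Round trips exactly with [parseFormula()].
#'
#' @param f An [ElementalFormula].
#' @return A single string; `""` for the empty formula.
#' @export
formulaString <- function(f) {
  cnt <- f@counts
  if (!length(cnt)) return("")
  paste0(names(cnt), ifelse(cnt == 1L, "", cnt), collapse = "")
}

setMethod("show", "ElementalFormula", function(object) {
  s <- formulaString(object)
  cat("ElementalFormula: ", if (nzchar(s)) s else "(empty)",
      "  [", format(monoisotopicMass(object), nsmall = 4), " Da]\n", sep = "")
})

#' Add or subtract elemental formulas
#'
#' Elementwise sum (`sign = +1`) or difference (`sign = -1`). A subtraction
#' that would drive any element count negative is a domain error.
#'
#' @param a,b [ElementalFormula] objects.
#' @param sign `+1` or `-1`.
#' @return An [ElementalFormula].
#' @examples
#' combineFormulas(parseFormula("C40H68N14O18"), parseFormula("C14H24O"))
#' @export
combineFormulas <- function(a, b, sign = 1L) {
  stopifnot(sign %in% c(1L, -1L))
  ca <- a@counts
  cb <- b@counts
  els <- union(names(ca), names(cb))
  out <- integer(length(els))
  names(out) <- els
  out[names(ca)] <- out[names(ca)] + ca
  out[names(cb)] <- out[names(cb)] + as.integer(sign) * cb
  if (any(out < 0L))
    stop("negative element count for ", paste(els[out < 0L], collapse = ", "),
         " in formula combination")
  elementalFormula(out)
}

#' Monoisotopic mass of a formula
#'
#' Sum of per-element monoisotopic masses (most abundant isotope). The empty
#' formula has mass 0.
#'
#' @param f An [ElementalFormula].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(parseFormula("H2O")) # 18.010565
#' @export
monoisotopicMass <- function(f) {
  cnt <- f@counts
  if (!length(cnt)) return(0)
  sum(cnt * massConstants()$elements[names(cnt)])
}

#' The built-in adduct registry
#'
#' Loads the shipped adduct table (`extdata/adducts.tsv`) or a user-supplied
#' table with the same columns (`name`, `atoms_added`, `hydrogens_removed`,
#' `charge`). Adducts describe cation formation from a neutral molecule M.
#'
#' The shipped registry covers \[M+H\]+, \[M+Na\]+, \[M+2H\]2+, the ferric
#' complex \[M-2H+Fe\]+, copper hypotheses \[M-H+Cu\]+ and
#' \[M-2H+Cu+H2O\]+, and \[M-2H+Au\]+. The copper and gold entries are
#' screening hypotheses only.
#'
#' @param path Optional path to an alternative registry TSV.
#' @return Named list of [AdductSpec] objects.
#' @export
adductRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "adducts.tsv", package = "delftiMS",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  needed <- c("name", "atoms_added", "hydrogens_removed", "charge")
  if (!all(needed %in% names(tab)))
    stop("adduct registry must have columns: ", paste(needed, collapse = ", "))
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    new("AdductSpec",
        name = tab$name[i],
        atomsAdded = parseFormula(ifelse(is.na(tab$atoms_added[i]), "",
                                         tab$atoms_added[i])),
        hydrogensRemoved = as.integer(tab$hydrogens_removed[i]),
        charge = as.integer(tab$charge[i]))
  })
  names(specs) <- tab$name
  specs
}

#' Look up one adduct by name
#'
#' @param name Adduct name, e.g. `"[M+H]+"`. A Unicode minus sign is accepted
#'   and normalised to ASCII `-`.
#' @param registry Registry list from [adductRegistry()].
#' @return An [AdductSpec].
#' @export
getAdduct <- function(name, registry = adductRegistry()) {
  name <- gsub("−", "-", name)
  if (!name %in% names(registry))
    stop("unknown adduct '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]
}

setMethod("show", "AdductSpec", function(object) {
  cat("AdductSpec ", object@name, ": +", formulaString(object@atomsAdded),
      " -", object@hydrogensRemoved, "H, charge ", object@charge, "+\n",
      sep = "")
})

#' Theoretical m/z of an ion
#'
#' Applies an [AdductSpec] to a neutral formula:
#' \deqn{m/z = (M + m_{added} - n_H m_H - z\, m_e)/z}
#' where \eqn{M} is the neutral monoisotopic mass, \eqn{m_{added}} the mass of
#' added atoms, \eqn{n_H} the removed hydrogens (as neutral H atoms),
#' \eqn{z} the charge and \eqn{m_e} the electron mass. The electron-mass
#' correction is what makes calculated cation m/z values agree with
#' high-resolution instruments at the fourth decimal place.
#'
#' @param neutral [ElementalFormula] of the neutral molecule.
#' @param adduct An [AdductSpec], or an adduct name resolved against
#'   `registry`.
#' @param registry Adduct registry used when `adduct` is a name.
#' @return m/z of the cation.
#' @examples
#' ionMz(parseFormula("C54H92N14O19"), "[M+H]+")      # 1241.6736
#' ionMz(parseFormula("C54H92N14O19"), "[M-2H+Fe]+")  # 1294.5851
#' @export
ionMz <- function(neutral, adduct, registry = adductRegistry()) {
  if (is.character(adduct)) adduct <- getAdduct(adduct, registry)
  k <- massConstants()
  nH <- adduct@hydrogensRemoved
  if (nH > 0L) {
    avail <- neutral@counts["H"]
    if (is.na(avail) || avail < nH)
      stop("adduct ", adduct@name, " removes ", nH,
           " H but the neutral formula has ",
           ifelse(is.na(avail), 0L, avail))
  }
  z <- as.numeric(adduct@charge)
  (monoisotopicMass(neutral) + monoisotopicMass(adduct@atomsAdded) -
     nH * k$elements[["H"]] - z * k$electron) / z
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppmError(1241.6730, 1241.6736) # -0.48 ppm
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}

#' Ring plus double-bond equivalents
#'
#' Standard RDBE over C/H/N/O/S/P: \eqn{C - H/2 + (N+P)/2 + 1}, treating N
#' and P as trivalent and O/S as divalent. Metals and alkali counterions are
#' ignored.
#'
#' @param f An [ElementalFormula].
#' @return RDBE as a double (can be half-integral for odd-electron species).
#' @examples
#' rdbe(parseFormula("C6H6")) # benzene: 4
#' @export
rdbe <- function(f) {
  cnt <- f@counts
  g <- function(el) if (el %in% names(cnt)) cnt[[el]] else 0L
  g("C") - g("H") / 2 + (g("N") + g("P")) / 2 + 1
}
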