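#' Monoisotopic mass constants
#'
#' Monoisotopic masses (most abundant isotope, Da) for the supported element
#' set, plus the electron and proton masses and the minor-isotope masses of
#' iron and copper used by the isotope-spacing check in the metal screen.
#' Values follow the CODATA 2018 / AME2020 atomic mass evaluation, truncated
#' at 7-10 decimal places.
#'
#' @return Named list with components `elements` (named numeric vector of
#'   monoisotopic masses in Da), `electron`, `proton`, and `isotopes`
#'   (named numeric vector with `Fe54`, `Fe56`, `Cu63`, `Cu65`).
#' @examples
#' massConstants()$elements[["O"]]
#' @export
massConstants <- function() .mass_constants

.mass_constants <- local({
  elements <- c(
    C  = 12.0,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    Fe = 55.9349375,     # Fe-56 (most abundant)
    Cu = 62.9295975,     # Cu-63
    Au = 196.9665687,
    Na = 22.9897692809,
    K  = 38.96370668
  )
  electron <- 0.000548579909
  list(
    elements = elements,
    electron = electron,
    proton   = elements[["H"]] - electron,
    isotopes = c(
      Fe54 = 53.9396105, Fe56 = 55.9349375,
      Cu63 = 62.9295975, Cu65 = 64.9277895
    )
  )
})

# valence used by the ring/double-bond equivalent formula; metals and
# monovalent alkali counterions are excluded from RDBE
.rdbe_valence <- c(C = 4, H = 1, N = 3, O = 2, S = 2, P = 3)
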