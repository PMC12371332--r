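# Bondi-style Van der Waals radii (A). Used both for grid pruning and to
# annotate parsed atoms. Elements missing from the table fall back to the
# generic carbon-like radius with a warning.
.vdw_table <- c(
  H = 1.20, D = 1.20, He = 1.40,
  C = 1.70, N = 1.55, O = 1.52, F = 1.47, Ne = 1.54,
  Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
  K = 2.75, Ca = 2.31, Ni = 1.63, Cu = 1.40, Zn = 1.39,
  Se = 1.90, Br = 1.85, Kr = 2.02,
  Cd = 1.58, I = 1.98, Xe = 2.16, Hg = 1.55, Fe = 2.00, Mn = 2.00
)

.vdw_default <- 1.70

#' Van der Waals radius of an element
#'
#' Looks up the Van der Waals radius used throughout the grid-pruning and
#' contact computations. Radii follow the Bondi compilation; unknown element
#' symbols fall back to the generic 1.70 A radius with a warning, so a parsed
#' structure with exotic elements never fails outright.
#'
#' @param element Character vector of element symbols (case-insensitive,
#'   e.g. `"C"`, `"Zn"`).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' vdw_radius(c("C", "O", "N"))
#' @export
vdw_radius <- function(element) {
  key <- paste0(
    toupper(substr(element, 1, 1)),
    tolower(substr(element, 2, nchar(element)))
  )
  r <- unname(.vdw_table[key])
  unknown <- is.na(r) | is.na(element) | element == ""
  if (any(unknown)) {
    warn(sprintf(
      "unknown element symbol(s) %s; using default VdW radius %.2f A",
      paste(unique(element[unknown]), collapse = ", "), .vdw_default
    ))
    r[unknown] <- .vdw_default
  }
  r
}
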