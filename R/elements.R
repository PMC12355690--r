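#' @keywords internal
"_PACKAGE"

# Element reference data used throughout: Cordero covalent radii, Bondi-style
# van der Waals radii, IUPAC 2021 standard atomic weights (abridged).
.element_data <- tibble::tribble(
  ~element, ~cov_radius, ~vdw_radius, ~mass,
  "H",  0.31, 1.20,  1.008,
  "B",  0.84, 1.92, 10.81,
  "C",  0.76, 1.70, 12.011,
  "N",  0.71, 1.55, 14.007,
  "O",  0.66, 1.52, 15.999,
  "F",  0.57, 1.47, 18.998,
  "Na", 1.66, 2.27, 22.990,
  "Mg", 1.41, 1.73, 24.305,
  "P",  1.07, 1.80, 30.974,
  "S",  1.05, 1.80, 32.06,
  "Cl", 1.02, 1.75, 35.45,
  "K",  2.03, 2.75, 39.098,
  "Ca", 1.76, 2.31, 40.078,
  "Cu", 1.32, 1.40, 63.546,
  "Zn", 1.22, 1.39, 65.38,
  "Br", 1.20, 1.85, 79.904,
  "I",  1.39, 1.98, 126.904,
  "Ar", 1.06, 1.88, 39.948
)

.element_lookup <- function(elements, column) {
  idx <- match(elements, .element_data$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("unsupported element(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  .element_data[[column]][idx]
}

#' Van der Waals radius of an element
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements) .element_lookup(elements, "vdw_radius")

#' Covalent radius of an element
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
covalent_radius <- function(elements) .element_lookup(elements, "cov_radius")

#' Standard atomic weight of an element
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of atomic masses (g/mol).
#' @export
atomic_mass <- function(elements) .element_lookup(elements, "mass")

# Conversion constants
.KCAL_PER_KJ <- 1 / 4.184
.KJ_PER_KCAL <- 4.184
.COULOMB_CONST <- 332.0637   # kcal*A/(mol*e^2)
.DEBYE_PER_EA <- 4.803       # 1 e*A = 4.803 D
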