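#' Molecule objects
#'
#' A molecule is a light S3 object wrapping two tibbles: an `atoms` table
#' (element, x, y, z in Angstrom, partial charge, Dreiding-style `ff_type`,
#' `vdw_radius`) and a `bonds` table (`i`, `j` atom indices and `order`, one of
#' "single", "double", "triple", "aromatic"). Ring systems detected by
#' [perceive_bonds()] live in `rings` (a list of integer atom-index vectors)
#' with a parallel logical `ring_aromatic` flag.
#'
#' @param atoms a data frame with at least `element`, `x`, `y`, `z`; optional
#'   `charge` (defaults 0). `vdw_radius` is filled from element data when
#'   absent.
#' @param bonds a data frame with `i`, `j`, `order`, or NULL for no bonds.
#' @param name molecule identifier.
#' @param rings list of integer vectors (atom indices per ring).
#' @param ring_aromatic logical vector parallel to `rings`.
#' @return an object of class `cocryst_molecule`.
#' @export
new_molecule <- function(atoms, bonds = NULL, name = "mol",
                         rings = list(), ring_aromatic = logical()) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!"charge" %in% names(atoms)) atoms$charge <- 0
  if (!"ff_type" %in% names(atoms)) atoms$ff_type <- NA_character_
  if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- vdw_radius(atoms$element)
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = character())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (is.null(bonds$order)) bonds$order <- rep("single", nrow(bonds))
    if (nrow(bonds) > 0 &&
        (max(bonds$i, bonds$j) > nrow(atoms) || min(bonds$i, bonds$j) < 1)) {
      stop("bond indices out of range", call. = FALSE)
    }
  }
  structure(
    list(atoms = atoms, bonds = bonds, name = name,
         rings = rings, ring_aromatic = ring_aromatic),
    class = "cocryst_molecule"
  )
}

#' @export
print.cocryst_molecule <- function(x, ...) {
  cat(sprintf("<cocryst_molecule '%s': %d atoms, %d bonds, %d rings>\n",
              x$name, nrow(x$atoms), nrow(x$bonds), length(x$rings)))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param mol a `cocryst_molecule`.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Geometric centroid of a molecule
#' @param mol a `cocryst_molecule`.
#' @return length-3 numeric vector.
#' @export
mol_centroid <- function(mol) colMeans(coords(mol))

#' Apply a rigid transform (rotation then translation) to a molecule
#' @param mol a `cocryst_molecule`.
#' @param rot 3x3 rotation matrix (Cartesian).
#' @param trans length-3 translation (Angstrom).
#' @return transformed molecule.
#' @export
transform_molecule <- function(mol, rot = diag(3), trans = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(rot)
  mol$atoms$x <- xyz[, 1] + trans[1]
  mol$atoms$y <- xyz[, 2] + trans[2]
  mol$atoms$z <- xyz[, 3] + trans[3]
  mol
}

# RMSD between two same-size coordinate sets after optimal superposition
# (Kabsch). Used for congruence checks in symmetry expansion tests.
#' Optimal-superposition RMSD between two conformers
#' @param a,b n x 3 coordinate matrices with matching atom order.
#' @return RMSD in Angstrom after Kabsch alignment.
#' @export
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(ac, bc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- bc - ac %*% t(rot)
  sqrt(mean(rowSums(diffs^2)))
}

# pairwise distance matrix between two coordinate matrices
.dist_xyz <- function(a, b) {
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
}
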