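#' Unit cells, symmetry operations and crystal structures
#'
#' A `cocryst_crystal` bundles a triclinic-capable unit cell, a list of
#' symmetry operations in the fractional basis, and the asymmetric-unit
#' molecules (Cartesian coordinates, right-handed cell with a along x).
#'
#' @param a,b,c cell lengths in Angstrom.
#' @param alpha,beta,gamma cell angles in degrees.
#' @return a `cocryst_cell` list with the lengths, angles, the 3x3 cell
#'   matrix `mat` (rows are the cell vectors) and derived `volume`.
#' @export
new_unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v <- sqrt(max(0, 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg))
  if (v <= 0) stop("degenerate cell (zero volume)", call. = FALSE)
  mat <- rbind(
    c(a, 0, 0),
    c(b * cg, b * sg, 0),
    c(c * cb, c * (ca - cb * cg) / sg, c * v / sg)
  )
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         mat = mat, volume = a * b * c * v),
    class = "cocryst_cell"
  )
}

#' @export
print.cocryst_cell <- function(x, ...) {
  cat(sprintf("<cell a=%.4g b=%.4g c=%.4g al=%.4g be=%.4g ga=%.4g V=%.4g A^3>\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert fractional to Cartesian coordinates (rows)
#' @param frac n x 3 fractional coordinates.
#' @param cell a `cocryst_cell`.
#' @return n x 3 Cartesian matrix (Angstrom).
#' @export
frac_to_cart <- function(frac, cell) frac %*% cell$mat

#' Convert Cartesian to fractional coordinates (rows)
#' @param cart n x 3 Cartesian coordinates (Angstrom).
#' @param cell a `cocryst_cell`.
#' @return n x 3 fractional matrix.
#' @export
cart_to_frac <- function(cart, cell) cart %*% solve(cell$mat)

#' Interplanar spacing of a lattice-plane family
#' @param cell a `cocryst_cell`.
#' @param hkl integer length-3 Miller indices.
#' @return d-spacing in Angstrom.
#' @export
d_spacing <- function(cell, hkl) {
  if (all(hkl == 0)) stop("hkl must not be (0,0,0)", call. = FALSE)
  g_star <- solve(tcrossprod(cell$mat))        # reciprocal metric tensor
  1 / sqrt(drop(t(hkl) %*% g_star %*% hkl))
}

#' Construct a symmetry operation
#' @param rotation 3x3 integer matrix in the fractional basis.
#' @param translation length-3 fractional vector.
#' @return a `cocryst_symop`.
#' @export
new_symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  if (abs(abs(det(rotation)) - 1) > 1e-8) {
    stop("symmetry rotation must have determinant +/-1", call. = FALSE)
  }
  structure(list(rot = rotation, trans = as.numeric(translation)),
            class = "cocryst_symop")
}

# --- xyz symmetry-string parsing/formatting ------------------------------

.parse_symop_xyz <- function(s) {
  parts <- strsplit(gsub("[ ']", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("bad symmetry xyz string: ", s, call. = FALSE)
  rot <- matrix(0, 3, 3); trans <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    # tokenize into signed terms
    toks <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tk in toks) {
      sign <- if (startsWith(tk, "-")) -1 else 1
      body <- sub("^[+-]", "", tk)
      if (body %in% c("x", "y", "z")) {
        rot[r, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        trans[r] <- trans[r] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[r] <- trans[r] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry term '", tk, "' in: ", s, call. = FALSE)
      }
    }
  }
  new_symop(rot, trans)
}

.format_symop_xyz <- function(op) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (r in 1:3) {
    terms <- character()
    for (cc in 1:3) {
      v <- op$rot[r, cc]
      if (abs(v) > 1e-9) {
        terms <- c(terms, paste0(if (v < 0) "-" else if (length(terms)) "+" else "",
                                 axes[cc]))
      }
    }
    tr <- op$trans[r] %% 1
    if (abs(tr) > 1e-9 && abs(tr - 1) > 1e-9) {
      fr <- .as_fraction(tr)
      terms <- c(terms, paste0("+", fr))
    }
    comp[r] <- paste(terms, collapse = "")
  }
  paste(comp, collapse = ",")
}

.as_fraction <- function(x, denoms = c(2, 3, 4, 6)) {
  for (d in denoms) {
    n <- round(x * d)
    if (abs(x - n / d) < 1e-6) return(paste0(n, "/", d))
  }
  format(x)
}

.symops_for_group <- function(label) {
  lab <- gsub("[ _]", "", label)
  if (toupper(lab) %in% c("P1")) {
    list(new_symop(diag(3)))
  } else if (toupper(lab) %in% c("P-1", "P1\U0305", "P-1(2)")) {
    list(new_symop(diag(3)), new_symop(-diag(3)))
  } else {
    stop("space-group symbol '", label,
         "' not supported; supply explicit symmetry xyz strings", call. = FALSE)
  }
}

#' Construct a crystal structure
#'
#' @param cell a `cocryst_cell`.
#' @param asym_molecules list of `cocryst_molecule` (Cartesian Angstrom
#'   coordinates consistent with `cell`).
#' @param ops list of `cocryst_symop` (default identity only, P1).
#' @param space_group_label text label, e.g. "P1" or "P-1".
#' @return a `cocryst_crystal`.
#' @export
new_crystal <- function(cell, asym_molecules, ops = list(new_symop(diag(3))),
                        space_group_label = "P1") {
  stopifnot(inherits(cell, "cocryst_cell"), length(asym_molecules) >= 1)
  structure(
    list(cell = cell, ops = ops, asym_molecules = asym_molecules,
         space_group_label = space_group_label),
    class = "cocryst_crystal"
  )
}

#' @export
print.cocryst_crystal <- function(x, ...) {
  cat(sprintf("<cocryst_crystal %s: Z'=%d, %d symmetry op(s)>\n",
              x$space_group_label, length(x$asym_molecules), length(x$ops)))
  print(x$cell)
  invisible(x)
}

#' Expand the asymmetric unit into all molecules of one unit cell
#'
#' Applies every symmetry operation to every asymmetric-unit molecule (whole
#' molecules are transformed together, so they stay connected), wraps each
#' molecule by its centroid into the [0,1) cell, and removes duplicates
#' (molecules mapped onto themselves by an operation).
#'
#' @param xtal a `cocryst_crystal`.
#' @return list of molecules; each carries `asym_id` and `op_id` attributes.
#' @export
expand_cell <- function(xtal) {
  out <- list(); keys <- character()
  for (mi in seq_along(xtal$asym_molecules)) {
    mol <- xtal$asym_molecules[[mi]]
    frac <- cart_to_frac(coords(mol), xtal$cell)
    for (oi in seq_along(xtal$ops)) {
      op <- xtal$ops[[oi]]
      f2 <- frac %*% t(op$rot) + matrix(op$trans, nrow(frac), 3, byrow = TRUE)
      cen <- colMeans(f2)
      shift <- floor(cen)
      f2 <- sweep(f2, 2, shift)
      key <- paste(mi, paste(sprintf("%.4f", colMeans(f2)), collapse = ","))
      if (key %in% keys) next
      # also drop if congruent with an already-kept image at same centroid
      keys <- c(keys, key)
      m2 <- mol
      xyz <- frac_to_cart(f2, xtal$cell)
      m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
      attr(m2, "asym_id") <- mi
      attr(m2, "op_id") <- oi
      out <- c(out, list(m2))
    }
  }
  out
}
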