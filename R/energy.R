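#' Intermolecular pair energy under the Dreiding-style potential
#'
#' Three terms, all in kcal/mol over intermolecular atom pairs:
#' \itemize{
#'   \item van der Waals: 12-6 Lennard-Jones
#'     `D_ij[(R_ij/r)^12 - 2(R_ij/r)^6]` with geometric (default) or
#'     arithmetic combination of the per-type parameters;
#'   \item Coulomb: atomic monopoles with a distance-dependent dielectric,
#'     `332.0637 q_i q_j / (eps0 r^2)` (i.e. eps(r) = eps0 * r);
#'   \item hydrogen bond: an explicit 12-10 well on the donor-acceptor
#'     distance, `D_hb[5(R_hb/r_DA)^12 - 6(R_hb/r_DA)^10] cos^4(theta)`
#'     with theta the D-H...A angle, applied when `r_DA < 4.5` Angstrom and
#'     `theta > 90` degrees; it replaces the LJ terms of the donor-acceptor
#'     and hydrogen-acceptor atom pairs.
#' }
#'
#' @param mol_a,mol_b typed, charged `cocryst_molecule`s (distinct).
#' @param params a `cocryst_forcefield` (see [dreiding_params()]).
#' @param detail return per-term attribution (atom indices and energies) as
#'   attribute `"terms"` for downstream decomposition.
#' @return one-row tibble: `e_vdw`, `e_coul`, `e_hb`, `e_total` (kcal/mol).
#' @export
pair_energy <- function(mol_a, mol_b, params = dreiding_params(),
                        detail = FALSE) {
  xa <- coords(mol_a); xb <- coords(mol_b)
  pa <- .ff_atom_params(params, mol_a$atoms$ff_type)
  pb <- .ff_atom_params(params, mol_b$atoms$ff_type)
  r <- .dist_xyz(xa, xb)
  r <- pmax(r, 1e-6)
  if (params$combining == "geometric") {
    r0 <- sqrt(outer(pa$r0, pb$r0))
  } else {
    r0 <- outer(pa$r0, pb$r0, "+") / 2
  }
  d0 <- sqrt(outer(pa$d0, pb$d0))
  s6 <- (r0 / r)^6
  e_vdw_mat <- d0 * (s6^2 - 2 * s6)
  qq <- outer(mol_a$atoms$charge, mol_b$atoms$charge)
  e_coul_mat <- .COULOMB_CONST * qq / (params$eps0 * r^2)

  # explicit hydrogen-bond treatment
  hb <- .hbond_terms(mol_a, mol_b, xa, xb, params)
  e_hb <- 0
  if (nrow(hb)) {
    for (k in seq_len(nrow(hb))) {
      # the 12-10 well replaces the LJ terms of the D...A and H...A pairs
      if (hb$donor_in_a[k]) {
        e_vdw_mat[hb$d_idx[k], hb$a_idx[k]] <- 0
        e_vdw_mat[hb$h_idx[k], hb$a_idx[k]] <- 0
      } else {
        e_vdw_mat[hb$a_idx[k], hb$d_idx[k]] <- 0
        e_vdw_mat[hb$a_idx[k], hb$h_idx[k]] <- 0
      }
    }
    e_hb <- sum(hb$e)
  }
  e_vdw <- sum(e_vdw_mat)
  e_coul <- sum(e_coul_mat)
  out <- tibble::tibble(e_vdw = e_vdw, e_coul = e_coul, e_hb = e_hb,
                        e_total = e_vdw + e_coul + e_hb)
  if (detail) {
    attr(out, "terms") <- list(e_vdw_mat = e_vdw_mat, e_coul_mat = e_coul_mat,
                               hb = hb)
  }
  out
}

.ensure_sites <- function(mol) {
  if (is.null(mol$hb_sites)) mol$hb_sites <- classify_hbond_sites(mol)
  mol
}

# qualifying donor-H...acceptor triples across two molecules
.hbond_terms <- function(mol_a, mol_b, xa, xb, params) {
  mol_a <- .ensure_sites(mol_a); mol_b <- .ensure_sites(mol_b)
  rows <- list()
  eval_dir <- function(don, acc, xd, xacc, donor_in_a) {
    if (nrow(don$donors) == 0 || nrow(acc$acceptors) == 0) return(NULL)
    res <- list()
    for (t in seq_len(nrow(don$donors))) {
      hpos <- xd[don$donors$h[t], ]
      dpos <- xd[don$donors$heavy[t], ]
      for (u in seq_len(nrow(acc$acceptors))) {
        apos <- xacc[acc$acceptors$atom[u], ]
        r_da <- sqrt(sum((dpos - apos)^2))
        if (r_da >= params$hb_rmax) next
        v1 <- dpos - hpos; v2 <- apos - hpos
        cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        theta <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
        if (theta <= params$hb_theta_min) next
        s <- params$r_hb / r_da
        e <- params$d_hb * (5 * s^12 - 6 * s^10) * cth^4
        res <- c(res, list(tibble::tibble(
          d_idx = don$donors$heavy[t], h_idx = don$donors$h[t],
          a_idx = acc$acceptors$atom[u], donor_in_a = donor_in_a,
          r_da = r_da, theta = theta, e = e
        )))
      }
    }
    res
  }
  rows <- c(eval_dir(mol_a$hb_sites, mol_b$hb_sites, xa, xb, TRUE),
            eval_dir(mol_b$hb_sites, mol_a$hb_sites, xb, xa, FALSE))
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(d_idx = integer(), h_idx = integer(), a_idx = integer(),
                   donor_in_a = logical(), r_da = numeric(), theta = numeric(),
                   e = numeric())
}

#' Build the crystal environment of a reference molecule
#'
#' Enumerates every whole symmetry/translation image of the asymmetric-unit
#' molecules whose centroid lies within `cutoff` of the reference molecule's
#' centroid. The supercell extent along each axis is
#' `ceil(cutoff / d_axis) + 1` (d-spacings of (100), (010), (001)), which
#' guarantees completeness of the centroid search.
#'
#' @param xtal a `cocryst_crystal` (typed/charged molecules for energy use).
#' @param ref index of the reference asymmetric-unit molecule (default 1).
#' @param cutoff centroid-centroid cutoff in Angstrom (default 30).
#' @return tibble of partners: `asym_id`, `op_id`, `tx`, `ty`, `tz`,
#'   `centroid_distance`, and list-column `mol` with the transformed
#'   molecule.
#' @export
build_environment <- function(xtal, ref = 1, cutoff = 30) {
  stopifnot(cutoff > 0)
  cell <- xtal$cell
  d_ax <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 function(h) d_spacing(cell, h), numeric(1))
  ext <- ceiling(cutoff / d_ax) + 1
  ref_mol <- xtal$asym_molecules[[ref]]
  ref_cen <- mol_centroid(ref_mol)

  # fractional coordinates + centroids of each asym molecule under each op
  op_frac <- list()
  for (mi in seq_along(xtal$asym_molecules)) {
    frac <- cart_to_frac(coords(xtal$asym_molecules[[mi]]), cell)
    for (oi in seq_along(xtal$ops)) {
      op <- xtal$ops[[oi]]
      f2 <- frac %*% t(op$rot) + matrix(op$trans, nrow(frac), 3, byrow = TRUE)
      op_frac[[length(op_frac) + 1]] <-
        list(mi = mi, oi = oi, frac = f2, cen = colMeans(f2))
    }
  }
  tr <- as.matrix(expand.grid(tx = -ext[1]:ext[1], ty = -ext[2]:ext[2],
                              tz = -ext[3]:ext[3]))
  rows <- list()
  for (im in op_frac) {
    cen_f <- sweep(tr, 2, -im$cen)          # image centroids, fractional
    cen_c <- frac_to_cart(cen_f, cell)
    dvec <- sweep(cen_c, 2, ref_cen)
    dist <- sqrt(rowSums(dvec^2))
    keep <- which(dist <= cutoff & dist > 1e-6)
    if (any(dist[keep] < 0.5)) {
      stop("cell too small relative to molecule: self-image centroid overlap",
           call. = FALSE)
    }
    for (k in keep) {
      rows[[length(rows) + 1]] <- list(
        asym_id = im$mi, op_id = im$oi,
        tx = tr[k, 1], ty = tr[k, 2], tz = tr[k, 3],
        centroid_distance = dist[k],
        frac = sweep(im$frac, 2, -as.numeric(tr[k, ]))
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(asym_id = integer(), op_id = integer(),
                          tx = integer(), ty = integer(), tz = integer(),
                          centroid_distance = numeric(), mol = list()))
  }
  partners <- purrr::map(rows, function(rr) {
    m <- xtal$asym_molecules[[rr$asym_id]]
    xyz <- frac_to_cart(rr$frac, cell)
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m
  })
  out <- tibble::tibble(
    asym_id = vapply(rows, `[[`, numeric(1), "asym_id"),
    op_id = vapply(rows, `[[`, numeric(1), "op_id"),
    tx = vapply(rows, `[[`, numeric(1), "tx"),
    ty = vapply(rows, `[[`, numeric(1), "ty"),
    tz = vapply(rows, `[[`, numeric(1), "tz"),
    centroid_distance = vapply(rows, `[[`, numeric(1), "centroid_distance"),
    mol = partners
  )
  dplyr::arrange(out, .data$centroid_distance)
}

# prepare typed/charged molecules once
.ensure_typed <- function(xtal) {
  xtal$asym_molecules <- lapply(xtal$asym_molecules, function(m) {
    if (anyNA(m$atoms$ff_type)) m <- assign_typing(m)
    .ensure_sites(m)
  })
  xtal
}

#' Lattice energy per asymmetric-unit molecule
#'
#' `E_lattice(ref) = 1/2 * sum over environment partners of pair_energy`;
#' the total is the sum over asymmetric-unit molecules. With
#' `convergence_check = TRUE` the sum is repeated at `cutoff + 10` and the
#' `converged` flag requires agreement within 0.1 kcal/mol.
#'
#' @param xtal a `cocryst_crystal`.
#' @param params a `cocryst_forcefield`.
#' @param cutoff centroid cutoff (Angstrom, default 30).
#' @param convergence_check also evaluate at `cutoff + 10` (default FALSE).
#' @return list: `per_molecule` tibble (`ref`, `e_vdw`, `e_coul`, `e_hb`,
#'   `e_lattice`, `n_partners`), `total` (kcal/mol), and `converged`
#'   (NA unless checked).
#' @export
lattice_energy <- function(xtal, params = dreiding_params(), cutoff = 30,
                           convergence_check = FALSE) {
  xtal <- .ensure_typed(xtal)
  net_q <- vapply(xtal$asym_molecules, function(m) sum(m$atoms$charge),
                  numeric(1))
  if (any(abs(net_q) > 1e-4)) {
    warning("net-charged molecule(s): direct Coulomb sum may not converge",
            call. = FALSE)
  }
  eval_at <- function(cf) {
    rows <- purrr::map(seq_along(xtal$asym_molecules), function(ri) {
      env <- build_environment(xtal, ref = ri, cutoff = cf)
      ref_mol <- xtal$asym_molecules[[ri]]
      if (nrow(env) == 0) {
        return(tibble::tibble(ref = ri, e_vdw = 0, e_coul = 0, e_hb = 0,
                              e_lattice = 0, n_partners = 0))
      }
      es <- purrr::map(env$mol, ~pair_energy(ref_mol, .x, params))
      es <- dplyr::bind_rows(es)
      tibble::tibble(ref = ri,
                     e_vdw = sum(es$e_vdw) / 2,
                     e_coul = sum(es$e_coul) / 2,
                     e_hb = sum(es$e_hb) / 2,
                     e_lattice = sum(es$e_total) / 2,
                     n_partners = nrow(env))
    })
    dplyr::bind_rows(rows)
  }
  per_mol <- eval_at(cutoff)
  total <- sum(per_mol$e_lattice)
  converged <- NA
  if (convergence_check) {
    total2 <- sum(eval_at(cutoff + 10)$e_lattice)
    converged <- abs(total - total2) < 0.1
  }
  list(per_molecule = per_mol, total = total, converged = converged)
}
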