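# shortest integer lattice vectors spanning the (hkl) plane, plus a
# completing vector stepping one layer (h.w = 1)
.plane_basis <- function(cell, hkl, search = 4) {
  cand <- as.matrix(expand.grid(-search:search, -search:search, -search:search))
  cand <- cand[rowSums(abs(cand)) > 0, ]
  dots <- drop(cand %*% hkl)
  inplane <- cand[dots == 0, , drop = FALSE]
  if (nrow(inplane) < 2) stop("no in-plane lattice basis found", call. = FALSE)
  lens <- sqrt(rowSums((inplane %*% cell$mat)^2))
  ord <- order(lens)
  u <- inplane[ord[1], ]
  v <- NULL
  for (k in ord[-1]) {
    w <- inplane[k, ]
    cr <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    if (sum(abs(cr)) > 0) { v <- w; break }
  }
  if (is.null(v)) stop("degenerate in-plane basis", call. = FALSE)
  steps <- cand[dots == 1, , drop = FALSE]
  if (nrow(steps) == 0) stop("no layer-step vector found for hkl", call. = FALSE)
  wlens <- sqrt(rowSums((steps %*% cell$mat)^2))
  w <- steps[which.min(wlens), ]
  list(u = as.numeric(u), v = as.numeric(v), w = as.numeric(w))
}

#' Cut a whole-molecule surface slab for a facet
#'
#' Builds a patch of `patch x patch` surface cells and `n_layers` growth
#' layers of the crystal, then retains whole molecules whose centroid lies
#' below the cutting plane. The termination offset (fractional position of
#' the cut within one d-spacing) defaults to the candidate that minimizes
#' the energy crossing the plane, with ties broken by smaller rugosity;
#' candidate offsets are the symmetry-distinct centroid heights.
#'
#' @param xtal a `cocryst_crystal`.
#' @param hkl integer Miller indices.
#' @param termination_offset fractional offset in `[0, 1)` of the cut within
#'   one d-spacing, or NULL for automatic selection.
#' @param params force field used for the crossing-energy criterion.
#' @param patch surface patch size in surface cells per direction (default 2).
#' @param n_layers slab thickness in d-spacings (default 3; slab thickness is
#'   therefore >= 2 d_hkl).
#' @return a `cocryst_slab`: molecules, facet frame (orthonormal in-plane
#'   axes + normal), patch vectors, projected `area` (Angstrom^2),
#'   `termination_offset`, `d_hkl`.
#' @export
cut_slab <- function(xtal, hkl, termination_offset = NULL,
                     params = dreiding_params(), patch = 2, n_layers = 3) {
  hkl <- normalize_hkl(hkl)
  xtal <- .ensure_typed(xtal)
  cell <- xtal$cell
  g <- .recip_vector(cell, hkl)
  d_hkl <- 1 / sqrt(sum(g^2))
  n_hat <- g * d_hkl
  basis <- .plane_basis(cell, hkl)
  u_c <- drop(matrix(basis$u, 1) %*% cell$mat)
  v_c <- drop(matrix(basis$v, 1) %*% cell$mat)
  w_c <- drop(matrix(basis$w, 1) %*% cell$mat)

  cell_mols <- expand_cell(xtal)
  cell_mols <- lapply(cell_mols, function(m) .ensure_sites(assign_typing(m)))
  # generate slab molecules: patch x patch x n_layers+1 images
  mols <- list()
  for (i in 0:(patch - 1)) for (j in 0:(patch - 1)) for (m in 0:n_layers) {
    tvec <- i * u_c + j * v_c - m * w_c
    for (cm in cell_mols) {
      mols <- c(mols, list(transform_molecule(cm, diag(3), tvec)))
    }
  }
  heights <- vapply(mols, function(mm) sum(mol_centroid(mm) * n_hat), numeric(1))

  # candidate cut offsets: distinct centroid heights (mod d)
  hmod <- sort(unique(round((heights %% d_hkl) / d_hkl, 6))) %% 1
  if (is.null(termination_offset)) {
    cands <- hmod
  } else {
    stopifnot(termination_offset >= 0, termination_offset < 1)
    cands <- termination_offset
  }
  top_ref <- max(heights)
  score <- purrr::map(cands, function(off) {
    # place the cut just above the highest molecule layer matching `off`
    z_cut <- .cut_height(heights, off, d_hkl)
    keep <- heights <= z_cut + 1e-6
    below <- which(keep & heights > z_cut - d_hkl)
    above <- which(!keep & heights < z_cut + d_hkl + 1e-6)
    e_cross <- 0
    for (b in below) for (a in above) {
      e_cross <- e_cross + pair_energy(mols[[b]], mols[[a]], params)$e_total
    }
    list(off = off, z_cut = z_cut, e_cross = e_cross, keep = keep)
  })
  e_abs <- vapply(score, function(s) abs(s$e_cross), numeric(1))
  best <- which(abs(e_abs - min(e_abs)) < 1e-9)
  if (length(best) > 1 && is.null(termination_offset)) {
    # tie-break by rugosity
    rugs <- vapply(best, function(bk) {
      sl <- .make_slab(xtal, hkl, mols[score[[bk]]$keep], n_hat, u_c, v_c,
                       patch, d_hkl, score[[bk]]$off)
      topology_map(sl, grid_spacing = 0.5)$rugosity
    }, numeric(1))
    best <- best[which.min(rugs)]
  } else {
    best <- best[1]
  }
  sel <- score[[best]]
  .make_slab(xtal, hkl, mols[sel$keep], n_hat, u_c, v_c, patch, d_hkl, sel$off)
}

.cut_height <- function(heights, off, d_hkl) {
  # highest plane position congruent to `off` (mod d) sitting just above a
  # molecule layer
  z_top <- max(heights)
  z <- z_top + ((off * d_hkl - z_top) %% d_hkl)
  z + 1e-9
}

.make_slab <- function(xtal, hkl, mols, n_hat, u_c, v_c, patch, d_hkl, off) {
  # orthonormal in-plane frame
  e1 <- u_c - sum(u_c * n_hat) * n_hat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n_hat[2] * e1[3] - n_hat[3] * e1[2],
          n_hat[3] * e1[1] - n_hat[1] * e1[3],
          n_hat[1] * e1[2] - n_hat[2] * e1[1])
  cr <- c(u_c[2] * v_c[3] - u_c[3] * v_c[2],
          u_c[3] * v_c[1] - u_c[1] * v_c[3],
          u_c[1] * v_c[2] - u_c[2] * v_c[1])
  structure(list(
    hkl = hkl, d_hkl = d_hkl, n_hat = n_hat, e1 = e1, e2 = e2,
    u_c = u_c, v_c = v_c, patch = patch,
    molecules = mols,
    area = patch^2 * sqrt(sum(cr^2)),
    termination_offset = off
  ), class = "cocryst_slab")
}

#' @export
print.cocryst_slab <- function(x, ...) {
  cat(sprintf("<cocryst_slab (%d %d %d): %d molecules, patch area %.1f A^2, offset %.3f>\n",
              x$hkl[1], x$hkl[2], x$hkl[3], length(x$molecules), x$area,
              x$termination_offset))
  invisible(x)
}

# in-patch membership of a molecule centroid (coefficients in u,v basis)
.patch_coords <- function(slab, point) {
  m <- cbind(slab$u_c, slab$v_c, slab$n_hat)
  drop(solve(m, point))
}

#' Van der Waals height map and rugosity of a slab surface
#'
#' Samples a regular grid over the projected patch; the height at a node is
#' the top of the highest van der Waals sphere above it,
#' `max_i (z_i + sqrt(r_i^2 - rho^2))`, measured along the facet normal and
#' reported relative to the average plane (so the map has zero mean).
#' Rugosity is the RMS height.
#'
#' @param slab a `cocryst_slab`.
#' @param grid_spacing target grid step in Angstrom (default 0.25). The
#'   field is evaluated on a 3x supersampled grid (effective step
#'   `grid_spacing / 3`), which keeps the RMS stable under in-plane
#'   translation of the grid origin.
#' @return a `cocryst_topology` list: `grid` tibble (`s1`, `s2`, `height`),
#'   `rugosity` (Angstrom), `mean_height_abs` (absolute height of the
#'   average plane along the normal), `nx`, `ny`.
#' @export
topology_map <- function(slab, grid_spacing = 0.25) {
  if (length(slab$molecules) == 0) stop("empty slab", call. = FALSE)
  over <- 3L   # supersampling factor for RMS stability
  atoms <- dplyr::bind_rows(lapply(slab$molecules, function(m) m$atoms))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$vdw_radius
  # in-plane orthonormal coordinates and axial heights
  U <- slab$patch * slab$u_c
  V <- slab$patch * slab$v_c
  Up <- c(sum(U * slab$e1), sum(U * slab$e2))
  Vp <- c(sum(V * slab$e1), sum(V * slab$e2))
  p1 <- drop(xyz %*% slab$e1); p2 <- drop(xyz %*% slab$e2)
  z <- drop(xyz %*% slab$n_hat)
  nx <- over * max(4L, ceiling(sqrt(sum(U^2)) / grid_spacing))
  ny <- over * max(4L, ceiling(sqrt(sum(V^2)) / grid_spacing))
  s1v <- (seq_len(nx) - 0.5) / nx
  s2v <- (seq_len(ny) - 0.5) / ny
  hmap <- matrix(-Inf, nx, ny)
  # affine map grid(s1,s2) -> plane Cartesian; invert for window lookup
  m2 <- cbind(Up, Vp)
  m2inv <- solve(m2)
  smin <- min(svd(m2)$d)
  # periodic in-plane images so spheres wrap across patch edges
  for (sa in -1:1) for (sb in -1:1) {
    for (a in seq_along(z)) {
      sc <- drop(m2inv %*% c(p1[a], p2[a])) + c(sa, sb)
      srad <- r[a] / smin
      i1 <- max(1L, ceiling((sc[1] - srad) * nx + 0.5))
      i2 <- min(nx, floor((sc[1] + srad) * nx + 0.5))
      j1 <- max(1L, ceiling((sc[2] - srad) * ny + 0.5))
      j2 <- min(ny, floor((sc[2] + srad) * ny + 0.5))
      if (i1 > i2 || j1 > j2) next
      ss1 <- s1v[i1:i2]; ss2 <- s2v[j1:j2]
      gx <- outer(ss1 * Up[1], ss2 * Vp[1], "+")
      gy <- outer(ss1 * Up[2], ss2 * Vp[2], "+")
      ax <- p1[a] + sa * Up[1] + sb * Vp[1]
      ay <- p2[a] + sa * Up[2] + sb * Vp[2]
      rho2 <- (gx - ax)^2 + (gy - ay)^2
      inside <- rho2 < r[a]^2
      if (any(inside)) {
        cand <- z[a] + sqrt(pmax(r[a]^2 - rho2, 0))
        sub <- hmap[i1:i2, j1:j2]
        sub[inside] <- pmax(sub[inside], cand[inside])
        hmap[i1:i2, j1:j2] <- sub
      }
    }
  }
  ok <- is.finite(hmap)
  mean_h <- mean(hmap[ok])
  rel <- hmap - mean_h
  rel[!ok] <- NA
  sgrid <- expand.grid(s1 = s1v, s2 = s2v)
  structure(list(
    grid = tibble::tibble(s1 = sgrid$s1, s2 = sgrid$s2,
                          height = as.vector(rel)),
    rugosity = sqrt(mean(rel[ok]^2)),
    mean_height_abs = mean_h,
    nx = nx, ny = ny,
    gx = sgrid$s1 * Up[1] + sgrid$s2 * Vp[1],
    gy = sgrid$s1 * Up[2] + sgrid$s2 * Vp[2],
    abs_height = as.vector(hmap)
  ), class = "cocryst_topology")
}

#' @export
print.cocryst_topology <- function(x, ...) {
  cat(sprintf("<cocryst_topology: %dx%d grid, rugosity %.3f A>\n",
              x$nx, x$ny, x$rugosity))
  invisible(x)
}

#' Surface densities of H-bond donors, acceptors and aromatic bonds
#'
#' Counts donor hydrogens, acceptor heavy atoms, and aromatic bonds exposed
#' at the surface (an atom is exposed when its vdW top, `z + r_vdw`, reaches
#' within `exposure_depth` of the topmost van der Waals surface of the
#' patch), restricted to molecules whose centroid lies in the projected
#' patch, divided by the projected patch area. These are the
#' counts/Angstrom^2 surface-chemistry measures; an aromatic bond counts
#' when either of its atoms is exposed.
#'
#' @param slab a `cocryst_slab`.
#' @param exposure_depth depth below the local top surface counted as
#'   exposed (Angstrom, default 3.0).
#' @param map optional precomputed [topology_map()] (default computes one at
#'   0.25 Angstrom).
#' @return one-row tibble: `hbd_density`, `hba_density`, `aromatic_density`
#'   (counts/Angstrom^2), `rugosity`, `exposure_depth`, `area`, plus raw
#'   counts `n_hbd`, `n_hba`, `n_aromatic_bonds`.
#' @export
bond_densities <- function(slab, exposure_depth = 3.0, map = NULL) {
  stopifnot(exposure_depth > 0)
  if (is.null(map)) map <- topology_map(slab, grid_spacing = 0.25)
  # the slab is periodic in-plane: membership is modulo the patch period so
  # each lattice image counts exactly once per surface cell
  in_patch <- vapply(slab$molecules, function(m) {
    pc <- .patch_coords(slab, mol_centroid(m)) %% slab$patch
    pc[pc > slab$patch - 1e-6] <- 0   # snap boundary wrap-around
    pc[1] < slab$patch - 1e-6 && pc[2] < slab$patch - 1e-6
  }, logical(1))
  top <- max(map$abs_height[is.finite(map$abs_height)])
  n_hbd <- 0L; n_hba <- 0L; n_arb <- 0L
  for (m in slab$molecules[in_patch]) {
    m <- .ensure_sites(m)
    xyz <- coords(m)
    z <- drop(xyz %*% slab$n_hat)
    exposed <- z + m$atoms$vdw_radius >= top - exposure_depth
    n_hbd <- n_hbd + sum(exposed[m$hb_sites$donors$h])
    n_hba <- n_hba + sum(exposed[m$hb_sites$acceptors$atom])
    if (nrow(m$bonds)) {
      arb <- m$bonds[m$bonds$order == "aromatic", ]
      if (nrow(arb)) {
        n_arb <- n_arb + sum(exposed[arb$i] | exposed[arb$j])
      }
    }
  }
  tibble::tibble(
    hbd_density = n_hbd / slab$area,
    hba_density = n_hba / slab$area,
    aromatic_density = n_arb / slab$area,
    rugosity = map$rugosity,
    exposure_depth = exposure_depth,
    area = slab$area,
    n_hbd = n_hbd, n_hba = n_hba, n_aromatic_bonds = n_arb
  )
}

#' Facet-specific surface and attachment-energy report
#'
#' One row per facet: aromatic bond density, polar/nonpolar attachment
#' energies (kJ/mol, factor 4.184 exactly), donor/acceptor densities and
#' rugosity. When `observed` facet labels are given, rows are ordered by
#' that list (largest observed facet first), otherwise by relative habit
#' area when available.
#'
#' @param xtal a `cocryst_crystal`.
#' @param facets tibble with `h`, `k`, `l` (e.g. from [enumerate_forms()] or
#'   a habit's facet table).
#' @param params a `cocryst_forcefield`.
#' @param cutoff centroid cutoff for energies (Angstrom).
#' @param exposure_depth passed to [bond_densities()].
#' @param grid_spacing passed to [topology_map()].
#' @param observed optional character vector like `"(0 1 0)"` ordering the
#'   report by the experimental morphology.
#' @return tibble: facet indices, `aromatic_density`, `e_att_nonpolar_kj`,
#'   `hbd_density`, `hba_density`, `e_att_polar_kj`, `rugosity`,
#'   `termination_offset`.
#' @export
surface_report <- function(xtal, facets, params = dreiding_params(),
                           cutoff = 30, exposure_depth = 3.0,
                           grid_spacing = 0.25, observed = NULL) {
  facets <- tibble::as_tibble(facets)
  rows <- purrr::pmap(facets[, c("h", "k", "l")], function(h, k, l) {
    hkl <- c(h, k, l)
    ae <- attachment_energy(xtal, hkl, params, cutoff)
    slab <- cut_slab(xtal, hkl, params = params)
    map <- topology_map(slab, grid_spacing = grid_spacing)
    bd <- bond_densities(slab, exposure_depth, map = map)
    tibble::tibble(
      h = h, k = k, l = l,
      label = sprintf("(%d %d %d)", h, k, l),
      aromatic_density = bd$aromatic_density,
      e_att_nonpolar_kj = ae$e_att_nonpolar_kj,
      hbd_density = bd$hbd_density,
      hba_density = bd$hba_density,
      e_att_polar_kj = ae$e_att_polar_kj,
      e_att_kj = ae$e_att_kj,
      rugosity = map$rugosity,
      termination_offset = slab$termination_offset
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(observed)) {
    ord <- match(observed, out$label)
    out <- dplyr::bind_rows(out[stats::na.omit(ord), ],
                            out[setdiff(seq_len(nrow(out)), ord), ])
  } else if ("relative_area" %in% names(facets)) {
    out$relative_area <- facets$relative_area
    out <- dplyr::arrange(out, dplyr::desc(.data$relative_area))
  }
  out
}
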