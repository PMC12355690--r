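# --- deterministic fixture generators ------------------------------------
# Geometric idealizations of H-bonding planar molecules and their crystals:
# chemically simplified, but with countable donors/acceptors/rings and
# controllable energetics so every pipeline stage has analytic ground truth.

.hexagon <- function(center = c(0, 0), radius = 1.4, phase = 30) {
  ang <- (phase + 60 * (0:5)) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

#' Generate a rigid planar polycyclic molecule with peripheral hydroxyls
#'
#' A linear chain of `n_rings` fused aromatic hexagons (bond length 1.40
#' Angstrom, all atoms in the xy-plane) whose peripheral carbons carry
#' hydrogens except for `n_oh` seeded positions that carry hydroxyl groups
#' (C-O 1.36, O-H 0.96, pointing outward in-plane). Donors and acceptors
#' are countable analytically: `n_oh` donor hydrogens, `n_oh` acceptor
#' oxygens.
#'
#' @param n_oh number of hydroxyl substituents (>= 0).
#' @param n_rings number of fused rings (>= 1).
#' @param seed RNG seed choosing which peripheral positions are substituted.
#' @return a typed, charged `cocryst_molecule`.
#' @export
make_planar_donor_molecule <- function(n_oh = 2, n_rings = 2, seed = 1) {
  stopifnot(n_oh >= 0, n_rings >= 1)
  centers <- cbind(2.4249 * (seq_len(n_rings) - 1), 0)
  verts <- do.call(rbind, lapply(seq_len(n_rings), function(k) {
    .hexagon(centers[k, ])
  }))
  verts <- verts[!duplicated(round(verts, 3)), , drop = FALSE]
  # peripheral = carbons with fewer than 3 carbon neighbours at ring distance
  dmat <- .dist_xyz(cbind(verts, 0), cbind(verts, 0))
  nnb <- rowSums(dmat < 1.5 & dmat > 0.1)
  periph <- which(nnb == 2)
  if (n_oh > length(periph)) {
    stop("infeasible substitution pattern: ", n_oh, " hydroxyls but only ",
         length(periph), " peripheral positions", call. = FALSE)
  }
  set.seed(seed)
  oh_pos <- sort(sample(periph, n_oh))
  atoms <- tibble::tibble(element = rep("C", nrow(verts)),
                          x = verts[, 1], y = verts[, 2], z = 0)
  # outward direction = away from the nearest ring centre
  for (p in periph) {
    cen <- centers[which.min((centers[, 1] - verts[p, 1])^2 +
                               (centers[, 2] - verts[p, 2])^2), ]
    dirv <- c(verts[p, ] - cen, 0)
    dirv <- dirv / sqrt(sum(dirv^2))
    if (p %in% oh_pos) {
      o <- c(verts[p, ], 0) + 1.36 * dirv
      h <- o + 0.96 * dirv
      atoms <- dplyr::bind_rows(atoms,
        tibble::tibble(element = c("O", "H"),
                       x = c(o[1], h[1]), y = c(o[2], h[2]), z = 0))
    } else {
      hh <- c(verts[p, ], 0) + 1.08 * dirv
      atoms <- dplyr::bind_rows(atoms,
        tibble::tibble(element = "H", x = hh[1], y = hh[2], z = 0))
    }
  }
  mol <- perceive_bonds(atoms, name = sprintf("planar_oh%d_r%d", n_oh, n_rings))
  assign_typing(mol)
}

# the ribbon building block: two fused rings extending along +y, with a
# hydroxyl donor on the +x tip and a carbonyl acceptor on the -x tip of the
# lower ring; plane = xy so stacks along z. The upper ring overhangs the
# donor/acceptor row, so facets parallel to the ribbon expose aromatic
# edges while the H-bonding groups sit several Angstrom below the top
# van der Waals surface.
.ribbon_monomer <- function() {
  v <- rbind(.hexagon(c(0, 0), 1.4, phase = 0),
             .hexagon(c(0, 2.4249), 1.4, phase = 0))
  v <- v[!duplicated(round(v, 3)), , drop = FALSE]
  centers <- rbind(c(0, 0), c(0, 2.4249))
  atoms <- tibble::tibble(element = rep("C", nrow(v)),
                          x = v[, 1], y = v[, 2], z = 0)
  # hydroxyl (+x) and carbonyl (-x) on the lower-ring tips
  atoms <- dplyr::bind_rows(
    atoms,
    tibble::tibble(element = "O", x = 1.4 + 1.36, y = 0, z = 0),
    tibble::tibble(element = "H", x = 1.4 + 1.36 + 0.96, y = 0, z = 0),
    tibble::tibble(element = "O", x = -1.4 - 1.23, y = 0, z = 0)
  )
  dmat <- .dist_xyz(cbind(v, 0), cbind(v, 0))
  nnb <- rowSums(dmat < 1.5 & dmat > 0.1)
  for (k in which(nnb == 2)) {
    if (abs(v[k, 2]) < 1e-6 && abs(abs(v[k, 1]) - 1.4) < 1e-6) next  # tips
    cen <- centers[which.min((centers[, 1] - v[k, 1])^2 +
                               (centers[, 2] - v[k, 2])^2), ]
    dirv <- (v[k, ] - cen) / sqrt(sum((v[k, ] - cen)^2))
    atoms <- dplyr::bind_rows(
      atoms,
      tibble::tibble(element = "H", x = v[k, 1] + 1.08 * dirv[1],
                     y = v[k, 2] + 1.08 * dirv[2], z = 0)
    )
  }
  atoms
}

#' Generate a model crystal of H-bonded ribbons with stacking
#'
#' A planar hydroxyl/carbonyl-substituted ring packed so that O-H...O=C
#' hydrogen bonds chain the molecules into ribbons along the a-axis while
#' the rings stack along the c-axis. `spacing_hb` is the donor-acceptor
#' O...O distance, `spacing_stack` the interplanar ring distance, and
#' `cell_padding` the inter-ribbon gap along b. With the default spacings
#' the strongest synthon is the in-ribbon hydrogen bond and the
#' second-strongest the stack; stretching `spacing_hb` and/or scaling the
#' charges down (`charge_scale`) flips the ranking to stacking-dominated.
#'
#' @param spacing_hb donor-acceptor distance (Angstrom, sensible 2.5-4.5).
#' @param spacing_stack ring stacking distance (Angstrom, sensible 3.2-4.0).
#' @param cell_padding inter-ribbon gap along b (Angstrom).
#' @param charge_scale multiplier on the Gasteiger charges (default 1).
#' @param inversion build the P-1 variant (asymmetric unit off-origin,
#'   identity + inversion ops) instead of P1.
#' @param randomize draw the three spacings from their sensible ranges
#'   (seeded) instead of using the supplied values.
#' @param seed RNG seed (used when `randomize = TRUE`).
#' @return a `cocryst_crystal` with typed, charged molecules.
#' @export
make_ribbon_crystal <- function(spacing_hb = 2.75, spacing_stack = 3.5,
                                cell_padding = 4.0, charge_scale = 1,
                                inversion = FALSE, randomize = FALSE,
                                seed = 1) {
  if (randomize) {
    set.seed(seed)
    spacing_hb <- stats::runif(1, 2.6, 3.2)
    spacing_stack <- stats::runif(1, 3.3, 3.9)
    cell_padding <- stats::runif(1, 3.5, 6)
  }
  stopifnot(spacing_hb >= 2.5, spacing_hb <= 4.5,
            spacing_stack >= 3.2, spacing_stack <= 4.0)
  atoms <- .ribbon_monomer()
  mol <- assign_typing(perceive_bonds(atoms, name = "ribbon_monomer"))
  mol$atoms$charge <- mol$atoms$charge * charge_scale
  # donor O sits at x = 2.76, acceptor O at x = -2.63 of the next image
  a_len <- spacing_hb + 2.76 + 2.63
  y_ext <- diff(range(mol$atoms$y)) + 2 * 1.2   # vdW margin
  b_len <- y_ext + cell_padding
  if (inversion) {
    c_len <- 2 * spacing_stack
    cell <- new_unit_cell(a_len, b_len, c_len)
    shift <- drop(c(0.25, 0.25, 0.25) %*% cell$mat)
    mol <- transform_molecule(mol, diag(3), shift)
    xt <- new_crystal(cell, list(mol),
                      list(new_symop(diag(3)), new_symop(-diag(3))), "P-1")
  } else {
    cell <- new_unit_cell(a_len, b_len, spacing_stack)
    xt <- new_crystal(cell, list(mol), space_group_label = "P1")
  }
  .check_no_overlap(xt)
  xt
}

.check_no_overlap <- function(xtal, min_dist = 1.2) {
  mols <- expand_cell(xtal)
  imgs <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    tvec <- drop(c(dx, dy, dz) %*% xtal$cell$mat)
    for (m in mols) imgs <- c(imgs, list(transform_molecule(m, diag(3), tvec)))
  }
  x0 <- coords(mols[[1]])
  for (k in seq_along(imgs)) {
    xi <- coords(imgs[[k]])
    if (nrow(xi) == nrow(x0) && max(abs(xi - x0)) < 1e-6) next  # self
    d <- .dist_xyz(x0, xi)
    if (min(d) < min_dist) {
      stop("overlapping molecules in generated crystal (min distance ",
           sprintf("%.2f", min(d)), " A)", call. = FALSE)
    }
  }
  invisible(xtal)
}

# construct a rigid "box molecule" with prescribed bounding-box axes,
# N+O fraction and dipole: six carbon frame atoms on the principal axes,
# filler atoms near the centre carrying the heteroatom count and charges.
.box_molecule <- function(l_axis, m_axis, s_axis, no_fraction, dipole,
                          name = "box") {
  r_c <- 1.7
  half <- c(l_axis, m_axis, s_axis) / 2 - r_c
  if (any(half <= 0.3) || l_axis < m_axis || m_axis < s_axis) {
    stop("infeasible window combination: requested box ",
         sprintf("%.2f x %.2f x %.2f", l_axis, m_axis, s_axis), call. = FALSE)
  }
  # keep the frame extents strictly ordered for a stable PCA frame
  frame <- rbind(c(half[1], 0, 0), c(-half[1], 0, 0),
                 c(0, half[2], 0), c(0, -half[2], 0),
                 c(0, 0, half[3]), c(0, 0, -half[3]))
  n_fill <- 6
  n_heavy <- 6 + n_fill
  n_no <- round(no_fraction * n_heavy)
  if (n_no > n_fill) {
    stop("infeasible window combination: no_fraction ", no_fraction,
         " needs ", n_no, " heteroatoms but only ", n_fill,
         " filler sites exist", call. = FALSE)
  }
  fill_el <- c(rep("N", n_no), rep("C", n_fill - n_no))
  # small fixed jitter keeps filler atoms distinct and off the frame axes
  fill <- 0.55 * rbind(c(1, 1, 0), c(-1, -1, 0), c(1, -1, 1), c(-1, 1, -1),
                       c(0, 1, 1), c(0, -1, -1))[seq_len(n_fill), , drop = FALSE]
  q <- dipole / .DEBYE_PER_EA / (2 * half[1])
  charges <- c(q, -q, rep(0, 4 + n_fill))
  atoms <- tibble::tibble(
    element = c(rep("C", 6), fill_el),
    x = c(frame[, 1], fill[, 1]),
    y = c(frame[, 2], fill[, 2]),
    z = c(frame[, 3], fill[, 3]),
    charge = charges
  )
  new_molecule(atoms, NULL, name = name)
}

#' Generate a coformer library with planted PASS/FAIL ground truth
#'
#' Constructs `n` rigid box molecules whose five complementarity
#' descriptors are planted relative to the target's: `n_pass` members sit
#' well inside every PASS window (at 30% of the window width), the rest are
#' pushed outside at least one window (at 160% of its width, cycling
#' through the descriptors). The planted flags are verified against
#' [mc_screen()] at construction time.
#'
#' @param n library size.
#' @param n_pass number of members inside all windows (0 <= n_pass <= n).
#' @param target target molecule (default [make_planar_donor_molecule()]).
#' @param thresholds PASS windows (see [mc_default_thresholds()]).
#' @param seed RNG seed for the in-window offsets.
#' @return list: `library` (list of molecules), `truth` (tibble with
#'   `coformer`, `planted_pass`), `target`.
#' @export
make_coformer_library <- function(n = 20, n_pass = 8,
                                  target = make_planar_donor_molecule(3, 2),
                                  thresholds = mc_default_thresholds(),
                                  seed = 1) {
  stopifnot(n_pass >= 0, n_pass <= n)
  set.seed(seed)
  td <- mc_descriptors(target)
  win <- stats::setNames(thresholds$window, thresholds$descriptor)
  desc_names <- c("s_axis", "s_over_l", "m_over_l", "no_fraction", "dipole")
  lib <- list(); truth <- list()
  for (k in seq_len(n)) {
    pass <- k <= n_pass
    off <- stats::runif(5, -0.3, 0.3) * win[desc_names]
    want <- unlist(td[desc_names]) + off
    if (!pass) {
      bad <- desc_names[(k - n_pass - 1) %% 5 + 1]
      want[bad] <- unlist(td[[bad]]) + 1.6 * win[bad] *
        if (bad %in% c("no_fraction", "s_over_l", "m_over_l") &&
            unlist(td[[bad]]) + 1.6 * win[bad] > 0.98) -1 else 1
    }
    # feasibility clamps for the frame construction (box axes need > 2 r_C
    # plus a margin; strict axis ordering keeps the PCA frame stable)
    want["s_axis"] <- max(want["s_axis"], 4.1)
    want["s_over_l"] <- min(max(want["s_over_l"], 0.08), 0.85)
    want["m_over_l"] <- min(max(want["m_over_l"], want["s_over_l"] + 0.05), 0.97)
    want["no_fraction"] <- min(max(want["no_fraction"], 0), 0.5)
    want["dipole"] <- max(want["dipole"], 0)
    l_axis <- want["s_axis"] / want["s_over_l"]
    m_axis <- want["m_over_l"] * l_axis
    mol <- .box_molecule(l_axis, m_axis, want["s_axis"],
                         want["no_fraction"], want["dipole"],
                         name = sprintf("coformer_%02d", k))
    lib <- c(lib, list(mol))
    truth[[k]] <- tibble::tibble(coformer = mol$name, planted_pass = pass)
  }
  truth <- dplyr::bind_rows(truth)
  got <- mc_screen(target, lib, thresholds)
  ok <- (got$overall == "PASS") == truth$planted_pass
  if (!all(ok)) {
    stop("library construction failed to realize planted flags for: ",
         paste(truth$coformer[!ok], collapse = ", "), call. = FALSE)
  }
  list(library = lib, truth = truth, target = target)
}

#' Generate a propensity table with a planted positive-score count
#'
#' Long-format donor/acceptor propensity entries for a target plus
#' `n_pairs` coformers, constructed so that exactly `n_positive_delta`
#' coformers have a strictly positive propensity difference. Each pair gets
#' one or two heteromeric rows and a homomeric row per component.
#'
#' @param n_pairs number of coformers.
#' @param n_positive_delta how many must score strictly positive.
#' @param seed RNG seed.
#' @param target target molecule name (default "target").
#' @return list: `table` (tibble: `donor_group`, `acceptor_group`, `mol_a`,
#'   `mol_b`, `propensity`), `expected` (tibble: `coformer`,
#'   `delta_expected`).
#' @export
make_propensity_table <- function(n_pairs = 56, n_positive_delta = 18,
                                  seed = 1, target = "target") {
  stopifnot(n_positive_delta >= 0, n_positive_delta <= n_pairs)
  set.seed(seed)
  p_tt <- 0.45
  rows <- list(tibble::tibble(donor_group = "OH", acceptor_group = "C=O",
                              mol_a = target, mol_b = target,
                              propensity = p_tt))
  expected <- list()
  for (k in seq_len(n_pairs)) {
    cf <- sprintf("cf%02d", k)
    p_cc <- round(stats::runif(1, 0.20, 0.60), 3)
    p_homo <- max(p_tt, p_cc)
    if (k <= n_positive_delta) {
      delta <- round(stats::runif(1, 0.02, min(0.30, 0.98 - p_homo)), 3)
    } else {
      delta <- -round(stats::runif(1, 0.02, min(0.30, p_homo - 0.02)), 3)
    }
    p_het <- p_homo + delta
    rows <- c(rows, list(
      tibble::tibble(donor_group = "OH", acceptor_group = "Nsp2",
                     mol_a = target, mol_b = cf, propensity = p_het),
      tibble::tibble(donor_group = "NH", acceptor_group = "C=O",
                     mol_a = target, mol_b = cf,
                     propensity = round(max(0.01, p_het / 2), 3)),
      tibble::tibble(donor_group = "NH", acceptor_group = "Nsp2",
                     mol_a = cf, mol_b = cf, propensity = p_cc)
    ))
    expected[[k]] <- tibble::tibble(coformer = cf, delta_expected = delta)
  }
  list(table = dplyr::bind_rows(rows),
       expected = dplyr::bind_rows(expected))
}

#' Write pipeline fixtures to standard files
#'
#' Convenience wrapper used by the workflow: writes a ribbon crystal CIF, a
#' coformer library SDF and a propensity TSV into a directory.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed forwarded to the generators.
#' @return invisible named list of written paths.
#' @export
write_fixture_set <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xt <- make_ribbon_crystal(seed = seed)
  cif <- file.path(dir, "ribbon.cif")
  write_cif(xt, cif)
  lib <- make_coformer_library(seed = seed)
  sdf <- file.path(dir, "library.sdf")
  write_sdf(lib$library, sdf)
  pt <- make_propensity_table(seed = seed)
  tsv <- file.path(dir, "propensities.tsv")
  utils::write.table(pt$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(cif = cif, sdf = sdf, propensities = tsv))
}
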