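#' Perceive bonds, rings and aromaticity from 3D coordinates
#'
#' Bonds are assigned between atoms i, j when their distance is below
#' `covalent_radius(i) + covalent_radius(j) + tol`. Ring systems are detected
#' on the bond graph (smallest ring through each cyclic edge); a ring is
#' flagged aromatic when it is planar (RMS out-of-plane < 0.1 Angstrom) and
#' every ring atom is sp2-capable (trigonal C, di-/tri-coordinate N). Ether
#' oxygens in a ring keep the ring non-aromatic, so a pyranone ring is
#' detected as a ring but not flagged aromatic.
#'
#' @param atoms a data frame with `element`, `x`, `y`, `z` (and optionally
#'   `charge`), or a `cocryst_molecule` whose bonds should be re-perceived.
#' @param tol bond-distance tolerance in Angstrom (default 0.4).
#' @param name molecule name.
#' @return a `cocryst_molecule` with bonds, rings and aromatic flags.
#' @export
perceive_bonds <- function(atoms, tol = 0.4, name = "mol") {
  if (inherits(atoms, "cocryst_molecule")) {
    name <- atoms$name
    atoms <- atoms$atoms
  }
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  stopifnot(n >= 1)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (n == 1) return(new_molecule(atoms, NULL, name))

  d <- .dist_xyz(xyz, xyz)
  diag(d) <- Inf
  if (any(d < 0.5)) {
    idx <- which(d < 0.5, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop("atom clash (< 0.5 A) between atoms: ",
         paste(apply(idx, 1, paste, collapse = "-"), collapse = ", "),
         call. = FALSE)
  }
  rcov <- covalent_radius(atoms$element)
  cut <- outer(rcov, rcov, "+") + tol
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  bonds <- tibble::tibble(
    i = as.integer(hit[, 1]), j = as.integer(hit[, 2]),
    order = .bond_order_guess(atoms$element[hit[, 1]], atoms$element[hit[, 2]],
                              d[hit])
  )
  mol <- new_molecule(atoms, bonds, name)
  .detect_rings(mol)
}

# crude distance-based bond order assignment; refined to "aromatic" for
# bonds inside aromatic rings by .detect_rings()
.bond_order_guess <- function(el_a, el_b, dist) {
  pair <- paste(pmin(el_a, el_b), pmax(el_a, el_b))
  order <- rep("single", length(dist))
  order[pair == "C C" & dist < 1.38] <- "double"
  order[pair == "C C" & dist < 1.22] <- "triple"
  order[pair == "C O" & dist < 1.28] <- "double"
  order[pair == "C N" & dist < 1.32] <- "double"
  order[pair == "N N" & dist < 1.28] <- "double"
  order[pair == "N O" & dist < 1.25] <- "double"
  order
}

.mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    data.frame(from = mol$bonds$i, to = mol$bonds$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# Smallest ring through each cyclic edge; deduplicated by atom set.
.detect_rings <- function(mol, max_ring = 8) {
  mol$rings <- list()
  mol$ring_aromatic <- logical()
  if (nrow(mol$bonds) == 0) return(mol)
  g <- .mol_graph(mol)
  seen <- character()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = as.character(i), to = as.character(j))
    )$vpath[[1]]
    if (length(sp) == 0 || length(sp) > max_ring) next
    ring <- as.integer(igraph::as_ids(sp))
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    mol$rings <- c(mol$rings, list(ring))
  }
  mol$ring_aromatic <- vapply(mol$rings, .is_aromatic_ring, logical(1),
                              mol = mol)
  # upgrade in-ring bonds of aromatic rings
  if (any(mol$ring_aromatic)) {
    arom_atoms <- unlist(mol$rings[mol$ring_aromatic])
    for (r in mol$rings[mol$ring_aromatic]) {
      cyc <- c(r, r[1])
      for (t in seq_len(length(r))) {
        sel <- (mol$bonds$i == cyc[t] & mol$bonds$j == cyc[t + 1]) |
               (mol$bonds$j == cyc[t] & mol$bonds$i == cyc[t + 1])
        mol$bonds$order[sel] <- "aromatic"
      }
    }
  }
  mol
}

.ring_planarity_rms <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(c0)
  normal <- sv$v[, 3]
  sqrt(mean((c0 %*% normal)^2))
}

.is_aromatic_ring <- function(ring, mol) {
  if (length(ring) < 5 || length(ring) > 7) return(FALSE)
  xyz <- coords(mol)[ring, , drop = FALSE]
  if (.ring_planarity_rms(xyz) >= 0.1) return(FALSE)
  deg <- .atom_degree(mol)
  for (a in ring) {
    el <- mol$atoms$element[a]
    ok <- (el == "C" && deg[a] <= 3) || (el == "N" && deg[a] <= 3)
    if (!ok) return(FALSE)
  }
  # exclude rings whose carbons carry sp3-like coordination (4 neighbours)
  TRUE
}

.atom_degree <- function(mol) {
  deg <- integer(nrow(mol$atoms))
  tab <- table(c(mol$bonds$i, mol$bonds$j))
  deg[as.integer(names(tab))] <- as.integer(tab)
  deg
}

.neighbors_of <- function(mol, a) {
  c(mol$bonds$j[mol$bonds$i == a], mol$bonds$i[mol$bonds$j == a])
}

#' Split a molecule into connected components
#'
#' @param mol a `cocryst_molecule` with perceived bonds.
#' @return list of `cocryst_molecule`, one per connected component, in order
#'   of each component's lowest atom index.
#' @export
molecule_components <- function(mol) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0) {
    comp <- seq_len(n)
  } else {
    g <- .mol_graph(mol)
    comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  }
  split_idx <- split(seq_len(n), comp)
  purrr::imap(unname(split_idx), function(idx, k) {
    sub_atoms <- mol$atoms[idx, ]
    remap <- match(seq_len(n), idx)
    keep <- mol$bonds$i %in% idx & mol$bonds$j %in% idx
    sub_bonds <- mol$bonds[keep, ]
    sub_bonds$i <- remap[sub_bonds$i]
    sub_bonds$j <- remap[sub_bonds$j]
    m <- new_molecule(sub_atoms, sub_bonds, paste0(mol$name, "_", k))
    .detect_rings(m)
  })
}
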