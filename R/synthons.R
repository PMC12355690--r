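#' Classify a molecule-molecule contact by interaction type
#'
#' Precedence H-bond > pi-pi stacking > offset stacking > vdW/other:
#' \itemize{
#'   \item "H-bond": at least one donor-H...acceptor contact with
#'     `r(H...A) < 2.5` Angstrom and D-H...A angle > 120 degrees;
#'   \item "pi-pi stacking": two aromatic ring centroids < 4.0 Angstrom
#'     apart, interplanar angle < 20 degrees, lateral offset < 1.5 Angstrom;
#'   \item "offset stacking": centroids < 6.5 Angstrom, angle < 20 degrees,
#'     offset >= 1.5 Angstrom;
#'   \item otherwise "vdW/other".
#' }
#'
#' @param mol_a,mol_b typed `cocryst_molecule`s with perceived rings.
#' @return a single type label string.
#' @export
classify_interaction <- function(mol_a, mol_b) {
  mol_a <- .ensure_sites(mol_a); mol_b <- .ensure_sites(mol_b)
  xa <- coords(mol_a); xb <- coords(mol_b)
  # H-bond test
  has_hb <- function(don, xd, acc, xacc) {
    if (nrow(don$donors) == 0 || nrow(acc$acceptors) == 0) return(FALSE)
    for (t in seq_len(nrow(don$donors))) {
      hpos <- xd[don$donors$h[t], ]; dpos <- xd[don$donors$heavy[t], ]
      for (u in seq_len(nrow(acc$acceptors))) {
        apos <- xacc[acc$acceptors$atom[u], ]
        r_ha <- sqrt(sum((hpos - apos)^2))
        if (r_ha >= 2.5) next
        v1 <- dpos - hpos; v2 <- apos - hpos
        cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
        if (ang > 120) return(TRUE)
      }
    }
    FALSE
  }
  if (has_hb(mol_a$hb_sites, xa, mol_b$hb_sites, xb) ||
      has_hb(mol_b$hb_sites, xb, mol_a$hb_sites, xa)) {
    return("H-bond")
  }
  # stacking tests on aromatic ring pairs
  ring_geo <- function(mol, xyz) {
    rings <- mol$rings[mol$ring_aromatic]
    purrr::map(rings, function(r) {
      rc <- xyz[r, , drop = FALSE]
      cen <- colMeans(rc)
      sv <- svd(sweep(rc, 2, cen))
      list(cen = cen, normal = sv$v[, 3])
    })
  }
  ga <- ring_geo(mol_a, xa); gb <- ring_geo(mol_b, xb)
  best <- "vdW/other"
  for (ra in ga) for (rb in gb) {
    v <- rb$cen - ra$cen
    dist <- sqrt(sum(v^2))
    if (dist >= 6.5) next
    cang <- abs(sum(ra$normal * rb$normal))
    ang <- acos(pmin(1, cang)) * 180 / pi
    if (ang >= 20) next
    offset <- sqrt(max(0, dist^2 - sum(v * ra$normal)^2))
    if (dist < 4.0 && offset < 1.5) return("pi-pi stacking")
    if (offset >= 1.5) best <- "offset stacking"
  }
  best
}

#' Rank the supramolecular synthons of a crystal
#'
#' Computes every reference-molecule/environment-partner interaction within
#' the cutoff, merges symmetry-equivalent pairs (identical `|e_total|`
#' within `group_tol` and identical centroid distance), classifies each
#' synthon, and sorts by `|e_total|` descending with ties broken by centroid
#' distance ascending then partner id. Percentages are taken against the
#' intermolecular lattice energy (sum over the asymmetric unit).
#'
#' @param xtal a `cocryst_crystal`.
#' @param params a `cocryst_forcefield`.
#' @param cutoff centroid cutoff (Angstrom).
#' @param min_abs_energy drop merged synthons weaker than this (kcal/mol,
#'   default 0.05 to keep reports readable; set 0 for everything).
#' @param group_tol energy tolerance for symmetry grouping (default 1e-6).
#' @return a `cocryst_synthons` tibble: `rank`, `ref`, `partner`,
#'   `type_label`, `centroid_distance`, `e_vdw`, `e_coul`, `e_hb`,
#'   `e_total`, `multiplicity`, `percent_of_lattice`; attribute
#'   `e_lattice_total` carries the reference lattice energy, attribute
#'   `pairs` the ungrouped flat pair list.
#' @export
rank_synthons <- function(xtal, params = dreiding_params(), cutoff = 30,
                          min_abs_energy = 0.05, group_tol = 1e-6) {
  xtal <- .ensure_typed(xtal)
  pair_rows <- list()
  for (ri in seq_along(xtal$asym_molecules)) {
    env <- build_environment(xtal, ref = ri, cutoff = cutoff)
    ref_mol <- xtal$asym_molecules[[ri]]
    for (k in seq_len(nrow(env))) {
      e <- pair_energy(ref_mol, env$mol[[k]], params)
      pair_rows[[length(pair_rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(ref = ri, partner_asym = env$asym_id[k],
                       partner_op = env$op_id[k],
                       tx = env$tx[k], ty = env$ty[k], tz = env$tz[k],
                       centroid_distance = env$centroid_distance[k],
                       partner_mol = env$mol[k]),
        e
      )
    }
  }
  pairs <- dplyr::bind_rows(pair_rows)
  e_lat <- sum(pairs$e_total) / 2

  # symmetry grouping: equal |e_total| and centroid distance
  pairs$grp <- paste(round(abs(pairs$e_total) / group_tol),
                     round(pairs$centroid_distance / 1e-4))
  grouped <- pairs |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(
      ref = min(.data$ref),
      partner = paste0("mol", min(.data$partner_asym), "/op",
                       .data$partner_op[which.min(.data$partner_asym)]),
      centroid_distance = .data$centroid_distance[1],
      e_vdw = .data$e_vdw[1], e_coul = .data$e_coul[1], e_hb = .data$e_hb[1],
      e_total = .data$e_total[1],
      multiplicity = dplyr::n(),
      first_idx = which.max(seq_along(.data$e_total) == 1),
      row_id = dplyr::cur_group_id(),
      .groups = "drop"
    )
  # classify using one representative pair per group
  rep_idx <- match(grouped$grp, pairs$grp)
  grouped$type_label <- vapply(rep_idx, function(k) {
    classify_interaction(xtal$asym_molecules[[pairs$ref[k]]],
                         pairs$partner_mol[[k]])
  }, character(1))
  grouped <- grouped[abs(grouped$e_total) >= min_abs_energy, ]
  grouped <- dplyr::arrange(grouped, dplyr::desc(abs(.data$e_total)),
                            .data$centroid_distance, .data$partner)
  out <- tibble::tibble(
    rank = seq_len(nrow(grouped)),
    ref = grouped$ref,
    partner = grouped$partner,
    type_label = grouped$type_label,
    centroid_distance = grouped$centroid_distance,
    e_vdw = grouped$e_vdw, e_coul = grouped$e_coul, e_hb = grouped$e_hb,
    e_total = grouped$e_total,
    multiplicity = grouped$multiplicity,
    percent_of_lattice = 100 * grouped$e_total / e_lat
  )
  class(out) <- c("cocryst_synthons", class(out))
  attr(out, "e_lattice_total") <- e_lat
  attr(out, "pairs") <- pairs[, setdiff(names(pairs), c("partner_mol", "grp"))]
  out
}

#' Aggregate synthon energies by interaction class
#'
#' Sums `|e_total|` and the percent-of-lattice contributions per interaction
#' class. Fine labels are coarsened: "H-bond" stays its own class;
#' "pi-pi stacking" and "offset stacking" merge into "stacking"; everything
#' else is "other". Grand totals are appended as class "total".
#'
#' @param ranking a tibble with `type_label`, `e_total` and (optionally)
#'   `percent_of_lattice` — a [rank_synthons()] result or a printed synthon
#'   table read from file.
#' @return tibble: `class`, `n`, `e_abs_total` (kcal/mol),
#'   `percent_total`.
#' @export
aggregate_by_type <- function(ranking) {
  ranking <- tibble::as_tibble(ranking)
  if (nrow(ranking) == 0) {
    return(tibble::tibble(class = "total", n = 0L, e_abs_total = 0,
                          percent_total = 0))
  }
  lab <- ranking$type_label
  cls <- dplyr::case_when(
    grepl("H-bond", lab, ignore.case = TRUE) ~ "H-bond",
    grepl("stack", lab, ignore.case = TRUE) ~ "stacking",
    TRUE ~ "other"
  )
  pct <- if ("percent_of_lattice" %in% names(ranking))
    ranking$percent_of_lattice else rep(NA_real_, nrow(ranking))
  per <- tibble::tibble(class = cls, e = abs(ranking$e_total), pct = pct) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(), e_abs_total = sum(.data$e),
                     percent_total = sum(.data$pct), .groups = "drop")
  dplyr::bind_rows(
    per,
    tibble::tibble(class = "total", n = nrow(ranking),
                   e_abs_total = sum(abs(ranking$e_total)),
                   percent_total = sum(pct))
  )
}

#' Decompose the lattice energy by functional group
#'
#' Every atom-pair energy term is attributed half to each participating
#' atom's group (hydrogen-bond terms half to donor heavy atom, half to
#' acceptor); partner-image atoms map back to their asymmetric-unit source
#' atoms. Group sums therefore add up to the lattice energy exactly.
#'
#' @param xtal a `cocryst_crystal`.
#' @param params a `cocryst_forcefield`.
#' @param cutoff centroid cutoff (Angstrom).
#' @param grouping list with one character vector per asymmetric-unit
#'   molecule assigning each atom to a functional-group label (or a single
#'   vector when Z' = 1). Every atom must be assigned.
#' @return tibble: `group`, `e_vdw`, `e_coul`, `e_hb`, `e_total` (kcal/mol);
#'   attribute `e_lattice_total`.
#' @export
group_decomposition <- function(xtal, params = dreiding_params(), cutoff = 30,
                                grouping) {
  xtal <- .ensure_typed(xtal)
  if (!is.list(grouping)) grouping <- list(grouping)
  stopifnot(length(grouping) == length(xtal$asym_molecules))
  for (mi in seq_along(grouping)) {
    na <- nrow(xtal$asym_molecules[[mi]]$atoms)
    g <- grouping[[mi]]
    if (length(g) != na || anyNA(g)) {
      g2 <- rep(NA_character_, na)
      g2[seq_len(min(na, length(g)))] <- g[seq_len(min(na, length(g)))]
      stop("unassigned atoms in molecule ", mi, ": ",
           paste(which(is.na(g2)), collapse = ", "), call. = FALSE)
    }
  }
  acc <- list()
  add <- function(group, kind, e) {
    for (k in seq_along(group)) {
      key <- group[k]
      if (is.null(acc[[key]])) {
        acc[[key]] <<- c(e_vdw = 0, e_coul = 0, e_hb = 0)
      }
      acc[[key]][kind] <<- acc[[key]][kind] + e[k]
    }
  }
  for (ri in seq_along(xtal$asym_molecules)) {
    env <- build_environment(xtal, ref = ri, cutoff = cutoff)
    ref_mol <- xtal$asym_molecules[[ri]]
    g_ref <- grouping[[ri]]
    for (k in seq_len(nrow(env))) {
      pm <- env$mol[[k]]
      g_par <- grouping[[env$asym_id[k]]]
      e <- pair_energy(ref_mol, pm, params, detail = TRUE)
      tm <- attr(e, "terms")
      # half to each side, and the overall 1/2 lattice factor
      row_v <- rowSums(tm$e_vdw_mat) / 4; col_v <- colSums(tm$e_vdw_mat) / 4
      row_c <- rowSums(tm$e_coul_mat) / 4; col_c <- colSums(tm$e_coul_mat) / 4
      add(g_ref, "e_vdw", row_v); add(g_par, "e_vdw", col_v)
      add(g_ref, "e_coul", row_c); add(g_par, "e_coul", col_c)
      hb <- tm$hb
      for (t in seq_len(nrow(hb))) {
        if (hb$donor_in_a[t]) {
          add(g_ref[hb$d_idx[t]], "e_hb", hb$e[t] / 4)
          add(g_par[hb$a_idx[t]], "e_hb", hb$e[t] / 4)
        } else {
          add(g_par[hb$d_idx[t]], "e_hb", hb$e[t] / 4)
          add(g_ref[hb$a_idx[t]], "e_hb", hb$e[t] / 4)
        }
      }
    }
  }
  out <- purrr::imap(acc, function(v, key) {
    tibble::tibble(group = key, e_vdw = v["e_vdw"], e_coul = v["e_coul"],
                   e_hb = v["e_hb"], e_total = sum(v))
  }) |> dplyr::bind_rows()
  attr(out, "e_lattice_total") <- sum(out$e_total)
  out
}
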