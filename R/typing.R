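#' Assign Dreiding-style atom types and partial charges
#'
#' Atom types follow the Dreiding convention (element + hybridization:
#' `C_3`, `C_R`, `C_2`, `C_1`, `N_3`, `N_R`, `N_2`, `O_3`, `O_2`, `H_`,
#' `H__HB`, ...). Hybridization is inferred from coordination number, bond
#' orders and aromatic-ring membership; hydrogens bonded to N or O get the
#' hydrogen-bonding type `H__HB`. Partial charges default to iterative
#' Gasteiger-style partial equalization of orbital electronegativity (PEOE);
#' the transfer is antisymmetric per bond so the net molecular charge is
#' preserved exactly.
#'
#' @param mol a `cocryst_molecule` with perceived bonds.
#' @param charge_scheme "gasteiger" (default) or "none" (keep charges as-is).
#' @param n_iter PEOE damping iterations (default 8).
#' @return the molecule with `ff_type` and `charge` columns filled.
#' @export
assign_typing <- function(mol, charge_scheme = c("gasteiger", "none"),
                          n_iter = 8) {
  charge_scheme <- match.arg(charge_scheme)
  n <- nrow(mol$atoms)
  deg <- .atom_degree(mol)
  el <- mol$atoms$element
  arom <- logical(n)
  if (length(mol$rings)) {
    arom[unlist(mol$rings[mol$ring_aromatic])] <- TRUE
  }
  has_double <- logical(n)
  dbl <- mol$bonds[mol$bonds$order %in% c("double", "triple"), ]
  has_double[c(dbl$i, dbl$j)] <- TRUE

  ff <- character(n)
  for (a in seq_len(n)) {
    ff[a] <- switch(
      el[a],
      H = {
        nb <- .neighbors_of(mol, a)
        if (length(nb) && any(el[nb] %in% c("N", "O", "F"))) "H__HB" else "H_"
      },
      C = if (arom[a]) "C_R"
          else if (deg[a] >= 4) "C_3"
          else if (deg[a] == 3 || has_double[a]) "C_2"
          else if (deg[a] == 2) "C_1"
          else "C_3",
      N = if (arom[a]) "N_R"
          else if (deg[a] <= 1) "N_1"
          else if (deg[a] == 2 || has_double[a] || .is_planar_center(mol, a)) "N_2"
          else "N_3",
      O = if (deg[a] <= 1 && has_double[a]) "O_2" else "O_3",
      S = "S_3", F = "F_", Cl = "Cl", Br = "Br", I = "I_",
      Ar = "Ar",
      stop("unsupported element for Dreiding typing: ", el[a], call. = FALSE)
    )
  }
  mol$atoms$ff_type <- ff
  if (charge_scheme == "gasteiger") {
    mol$atoms$charge <- .gasteiger_charges(mol, n_iter = n_iter)
  }
  mol
}

.is_planar_center <- function(mol, a) {
  nb <- .neighbors_of(mol, a)
  if (length(nb) < 3) return(FALSE)
  xyz <- coords(mol)[c(a, nb[1:3]), ]
  v1 <- xyz[2, ] - xyz[1, ]; v2 <- xyz[3, ] - xyz[1, ]; v3 <- xyz[4, ] - xyz[1, ]
  nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
           v1[3] * v2[1] - v1[1] * v2[3],
           v1[1] * v2[2] - v1[2] * v2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  abs(sum(v3 * nrm)) / sqrt(sum(v3^2)) < 0.15
}

# PEOE orbital electronegativity parameters (a, b, c), by Gasteiger class.
.peoe_params <- list(
  H      = c(7.17, 6.24, -0.56),
  C_sp3  = c(7.98, 9.18, 1.88),
  C_sp2  = c(8.79, 9.32, 1.51),
  C_sp   = c(10.39, 9.45, 0.73),
  N_sp3  = c(11.54, 10.82, 1.36),
  N_sp2  = c(12.87, 11.15, 0.85),
  N_sp   = c(15.68, 11.70, -0.27),
  O_sp3  = c(14.18, 12.92, 1.39),
  O_sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S_sp3  = c(10.14, 9.13, 1.38)
)

.peoe_class <- function(ff_type) {
  map <- c(H_ = "H", H__HB = "H",
           C_3 = "C_sp3", C_R = "C_sp2", C_2 = "C_sp2", C_1 = "C_sp",
           N_3 = "N_sp3", N_R = "N_sp2", N_2 = "N_sp2", N_1 = "N_sp",
           O_3 = "O_sp3", O_R = "O_sp3", O_2 = "O_sp2",
           F_ = "F", Cl = "Cl", Br = "Br", I_ = "I", S_3 = "S_sp3",
           Ar = "Cl")  # inert placeholder; charges stay ~0 anyway
  cls <- map[ff_type]
  if (anyNA(cls)) {
    stop("no PEOE parameters for type(s): ",
         paste(unique(ff_type[is.na(cls)]), collapse = ", "), call. = FALSE)
  }
  cls
}

.gasteiger_charges <- function(mol, n_iter = 8) {
  n <- nrow(mol$atoms)
  if (nrow(mol$bonds) == 0) return(mol$atoms$charge)
  cls <- .peoe_class(mol$atoms$ff_type)
  par <- do.call(rbind, .peoe_params[cls])
  q <- rep(0, n)
  bi <- mol$bonds$i; bj <- mol$bonds$j
  # cation electronegativity (chi at q = +1); H uses the standard 20.02
  chi_plus <- rowSums(par)
  chi_plus[cls == "H"] <- 20.02
  for (k in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    damp <- 0.5^k
    dq <- numeric(n)
    lo <- ifelse(chi[bi] <= chi[bj], bi, bj)
    hi <- ifelse(chi[bi] <= chi[bj], bj, bi)
    transfer <- (chi[hi] - chi[lo]) / chi_plus[lo] * damp
    for (b in seq_along(bi)) {
      dq[lo[b]] <- dq[lo[b]] + transfer[b]
      dq[hi[b]] <- dq[hi[b]] - transfer[b]
    }
    q <- q + dq
  }
  q
}

#' Inventory hydrogen-bond donors and acceptors
#'
#' Donors are hydrogen atoms bonded to N or O (reported with their heavy
#' atom). Acceptors are N/O atoms with an available lone pair: any oxygen
#' (hydroxyl O counts as both donor-bearing and acceptor, as do carbonyl and
#' ether O), and nitrogens without a bonded hydrogen (pyridine-type sp2 N,
#' sp3 amine N). A pyrrole-type N-H contributes its H as donor but is not an
#' acceptor.
#'
#' @param mol a typed `cocryst_molecule` (see [assign_typing()]).
#' @return a list with tibbles `donors` (columns `h`, `heavy`, `heavy_element`)
#'   and `acceptors` (columns `atom`, `element`), plus counts `n_donor`,
#'   `n_acceptor`.
#' @export
classify_hbond_sites <- function(mol) {
  el <- mol$atoms$element
  n <- nrow(mol$atoms)
  don_h <- integer(); don_heavy <- integer()
  has_h <- logical(n)
  for (a in which(el == "H")) {
    nb <- .neighbors_of(mol, a)
    if (length(nb) && el[nb[1]] %in% c("N", "O")) {
      don_h <- c(don_h, a); don_heavy <- c(don_heavy, nb[1])
      has_h[nb[1]] <- TRUE
    }
  }
  deg <- .atom_degree(mol)
  acc <- integer()
  for (a in which(el %in% c("N", "O"))) {
    if (el[a] == "O") {
      acc <- c(acc, a)
    } else if (!has_h[a] && (deg[a] <= 2 || mol$atoms$ff_type[a] == "N_3")) {
      acc <- c(acc, a)
    }
  }
  list(
    donors = tibble::tibble(h = don_h, heavy = don_heavy,
                            heavy_element = el[don_heavy]),
    acceptors = tibble::tibble(atom = acc, element = el[acc]),
    n_donor = length(don_h),
    n_acceptor = length(acc)
  )
}
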