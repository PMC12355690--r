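# two single-atom molecules with controllable type/charge, for closed forms
atom_mol <- function(element, x, charge = 0, ff_type = NULL) {
  m <- new_molecule(tibble::tibble(element = element, x = x, y = 0, z = 0,
                                   charge = charge))
  m$atoms$ff_type <- if (is.null(ff_type)) element else ff_type
  m
}

test_that("pair energy reproduces the LJ, Coulomb and H-bond closed forms", {
  ff <- dreiding_params()
  # LJ dimer at the well minimum: E = -D0 exactly (12-6 with R0 the minimum)
  a <- atom_mol("Ar", 0, ff_type = "Ar")
  b <- atom_mol("Ar", 3.868, ff_type = "Ar")
  e <- pair_energy(a, b, ff)
  expect_equal(e$e_vdw, -0.185, tolerance = 1e-9)
  expect_equal(e$e_coul, 0)
  expect_equal(e$e_hb, 0)

  # two point charges +/-0.3 e at 3.0 A with eps(r) = r
  a <- atom_mol("C", 0, charge = 0.3, ff_type = "C_3")
  b <- atom_mol("C", 30, charge = -0.3, ff_type = "C_3")  # LJ negligible
  e <- pair_energy(a, b, ff)
  expect_equal(e$e_coul, 332.0637 * (0.3 * -0.3) / 30^2, tolerance = 1e-12)
  b3 <- atom_mol("C", 3, charge = -0.3, ff_type = "C_3")
  e3 <- pair_energy(a, b3, ff)
  expect_equal(e3$e_coul, 332.0637 * (-0.09) / 9.0, tolerance = 1e-9)

  # linear O-H...O dimer at r_DA = R_hb, theta = 180: e_hb = -D_hb exactly
  don <- new_molecule(tibble::tibble(element = c("O", "H"),
                                     x = c(0, 0.96), y = 0, z = 0))
  don <- assign_typing(perceive_bonds(don$atoms), charge_scheme = "none")
  acc <- atom_mol("O", ff$r_hb, ff_type = "O_2")
  e <- pair_energy(don, acc, ff)
  expect_equal(e$e_hb, -ff$d_hb, tolerance = 1e-9)
  expect_equal(e$e_vdw, 0)   # D...A and H...A LJ replaced by the 12-10 term
  expect_equal(e$e_total, e$e_vdw + e$e_coul + e$e_hb, tolerance = 1e-12)
})

test_that("pair energy is symmetric to 1e-12", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  env <- build_environment(xt, 1, cutoff = 10)
  for (k in seq_len(min(3, nrow(env)))) {
    e_ab <- pair_energy(xt$asym_molecules[[1]], env$mol[[k]], ff)
    e_ba <- pair_energy(env$mol[[k]], xt$asym_molecules[[1]], ff)
    expect_equal(e_ab$e_total, e_ba$e_total, tolerance = 1e-12)
    expect_equal(e_ab$e_vdw, e_ba$e_vdw, tolerance = 1e-12)
    expect_equal(e_ab$e_hb, e_ba$e_hb, tolerance = 1e-12)
  }
})

test_that("environment membership matches brute-force enumeration", {
  # point-like molecule in a cubic P1 cell: neighbours within the cutoff
  # are exactly the nonzero integer lattice vectors with |v|*a <= cutoff
  a <- 10
  ar <- atom_mol("Ar", 0, ff_type = "Ar")
  ar$atoms$element <- "Ar"
  xt <- new_crystal(new_unit_cell(a, a, a), list(ar))
  for (cutoff in c(10, 14.2, 17.4)) {
    env <- build_environment(xt, 1, cutoff)
    grid <- as.matrix(expand.grid(-7:7, -7:7, -7:7))
    grid <- grid[rowSums(abs(grid)) > 0, ]
    n_brute <- sum(sqrt(rowSums(grid^2)) * a <= cutoff)
    expect_equal(nrow(env), n_brute)
  }
  # cutoff below the nearest-neighbour distance: empty environment
  env0 <- build_environment(xt, 1, cutoff = 5)
  expect_equal(nrow(env0), 0)
})

test_that("cutoff environment sum equals an explicit supercell brute force", {
  ff <- dreiding_params()
  cutoff <- 12
  # cells with every axis >= cutoff/3, so a 7x7x7 supercell covers the cutoff
  ar <- atom_mol("Ar", 0, ff_type = "Ar")
  ar$atoms$charge <- 0.0
  tricl <- new_crystal(new_unit_cell(9, 10, 11, 80, 95, 100), list(ar))
  for (xt in list(make_ribbon_crystal(inversion = TRUE), tricl)) {
    # independent enumeration: all ops x translations in a 7x7x7 supercell,
    # same centroid criterion, direct half-sum
    brute_total <- 0
    for (ri in seq_along(xt$asym_molecules)) {
      ref <- cocryst:::.ensure_typed(xt)$asym_molecules[[ri]]
      ref_cen <- mol_centroid(ref)
      frac <- cart_to_frac(coords(ref), xt$cell)
      for (oi in seq_along(xt$ops)) {
        op <- xt$ops[[oi]]
        for (mi in seq_along(xt$asym_molecules)) {
          fm <- cart_to_frac(coords(cocryst:::.ensure_typed(xt)$asym_molecules[[mi]]),
                             xt$cell)
          f2 <- fm %*% t(op$rot) + matrix(op$trans, nrow(fm), 3, byrow = TRUE)
          for (tx in -3:3) for (ty in -3:3) for (tz in -3:3) {
            f3 <- sweep(f2, 2, -c(tx, ty, tz))
            xyz <- frac_to_cart(f3, xt$cell)
            cen <- colMeans(xyz)
            d <- sqrt(sum((cen - ref_cen)^2))
            if (d < 1e-6 || d > cutoff) next
            part <- cocryst:::.ensure_typed(xt)$asym_molecules[[mi]]
            part$atoms$x <- xyz[, 1]; part$atoms$y <- xyz[, 2]
            part$atoms$z <- xyz[, 3]
            brute_total <- brute_total +
              pair_energy(ref, part, ff)$e_total / 2
          }
        }
      }
    }
    le <- lattice_energy(xt, ff, cutoff = cutoff)
    expect_equal(le$total, brute_total, tolerance = 1e-6)
  }
})

test_that("lattice energy limits behave analytically", {
  ff <- dreiding_params()
  # noninteracting crystal: zero charges, separations far beyond LJ range
  ar <- atom_mol("Ar", 0, ff_type = "Ar")
  xt <- new_crystal(new_unit_cell(50, 50, 50), list(ar))
  le <- lattice_energy(xt, ff, cutoff = 55)
  expect_lt(abs(le$total), 1e-6)

  # 1D LJ chain at the well minimum: E = sum_{n>=1} D0[(1/n)^12 - 2(1/n)^6]
  r0 <- 3.868; d0 <- 0.185
  xt1 <- new_crystal(new_unit_cell(r0, 200, 200), list(ar))
  cutoff <- 20.5 * r0
  le1 <- lattice_energy(xt1, ff, cutoff = cutoff)
  n <- 1:20   # images within the cutoff
  series <- sum(d0 * ((1 / n)^12 - 2 * (1 / n)^6))
  expect_equal(le1$total, series, tolerance = 1e-6)

  # convergence flag on the ribbon fixture
  le2 <- lattice_energy(make_ribbon_crystal(), ff, cutoff = 30,
                        convergence_check = TRUE)
  expect_true(le2$converged)
})

test_that("doubling the automatic supercell extent changes nothing", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  env <- build_environment(xt, 1, cutoff = 12)
  # manual enumeration with doubled extent, same criterion
  d_ax <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                 function(h) d_spacing(xt$cell, h), numeric(1))
  ext <- 2 * (ceiling(12 / d_ax) + 1)
  frac <- cart_to_frac(coords(xt$asym_molecules[[1]]), xt$cell)
  cen0 <- colMeans(frac)
  ref_cen <- mol_centroid(xt$asym_molecules[[1]])
  cnt <- 0
  for (tx in -ext[1]:ext[1]) for (ty in -ext[2]:ext[2]) for (tz in -ext[3]:ext[3]) {
    cen <- frac_to_cart(matrix(cen0 + c(tx, ty, tz), 1), xt$cell)
    d <- sqrt(sum((cen - ref_cen)^2))
    if (d > 1e-6 && d <= 12) cnt <- cnt + 1
  }
  expect_equal(nrow(env), cnt)
})

test_that("symmetry-equivalent references report equal lattice energies", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal(inversion = TRUE)
  # expand to a two-molecule P1 description: both should agree
  mols <- expand_cell(xt)
  xt2 <- new_crystal(xt$cell, mols, space_group_label = "P1")
  le <- lattice_energy(xt2, ff, cutoff = 12)
  expect_lt(abs(diff(le$per_molecule$e_lattice)), 1e-6)
})
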