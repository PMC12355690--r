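test_that("bond perception recovers rings and handles edge cases", {
  bz <- make_benzene()
  cc <- sum(bz$atoms$element[bz$bonds$i] == "C" &
              bz$atoms$element[bz$bonds$j] == "C")
  ch <- nrow(bz$bonds) - cc
  expect_equal(cc, 6)
  expect_equal(ch, 6)
  expect_length(bz$rings, 1)
  expect_true(all(bz$ring_aromatic))

  # two far-apart atoms: no bonds, two single-atom components
  far <- perceive_bonds(tibble::tibble(element = c("C", "C"),
                                       x = c(0, 5), y = 0, z = 0))
  expect_equal(nrow(far$bonds), 0)
  expect_length(molecule_components(far), 2)

  # clashing atoms rejected
  expect_error(
    perceive_bonds(tibble::tibble(element = c("C", "C"),
                                  x = c(0, 0.3), y = 0, z = 0)),
    "clash"
  )
})

test_that("quercetin connection table is perceived correctly", {
  q <- make_quercetin()
  expect_equal(sort(table(q$atoms$element)),
               sort(table(c(rep("C", 15), rep("H", 10), rep("O", 7)))))
  expect_length(q$rings, 3)
  # two aromatic carbocycles; the pyranone ring detected but not aromatic
  expect_equal(sum(q$ring_aromatic), 2)
  arom_elements <- unique(q$atoms$element[unlist(q$rings[q$ring_aromatic])])
  expect_equal(arom_elements, "C")
  s <- classify_hbond_sites(q)
  expect_equal(s$n_donor, 5)       # five hydroxyls
  expect_equal(s$n_acceptor, 7)    # 5 OH + carbonyl + ring ether oxygens
})

test_that("bond perception is invariant under rigid motion", {
  q <- make_quercetin()
  rot <- random_rotation(42)
  q2 <- perceive_bonds(transform_molecule(q, rot, c(5, -3, 2)))
  key <- function(m) {
    paste(sort(paste(pmin(m$bonds$i, m$bonds$j),
                     pmax(m$bonds$i, m$bonds$j))), collapse = ";")
  }
  expect_identical(key(q2), key(q))
  expect_equal(length(q2$rings), length(q$rings))
})

test_that("Dreiding typing and PEOE charges behave as specified", {
  w <- make_water()
  expect_equal(w$atoms$ff_type[w$atoms$element == "O"], "O_3")
  expect_true(all(w$atoms$ff_type[w$atoms$element == "H"] == "H__HB"))
  expect_lt(abs(sum(w$atoms$charge)), 1e-6)
  expect_lt(w$atoms$charge[1], 0)   # oxygen negative

  im <- make_imidazole()
  s <- classify_hbond_sites(im)
  expect_equal(s$n_donor, 1)
  expect_equal(s$donors$heavy_element, "N")
  expect_equal(s$n_acceptor, 1)
  expect_equal(s$acceptors$element, "N")
  # all ring atoms aromatic sp2 types
  ring_types <- im$atoms$ff_type[unlist(im$rings)]
  expect_true(all(ring_types %in% c("C_R", "N_R")))

  me <- make_methane()
  sm <- classify_hbond_sites(me)
  expect_equal(sm$n_donor, 0)
  expect_equal(sm$n_acceptor, 0)

  # charge conservation across a panel of molecules
  for (m in list(make_benzene(), make_quercetin(), im,
                 make_planar_donor_molecule(4, 3, seed = 3))) {
    expect_lt(abs(sum(m$atoms$charge)), 1e-6)
  }
  expect_error(
    assign_typing(perceive_bonds(tibble::tibble(element = "Xx", x = 0,
                                                y = 0, z = 0))),
    "element"
  )
})

test_that("CIF write/read round-trips structures and validates input", {
  xt <- make_ribbon_crystal()
  tmp <- withr::local_tempfile(fileext = ".cif")
  write_cif(xt, tmp)
  xt2 <- read_cif(tmp)
  expect_equal(length(xt2$asym_molecules), 1)
  expect_equal(xt2$cell$a, xt$cell$a, tolerance = 1e-9)
  expect_equal(xt2$cell$volume, xt$cell$volume, tolerance = 1e-9)
  err <- max(abs(coords(xt2$asym_molecules[[1]]) -
                   coords(xt$asym_molecules[[1]])))
  expect_lt(err, 1e-6)

  # fractional coordinates round-trip through a second write
  tmp2 <- withr::local_tempfile(fileext = ".cif")
  write_cif(xt2, tmp2)
  xt3 <- read_cif(tmp2)
  expect_lt(max(abs(cart_to_frac(coords(xt3$asym_molecules[[1]]), xt3$cell) -
                      cart_to_frac(coords(xt2$asym_molecules[[1]]), xt2$cell))),
            1e-6)
})

test_that("a P1 water cell reads as one molecule with identity symmetry", {
  tmp <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_w",
    "_symmetry_space_group_name_H-M 'P1'",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "O1 O 0.5 0.5 0.5",
    "H1 H 0.5957 0.5 0.5",
    "H2 H 0.476 0.5927 0.5"
  ), tmp)
  xt <- read_cif(tmp)
  expect_length(xt$asym_molecules, 1)
  expect_equal(nrow(xt$asym_molecules[[1]]$atoms), 3)
  expect_length(xt$ops, 1)
})

test_that("P-1 expansion doubles the cell content with congruent copies", {
  xt <- make_ribbon_crystal(inversion = TRUE)
  mols <- expand_cell(xt)
  expect_length(mols, 2 * length(xt$asym_molecules) * 1)
  rmsd <- kabsch_rmsd(coords(mols[[1]]), coords(mols[[2]]))
  expect_lt(rmsd, 1e-6)

  tmp <- withr::local_tempfile(fileext = ".cif")
  write_cif(xt, tmp)
  xt2 <- read_cif(tmp)
  expect_length(xt2$ops, 2)
  expect_length(expand_cell(xt2), 2)
})

test_that("molecules split across the cell boundary are reassembled whole", {
  xt <- make_ribbon_crystal()
  # shift the molecule so it straddles the a-axis boundary
  shifted <- transform_molecule(xt$asym_molecules[[1]], diag(3),
                                c(xt$cell$a - 2, 0, 0))
  frac <- cart_to_frac(coords(shifted), xt$cell) %% 1
  xyz <- frac_to_cart(frac, xt$cell)
  shifted$atoms$x <- xyz[, 1]; shifted$atoms$y <- xyz[, 2]
  shifted$atoms$z <- xyz[, 3]
  xt_wrapped <- new_crystal(xt$cell, list(shifted))
  tmp <- withr::local_tempfile(fileext = ".cif")
  write_cif(xt_wrapped, tmp)
  xt2 <- read_cif(tmp)
  expect_length(xt2$asym_molecules, 1)
  expect_equal(nrow(xt2$asym_molecules[[1]]$bonds),
               nrow(xt$asym_molecules[[1]]$bonds))
})

test_that("CIF reader errors name the missing item and disordered sites", {
  tmp <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_a 10"), tmp)
  expect_error(read_cif(tmp), "missing cell")

  writeLines(c(
    "data_x",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.1 0.1"
  ), tmp)
  expect_error(read_cif(tmp), "missing symmetry")

  writeLines(c(
    "data_x",
    "_symmetry_space_group_name_H-M 'P1'",
    "_cell_length_a 10", "_cell_length_b 10", "_cell_length_c 10",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "_atom_site_occupancy",
    "C1 C 0.1 0.1 0.1 0.5",
    "C2 C 0.6 0.6 0.6 1.0"
  ), tmp)
  expect_error(read_cif(tmp), "C1")
  expect_silent(read_cif(tmp, keep_major_occupancy = TRUE))
})

test_that("unit cell volume matches the triclinic closed form", {
  cell <- new_unit_cell(7.1, 8.3, 9.7, 71, 85, 110)
  ca <- cos(71 * pi / 180); cb <- cos(85 * pi / 180); cg <- cos(110 * pi / 180)
  v_ref <- 7.1 * 8.3 * 9.7 *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  expect_equal(cell$volume, v_ref, tolerance = 1e-12)
  expect_equal(det(cell$mat), cell$volume, tolerance = 1e-9)
  expect_error(new_unit_cell(-1, 2, 3), "a > 0")
})
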