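test_that("slabs keep whole molecules and the required thickness", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  sl <- cut_slab(xt, c(1, 0, 0), params = ff)
  expect_s3_class(sl, "cocryst_slab")
  n_at <- nrow(xt$asym_molecules[[1]]$atoms)
  expect_true(all(vapply(sl$molecules, function(m) nrow(m$atoms),
                         numeric(1)) == n_at))
  heights <- vapply(sl$molecules, function(m) sum(mol_centroid(m) * sl$n_hat),
                    numeric(1))
  expect_gte(diff(range(heights)), 2 * sl$d_hkl)
  expect_error(cut_slab(xt, c(0, 0, 0)), "0,0,0")
})

test_that("automatic termination matches a brute-force offset sweep", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  sl <- cut_slab(xt, c(0, 0, 1), params = ff)
  # independent sweep: crossing energy on a 50-point offset grid
  cross_energy <- function(off) {
    sl_off <- cut_slab(xt, c(0, 0, 1), termination_offset = off, params = ff)
    heights <- vapply(sl_off$molecules,
                      function(m) sum(mol_centroid(m) * sl_off$n_hat),
                      numeric(1))
    z_cut <- max(heights) + 1e-6
    # rebuild the uncut molecule set and sum across-plane pair energies
    full <- cut_slab(xt, c(0, 0, 1), termination_offset = off, params = ff,
                     n_layers = 4)
    h_full <- vapply(full$molecules,
                     function(m) sum(mol_centroid(m) * full$n_hat), numeric(1))
    below <- which(h_full <= z_cut & h_full > z_cut - full$d_hkl)
    above <- which(h_full > z_cut & h_full < z_cut + full$d_hkl)
    e <- 0
    for (b in below) for (a in above) {
      e <- e + pair_energy(full$molecules[[b]], full$molecules[[a]], ff)$e_total
    }
    abs(e)
  }
  grid <- seq(0, 0.98, length.out = 50)
  sweep_best <- min(vapply(grid, cross_energy, numeric(1)))
  expect_lte(cross_energy(sl$termination_offset), sweep_best + 1e-6)
})

test_that("height maps are centred, convergent and motion-stable", {
  ff <- dreiding_params()
  # dense flat monolayer: near-zero rugosity
  ar <- new_molecule(tibble::tibble(element = "Ar", x = 0, y = 0, z = 0))
  ar$atoms$ff_type <- "Ar"
  flat <- new_crystal(new_unit_cell(2.0, 2.0, 20), list(ar))
  slf <- cut_slab(flat, c(0, 0, 1), termination_offset = 0.5, params = ff)
  tmf <- topology_map(slf, 0.25)
  expect_lt(abs(mean(tmf$grid$height, na.rm = TRUE)), 1e-9)
  expect_lt(tmf$rugosity, 0.2)

  xt <- make_ribbon_crystal()
  sl <- cut_slab(xt, c(0, 0, 1), params = ff)
  tm <- topology_map(sl, 0.25)
  expect_lt(abs(mean(tm$grid$height, na.rm = TRUE)), 1e-9)

  # raising one molecule strictly increases rugosity
  sl2 <- sl
  k <- which.max(vapply(sl2$molecules,
                        function(m) sum(mol_centroid(m) * sl2$n_hat),
                        numeric(1)))
  sl2$molecules[[k]] <- transform_molecule(sl2$molecules[[k]], diag(3),
                                           2 * sl2$n_hat)
  expect_gt(topology_map(sl2, 0.25)$rugosity, tm$rugosity)

  # grid refinement: 0.25 vs 0.1 within 2%
  r_fine <- topology_map(sl, 0.1)$rugosity
  expect_lt(abs(tm$rugosity - r_fine) / r_fine, 0.02)

  # in-plane translation of the structure: rugosity drift < 1%
  sl3 <- sl
  shift <- 0.37 * sl$e1 + 0.59 * sl$e2
  sl3$molecules <- lapply(sl$molecules, transform_molecule, rot = diag(3),
                          trans = shift)
  expect_lt(abs(topology_map(sl3, 0.25)$rugosity - tm$rugosity) /
              tm$rugosity, 0.01)

  expect_error(topology_map(structure(list(molecules = list()),
                                      class = "cocryst_slab")), "empty")
})

test_that("surface densities are intensive and chemically sane", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  sl2 <- cut_slab(xt, c(1, 0, 0), params = ff, patch = 2)
  bd2 <- bond_densities(sl2, 3.0)
  sl4 <- cut_slab(xt, c(1, 0, 0), params = ff, patch = 4)
  bd4 <- bond_densities(sl4, 3.0)
  expect_lt(abs(bd4$hbd_density - bd2$hbd_density) /
              max(bd2$hbd_density, 1e-9), 0.05)
  expect_lt(abs(bd4$aromatic_density - bd2$aromatic_density) /
              bd2$aromatic_density, 0.05)

  # an all-aliphatic surface has zero aromatic density
  me <- make_methane()
  mxt <- new_crystal(new_unit_cell(5, 5, 5), list(me))
  slm <- cut_slab(mxt, c(0, 0, 1), termination_offset = 0.5, params = ff)
  expect_equal(bond_densities(slm, 3.0)$aromatic_density, 0)
})

test_that("donor exposure is highest on the facet normal to the ribbons", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  dens <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(hkl) {
    sl <- cut_slab(xt, hkl, params = ff)
    bond_densities(sl, 3.0, map = topology_map(sl, 0.4))$hbd_density
  }, numeric(1))
  expect_equal(which.max(dens), 1)      # (100)
  # the ribbon-parallel side facet buries its H-bonded hydroxyls
  expect_lt(dens[2], dens[1] / 2)
})

test_that("facet reports carry consistent units and symmetry", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal(inversion = TRUE)
  facets <- tibble::tibble(h = c(0, 0), k = c(1, -1), l = c(0, 0))
  rep2 <- surface_report(xt, facets, ff, cutoff = 10, grid_spacing = 0.5)
  # Friedel-paired facets of a centrosymmetric crystal: identical reports
  expect_equal(rep2$hbd_density[1], rep2$hbd_density[2], tolerance = 1e-9)
  expect_equal(rep2$e_att_polar_kj[1], rep2$e_att_polar_kj[2],
               tolerance = 1e-6)
  expect_equal(rep2$rugosity[1], rep2$rugosity[2], tolerance = 1e-9)
  # kJ column is the kcal value times 4.184 exactly
  ae <- attachment_energy(xt, c(0, 1, 0), ff, 10)
  expect_equal(rep2$e_att_polar_kj[1], ae$e_att_polar * 4.184,
               tolerance = 1e-9)
  expect_equal(nrow(rep2), 2)
})

test_that("a layered polar/apolar fixture is more anisotropic than a uniform one", {
  ff <- dreiding_params()
  # layered: polar ribbon crystal (strong polar contrast across facets)
  xt_layered <- make_ribbon_crystal()
  # uniform: same lattice but all charges off and H-bond well quenched
  xt_uniform <- make_ribbon_crystal(charge_scale = 0)
  ff0 <- ff; ff0$d_hb <- 1e-9
  aniso <- function(xt, ffx) {
    vals <- vapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(hkl) {
      ae <- attachment_energy(xt, hkl, ffx, 12)
      abs(ae$e_att_polar)
    }, numeric(1))
    max(vals) / max(min(vals), 1e-12)
  }
  expect_gt(aniso(xt_layered, ff), aniso(xt_uniform, ff0))
})
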