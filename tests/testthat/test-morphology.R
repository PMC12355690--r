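test_that("form enumeration is symmetry-unique, coprime and d-sorted", {
  xt <- make_ribbon_crystal(inversion = TRUE)
  forms <- enumerate_forms(xt, 1)
  expect_equal(nrow(forms), 13)    # 26 index-1 planes paired by inversion
  expect_true(all(diff(forms$d_spacing) <= 1e-9))
  expect_true(all(forms$multiplicity == 2))

  # P1: no merging, 26 forms
  xt1 <- make_ribbon_crystal()
  expect_equal(nrow(enumerate_forms(xt1, 1)), 26)

  expect_equal(normalize_hkl(c(2, 2, 0)), c(1L, 1L, 0L))
  expect_error(normalize_hkl(c(0, 0, 0)), "0,0,0")

  # cubic cell: d(100) = a
  cub <- new_unit_cell(10, 10, 10)
  expect_equal(d_spacing(cub, c(1, 0, 0)), 10, tolerance = 1e-12)
  expect_equal(d_spacing(cub, c(1, 1, 0)), 10 / sqrt(2), tolerance = 1e-12)
})

test_that("slice + attachment energies conserve the lattice energy", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  fe <- facet_energies(xt, ff, max_index = 1, cutoff = 12)
  expect_true(all(abs(fe$e_slice + fe$e_att - fe$e_lattice) < 1e-6))
  # kJ columns use the exact factor
  expect_equal(fe$e_att_kj, fe$e_att * 4.184, tolerance = 1e-12)
  expect_equal(fe$e_att_polar + fe$e_att_nonpolar, fe$e_att, tolerance = 1e-9)
})

test_that("a 1D-bonded chain puts all attachment energy on the end facet", {
  ff <- dreiding_params()
  # single LJ atom chained along a only (b, c far apart)
  ar <- new_molecule(tibble::tibble(element = "Ar", x = 0, y = 0, z = 0))
  ar$atoms$ff_type <- "Ar"
  xt <- new_crystal(new_unit_cell(3.868, 40, 40), list(ar))
  e100 <- attachment_energy(xt, c(1, 0, 0), ff, cutoff = 12)
  e010 <- attachment_energy(xt, c(0, 1, 0), ff, cutoff = 12)
  e001 <- attachment_energy(xt, c(0, 0, 1), ff, cutoff = 12)
  # planes containing a: everything in-slab, zero attachment
  expect_lt(abs(e010$e_att), 1e-9)
  expect_lt(abs(e001$e_att), 1e-9)
  # plane normal to a: all chain interactions are attachment
  expect_equal(e100$e_att, e100$e_lattice, tolerance = 1e-9)
  expect_lt(e100$e_att, -0.1)
})

test_that("the facet normal to the H-bond ribbons grows fastest and is polar", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  ax <- dplyr::bind_rows(
    attachment_energy(xt, c(1, 0, 0), ff, 12),
    attachment_energy(xt, c(0, 1, 0), ff, 12),
    attachment_energy(xt, c(0, 0, 1), ff, 12)
  )
  expect_equal(which.max(abs(ax$e_att)), 1)   # (100), normal to the ribbon
  polar_frac <- ax$e_att_polar / ax$e_att
  expect_equal(which.max(polar_frac), 1)
  # all-charges-zero crystal: every facet has zero polar attachment term
  xt0 <- make_ribbon_crystal(charge_scale = 0)
  xt0$asym_molecules[[1]]$atoms$charge <- 0
  ff0 <- ff; ff0$d_hb <- 1e-12     # no H-bond wells either
  e0 <- attachment_energy(xt0, c(1, 0, 0), ff0, 12)
  expect_lt(abs(e0$e_att_polar), 1e-9)
})

test_that("Friedel mates report identical attachment energies", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal(inversion = TRUE)
  a <- attachment_energy(xt, c(1, -1, 1), ff, 10)
  b <- attachment_energy(xt, c(-1, 1, -1), ff, 10)
  expect_equal(a$e_att, b$e_att, tolerance = 1e-9)
  expect_equal(a$e_slice, b$e_slice, tolerance = 1e-9)
})

test_that("the Wulff construction recovers the cube and its limits", {
  cub <- new_unit_cell(10, 10, 10)
  facets <- tibble::tibble(h = c(1, 0, 0), k = c(0, 1, 0), l = c(0, 0, 1),
                           e_att = c(-2, -2, -2))
  hab <- wulff_habit(facets, cub)
  expect_equal(nrow(hab$vertices), 8)
  expect_equal(hab$facets$relative_area, rep(1 / 3, 3), tolerance = 1e-9)

  # slowest-growing facet dominates as its |e_att| shrinks
  f2 <- facets; f2$e_att <- c(-0.05, -2, -2)
  hab2 <- wulff_habit(f2, cub)
  expect_gt(hab2$facets$relative_area[hab2$facets$h == 1], 0.9)

  # scaling invariance
  f3 <- facets; f3$e_att <- facets$e_att * 7.3
  hab3 <- wulff_habit(f3, cub)
  expect_equal(hab3$facets$relative_area, hab$facets$relative_area,
               tolerance = 1e-9)

  # degenerate normals rejected
  flat <- tibble::tibble(h = c(1, 0), k = c(0, 1), l = c(0, 0),
                         e_att = c(-1, -1))
  expect_error(wulff_habit(flat, cub), "span")
  # a non-growing facet floors to the plate-like limit and dominates
  expect_warning(
    hab0 <- wulff_habit(dplyr::mutate(facets, e_att = c(0, -1, -1)), cub),
    "floored"
  )
  expect_gt(hab0$facets$relative_area[hab0$facets$h == 1], 0.9)
  expect_error(wulff_habit(dplyr::mutate(facets, e_att = c(0, 0, 0)), cub),
               "e_att")
})

test_that("polyhedral facet areas match Monte-Carlo ray sampling within 1%", {
  set.seed(91)
  for (trial in 1:3) {
    cell <- new_unit_cell(stats::runif(1, 7, 12), stats::runif(1, 7, 12),
                          stats::runif(1, 7, 12), stats::runif(1, 75, 105),
                          stats::runif(1, 75, 105), stats::runif(1, 75, 105))
    xt_forms <- expand.grid(h = -1:1, k = -1:1, l = -1:1)
    xt_forms <- xt_forms[rowSums(abs(xt_forms)) > 0, ]
    # one hemisphere representative per Friedel pair
    keep <- apply(xt_forms, 1, function(v) {
      v <- v[v != 0]; v[1] > 0
    })
    fam <- xt_forms[keep, ]
    fam$e_att <- -stats::runif(nrow(fam), 0.5, 3)
    hab <- wulff_habit(fam, cell)
    mc <- sample_habit_areas(hab, n = 2e6, seed = 100 + trial)
    j <- dplyr::inner_join(hab$facets, mc, by = "family")
    expect_lt(max(abs(j$relative_area - j$relative_area_mc)), 0.01)
  }
})
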