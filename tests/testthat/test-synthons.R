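test_that("interaction classification follows the geometric rules", {
  # linear O-H...O dimer
  don <- assign_typing(perceive_bonds(tibble::tibble(
    element = c("O", "H"), x = c(0, 0.96), y = 0, z = 0)), "none")
  acc <- new_molecule(tibble::tibble(element = "O", x = 2.75, y = 0, z = 0))
  acc$atoms$ff_type <- "O_2"
  expect_equal(classify_interaction(don, acc), "H-bond")

  bz <- make_benzene()
  stacked <- transform_molecule(bz, diag(3), c(0, 0, 3.5))
  expect_equal(classify_interaction(bz, stacked), "pi-pi stacking")

  offset <- transform_molecule(bz, diag(3), c(3, 0, 3.5))
  expect_equal(classify_interaction(bz, offset), "offset stacking")

  apart <- transform_molecule(bz, diag(3), c(10, 0, 0))
  expect_equal(classify_interaction(bz, apart), "vdW/other")
})

test_that("synthon ranking sorts by |E| with symmetry grouping", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  rs <- rank_synthons(xt, ff, cutoff = 15)
  # strongest synthon is the in-ribbon H-bond, second the stack
  expect_equal(rs$type_label[1], "H-bond")
  expect_equal(rs$type_label[2], "pi-pi stacking")
  # P1 with one molecule: +a and -a partners merge, multiplicity 2
  expect_equal(rs$multiplicity[1], 2)
  # flat pair list re-sorted is the grouped order (oracle)
  pairs <- attr(rs, "pairs")
  flat <- sort(unique(round(abs(pairs$e_total), 6)), decreasing = TRUE)
  flat <- flat[flat >= 0.05]
  expect_equal(round(abs(rs$e_total), 6), flat)
  # percentages are taken against one lattice energy
  e_lat <- attr(rs, "e_lattice_total")
  expect_equal(rs$percent_of_lattice, 100 * rs$e_total / e_lat,
               tolerance = 1e-12)
})

test_that("inversion-related pairs merge with multiplicity two", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal(inversion = TRUE)
  rs <- rank_synthons(xt, ff, cutoff = 12)
  # every grouped synthon collects at least the Friedel-mate pair
  expect_true(all(rs$multiplicity >= 2))
})

test_that("charge weakening flips the ranking to stacking-dominated", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal(spacing_hb = 4.3, spacing_stack = 3.3,
                            charge_scale = 0.1)
  rs <- rank_synthons(xt, ff, cutoff = 15)
  expect_equal(rs$type_label[1], "pi-pi stacking")
})

test_that("type aggregation reproduces the printed reference totals", {
  tb <- reference_synthon_table()
  agg <- aggregate_by_type(tb)
  hb <- agg[agg$class == "H-bond", ]
  st <- agg[agg$class == "stacking", ]
  expect_equal(hb$e_abs_total, 19.12, tolerance = 1e-9)
  expect_equal(st$e_abs_total, 12.07, tolerance = 1e-9)
  expect_equal(hb$percent_total, 48.5, tolerance = 1e-9)
  expect_equal(st$percent_total, 30.8, tolerance = 1e-9)
  tot <- agg[agg$class == "total", ]
  expect_equal(tot$percent_total, 79.3, tolerance = 1e-9)

  empty <- aggregate_by_type(tb[0, ])
  expect_equal(empty$e_abs_total, 0)
})

test_that("group decomposition conserves the lattice energy", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  le <- lattice_energy(xt, ff, cutoff = 12)
  n <- nrow(xt$asym_molecules[[1]]$atoms)

  # single group: total equals E_lattice
  g1 <- group_decomposition(xt, ff, cutoff = 12,
                            grouping = rep("all", n))
  expect_equal(g1$e_total, le$total, tolerance = 1e-6)

  # two-group split sums to E_lattice
  el <- xt$asym_molecules[[1]]$atoms$element
  grp <- ifelse(el == "O" | el == "H", "polar_groups", "core")
  g2 <- group_decomposition(xt, ff, cutoff = 12, grouping = grp)
  expect_equal(sum(g2$e_total), le$total, tolerance = 1e-6)

  expect_error(
    group_decomposition(xt, ff, cutoff = 12, grouping = rep("g", n - 1)),
    "unassigned"
  )
})

test_that("Coulomb energy concentrates where the charges are", {
  ff <- dreiding_params()
  xt <- make_ribbon_crystal()
  # zero all charges except the hydroxyl/carbonyl trio
  m <- xt$asym_molecules[[1]]
  keep <- m$atoms$element == "O" |
    (m$atoms$element == "H" & abs(m$atoms$x - 3.72) < 0.1)
  q <- m$atoms$charge
  q[!keep] <- 0
  q[keep] <- q[keep] - sum(q) / sum(keep)   # renormalize to neutrality
  m$atoms$charge <- q
  xt$asym_molecules[[1]] <- m
  grp <- ifelse(keep, "hydroxyl", "rest")
  g <- group_decomposition(xt, ff, cutoff = 12, grouping = grp)
  e_hydroxyl <- abs(g$e_coul[g$group == "hydroxyl"])
  e_rest <- abs(g$e_coul[g$group == "rest"])
  expect_gt(e_hydroxyl, e_rest)
})
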