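# Reference molecules built from idealized geometry (bond length 1.40 A for
# aromatic rings, standard substituent distances), used across the tests.

hexagon_pts <- function(center = c(0, 0), radius = 1.4, phase = 30) {
  ang <- (phase + 60 * (0:5)) * pi / 180
  cbind(center[1] + radius * cos(ang), center[2] + radius * sin(ang))
}

make_benzene <- function() {
  v <- hexagon_pts()
  h <- hexagon_pts(radius = 1.4 + 1.08)
  atoms <- tibble::tibble(
    element = rep(c("C", "H"), each = 6),
    x = c(v[, 1], h[, 1]), y = c(v[, 2], h[, 2]), z = 0
  )
  assign_typing(perceive_bonds(atoms, name = "benzene"))
}

make_water <- function() {
  atoms <- tibble::tibble(
    element = c("O", "H", "H"),
    x = c(0, 0.9572, -0.23999), y = c(0, 0, 0.92663), z = 0
  )
  assign_typing(perceive_bonds(atoms, name = "water"))
}

make_methane <- function() {
  s <- 1.09 / sqrt(3)
  atoms <- tibble::tibble(
    element = c("C", "H", "H", "H", "H"),
    x = c(0, s, s, -s, -s), y = c(0, s, -s, s, -s), z = c(0, s, -s, -s, s)
  )
  assign_typing(perceive_bonds(atoms, name = "methane"))
}

# imidazole: planar five-membered ring, N1-H pyrrole-type donor, N3
# pyridine-type acceptor, C2/C4/C5 carry H
make_imidazole <- function() {
  r <- 1.37 / (2 * sin(pi / 5))
  ang <- (90 + 72 * (0:4)) * pi / 180
  ring <- cbind(r * cos(ang), r * sin(ang))
  elements <- c("N", "C", "N", "C", "C")   # N1, C2, N3, C4, C5
  atoms <- tibble::tibble(element = elements, x = ring[, 1], y = ring[, 2],
                          z = 0)
  for (k in c(1, 2, 4, 5)) {               # H on N1, C2, C4, C5
    dirv <- ring[k, ] / sqrt(sum(ring[k, ]^2))
    d <- if (k == 1) 1.01 else 1.08
    atoms <- dplyr::bind_rows(atoms, tibble::tibble(
      element = "H", x = ring[k, 1] + d * dirv[1],
      y = ring[k, 2] + d * dirv[2], z = 0))
  }
  assign_typing(perceive_bonds(atoms, name = "imidazole"))
}

# quercetin from its connection table: chromen-4-one core (rings A and C
# fused) plus catechol ring B at C2; hydroxyls at C3, C5, C7, C3', C4'
make_quercetin <- function() {
  ringA_c <- c(0, 0); ringC_c <- c(2.4249, 0)
  vA <- hexagon_pts(ringA_c)            # phase 30: vertices at (1.2124,+-0.7), (0,+-1.4)
  vC <- hexagon_pts(ringC_c)
  # ring C positions (shared edge x = 1.2124)
  C8a <- c(1.2124, 0.7); C4a <- c(1.2124, -0.7)
  O1 <- c(2.4249, 1.4); C2 <- c(3.6373, 0.7); C3 <- c(3.6373, -0.7)
  C4 <- c(2.4249, -1.4)
  # ring A remaining: C5..C8 (C5 adjacent to C4a)
  C5 <- c(0, -1.4); C6 <- c(-1.2124, -0.7); C7 <- c(-1.2124, 0.7)
  C8 <- c(0, 1.4)
  pos <- rbind(C2, C3, C4, C4a, C5, C6, C7, C8, C8a)
  elements <- rep("C", 9)
  atoms <- tibble::tibble(element = c(elements, "O"),
                          x = c(pos[, 1], O1[1]),
                          y = c(pos[, 2], O1[2]), z = 0)
  outward <- function(p, cen) (p - cen) / sqrt(sum((p - cen)^2))
  add <- function(atoms, el, p) {
    dplyr::bind_rows(atoms, tibble::tibble(element = el, x = p[1], y = p[2],
                                           z = 0))
  }
  # carbonyl at C4
  d4 <- outward(C4, ringC_c)
  atoms <- add(atoms, "O", C4 + 1.23 * d4)
  # hydroxyls at C3, C5, C7 (+ H on C6, C8)
  for (p in list(list(C3, ringC_c), list(C5, ringA_c), list(C7, ringA_c))) {
    dv <- outward(p[[1]], p[[2]])
    o <- p[[1]] + 1.36 * dv
    atoms <- add(atoms, "O", o)
    atoms <- add(atoms, "H", o + 0.96 * dv)
  }
  for (p in list(C6, C8)) {
    dv <- outward(p, ringA_c)
    atoms <- add(atoms, "H", p + 1.08 * dv)
  }
  # ring B (catechol) bonded at C2
  d2 <- outward(C2, ringC_c)
  C1p <- C2 + 1.48 * d2
  ringB_c <- C1p + 1.4 * d2
  phase0 <- atan2(C1p[2] - ringB_c[2], C1p[1] - ringB_c[1]) * 180 / pi
  vB <- hexagon_pts(ringB_c, phase = phase0)
  atoms <- add(atoms, "C", vB[1, ])     # C1'
  for (k in 2:6) {
    atoms <- add(atoms, "C", vB[k, ])
    dv <- outward(vB[k, ], ringB_c)
    if (k %in% c(3, 4)) {               # 3', 4' hydroxyls
      o <- vB[k, ] + 1.36 * dv
      atoms <- add(atoms, "O", o)
      atoms <- add(atoms, "H", o + 0.96 * dv)
    } else {
      atoms <- add(atoms, "H", vB[k, ] + 1.08 * dv)
    }
  }
  assign_typing(perceive_bonds(atoms, name = "quercetin"))
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
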