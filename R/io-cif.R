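#' Read a crystal structure from a CIF file
#'
#' Parses the core-dictionary items: cell parameters, symmetry (explicit
#' `_symmetry_equiv_pos_as_xyz` / `_space_group_symop_operation_xyz` strings
#' or, failing that, the space-group name), and the `_atom_site_` loop with
#' fractional coordinates. Molecules are reassembled into whole connected
#' units by lattice-translation unwrapping (each bonded neighbour is placed
#' at its nearest periodic image), so no covalent bond crosses a molecule
#' boundary in the returned structure. When both xyz strings and a
#' space-group name are present, the xyz strings win (a warning notes a
#' conflict in operation count).
#'
#' @param path CIF file path.
#' @param keep_major_occupancy keep sites with the highest occupancy instead
#'   of rejecting disordered files (default FALSE: occupancy < 1 is an error
#'   listing the offending sites).
#' @param bond_tol bond perception tolerance (Angstrom).
#' @return a `cocryst_crystal` with perceived bonds on each asymmetric-unit
#'   molecule.
#' @export
read_cif <- function(path, keep_major_occupancy = FALSE, bond_tol = 0.4) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  getval <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (!length(hit)) return(NA_character_)
    v <- sub(paste0("^\\s*", tag, "\\s+"), "", hit[1])
    gsub("^'|'$", "", trimws(v))
  }
  num <- function(tag) {
    v <- getval(tag)
    if (is.na(v)) return(NA_real_)
    as.numeric(sub("\\(.*\\)", "", v))
  }

  cell_vals <- c(a = num("_cell_length_a"), b = num("_cell_length_b"),
                 c = num("_cell_length_c"), alpha = num("_cell_angle_alpha"),
                 beta = num("_cell_angle_beta"), gamma = num("_cell_angle_gamma"))
  if (anyNA(cell_vals)) {
    stop("CIF format error: missing cell item(s): ",
         paste(names(cell_vals)[is.na(cell_vals)], collapse = ", "),
         call. = FALSE)
  }
  cell <- do.call(new_unit_cell, as.list(unname(cell_vals)))

  # --- symmetry -----------------------------------------------------------
  loops <- .cif_loops(lines)
  xyz_strings <- character()
  for (lp in loops) {
    tagn <- tolower(lp$tags)
    hit <- which(tagn %in% c("_symmetry_equiv_pos_as_xyz",
                             "_space_group_symop_operation_xyz"))
    if (length(hit)) xyz_strings <- vapply(lp$rows, `[[`, "", hit[1])
  }
  sg_label <- getval("_symmetry_space_group_name_H-M")
  if (is.na(sg_label)) sg_label <- getval("_space_group_name_H-M_alt")
  if (length(xyz_strings)) {
    ops <- lapply(xyz_strings, .parse_symop_xyz)
    if (!is.na(sg_label)) {
      sym_ops <- tryCatch(.symops_for_group(sg_label), error = function(e) NULL)
      if (!is.null(sym_ops) && length(sym_ops) != length(ops)) {
        warning("space-group name and explicit xyz strings disagree; ",
                "using xyz strings", call. = FALSE)
      }
    }
  } else if (!is.na(sg_label)) {
    ops <- .symops_for_group(sg_label)
  } else {
    stop("CIF format error: missing symmetry (no xyz loop, no space-group name)",
         call. = FALSE)
  }
  if (is.na(sg_label)) sg_label <- if (length(ops) == 1) "P1" else "P-1"

  # --- atom sites ---------------------------------------------------------
  sites <- NULL
  for (lp in loops) {
    tagn <- tolower(lp$tags)
    if ("_atom_site_fract_x" %in% tagn) {
      col <- function(tag) {
        k <- match(tag, tagn)
        if (is.na(k)) return(NULL)
        vapply(lp$rows, `[[`, "", k)
      }
      lab <- col("_atom_site_label")
      elem <- col("_atom_site_type_symbol")
      if (is.null(elem)) elem <- gsub("[0-9'.].*$", "", lab)
      occv <- col("_atom_site_occupancy")
      occ <- if (is.null(occv)) rep(1, length(lab)) else
        as.numeric(sub("\\(.*\\)", "", occv))
      sites <- tibble::tibble(
        label = lab,
        element = .normalize_element(elem),
        fx = as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_x"))),
        fy = as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_y"))),
        fz = as.numeric(sub("\\(.*\\)", "", col("_atom_site_fract_z"))),
        occupancy = occ
      )
    }
  }
  if (is.null(sites)) {
    stop("CIF format error: missing _atom_site_ loop", call. = FALSE)
  }
  low <- sites$occupancy < 1 - 1e-6
  if (any(low)) {
    if (keep_major_occupancy) {
      sites <- sites[sites$occupancy >= 0.5, ]
    } else {
      stop("unresolved disorder (occupancy < 1) at sites: ",
           paste(sites$label[low], collapse = ", "), call. = FALSE)
    }
  }

  mols <- .reassemble_molecules(sites, cell, bond_tol)
  new_crystal(cell, mols, ops, sg_label)
}

.normalize_element <- function(x) {
  x <- gsub("[^A-Za-z]", "", x)
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

# Parse CIF loop_ blocks into tag lists + row token lists.
.cif_loops <- function(lines) {
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      tags <- character(); i <- i + 1
      while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1
      }
      rows <- list()
      while (i <= length(lines) && !grepl("^\\s*(_|loop_|data_)", lines[i]) &&
             nzchar(trimws(lines[i]))) {
        toks <- scan(text = lines[i], what = "", quiet = TRUE)
        if (length(toks) == length(tags)) rows <- c(rows, list(toks))
        i <- i + 1
      }
      out <- c(out, list(list(tags = tags, rows = rows)))
    } else {
      i <- i + 1
    }
  }
  out
}

# Unwrap sites across periodic boundaries: bond under minimum image, then
# BFS placing each atom at the image nearest its already-placed neighbour.
.reassemble_molecules <- function(sites, cell, bond_tol = 0.4) {
  n <- nrow(sites)
  frac <- as.matrix(sites[, c("fx", "fy", "fz")])
  rcov <- covalent_radius(sites$element)
  # minimum-image adjacency
  adj <- vector("list", n)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cart0 <- frac_to_cart(frac, cell)
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    cart_s <- frac_to_cart(sweep(frac, 2, -as.numeric(sh)), cell)
    d <- .dist_xyz(cart0, cart_s)
    cut <- outer(rcov, rcov, "+") + bond_tol
    hit <- which(d < cut & d > 0.1, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; j <- hit[r, 2]
      adj[[i]] <- c(adj[[i]], list(list(j = j, shift = as.numeric(sh))))
    }
  }
  placed <- rep(NA_real_, n * 3); dim(placed) <- c(n, 3)
  comp_id <- rep(NA_integer_, n)
  ncomp <- 0
  for (seed in seq_len(n)) {
    if (!is.na(comp_id[seed])) next
    ncomp <- ncomp + 1
    comp_id[seed] <- ncomp
    placed[seed, ] <- frac[seed, ]
    queue <- seed
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      base_shift <- placed[a, ] - frac[a, ]
      for (nb in adj[[a]]) {
        j <- nb$j
        if (!is.na(comp_id[j])) next
        comp_id[j] <- ncomp
        placed[j, ] <- frac[j, ] + base_shift + nb$shift
        queue <- c(queue, j)
      }
    }
  }
  lapply(seq_len(ncomp), function(k) {
    idx <- which(comp_id == k)
    xyz <- frac_to_cart(placed[idx, , drop = FALSE], cell)
    atoms <- tibble::tibble(element = sites$element[idx],
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            label = sites$label[idx])
    perceive_bonds(atoms, tol = bond_tol, name = paste0("mol", k))
  })
}

#' Write a crystal structure to a CIF file
#'
#' Writes cell parameters, the symmetry operations as xyz strings, and all
#' asymmetric-unit atoms in fractional coordinates (full precision, so a
#' write/read cycle round-trips coordinates).
#'
#' @param xtal a `cocryst_crystal`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(xtal, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_cocryst")
  w("_symmetry_space_group_name_H-M '%s'", xtal$space_group_label)
  w("_cell_length_a %.9f", xtal$cell$a)
  w("_cell_length_b %.9f", xtal$cell$b)
  w("_cell_length_c %.9f", xtal$cell$c)
  w("_cell_angle_alpha %.9f", xtal$cell$alpha)
  w("_cell_angle_beta %.9f", xtal$cell$beta)
  w("_cell_angle_gamma %.9f", xtal$cell$gamma)
  w("loop_")
  w("_space_group_symop_operation_xyz")
  for (op in xtal$ops) w("'%s'", .format_symop_xyz(op))
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  w("_atom_site_occupancy")
  cnt <- 0
  for (mol in xtal$asym_molecules) {
    frac <- cart_to_frac(coords(mol), xtal$cell)
    for (a in seq_len(nrow(mol$atoms))) {
      cnt <- cnt + 1
      w("%s%d %s %.9f %.9f %.9f 1.0", mol$atoms$element[a], cnt,
        mol$atoms$element[a], frac[a, 1], frac[a, 2], frac[a, 3])
    }
  }
  invisible(path)
}
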