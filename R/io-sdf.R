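#' Read molecules from an SDF/MOL V2000 file
#'
#' Parses the V2000 connection table: counts line, atom block (coordinates +
#' element), bond block (indices + order). Multi-record SDF files (records
#' separated by `$$$$`) return one molecule per record. Ring perception runs
#' on the file's bond list.
#'
#' @param path SDF or MOL file path.
#' @return list of `cocryst_molecule` (length one for a single MOL file).
#' @export
read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (length(rec) < 4 || !any(nzchar(trimws(rec)))) next
    name <- trimws(rec[1])
    counts <- rec[4]
    na <- as.integer(substr(counts, 1, 3))
    nb <- as.integer(substr(counts, 4, 6))
    atom_lines <- rec[5:(4 + na)]
    atoms <- tibble::tibble(
      element = trimws(substr(atom_lines, 32, 34)),
      x = as.numeric(substr(atom_lines, 1, 10)),
      y = as.numeric(substr(atom_lines, 11, 20)),
      z = as.numeric(substr(atom_lines, 21, 30))
    )
    bonds <- NULL
    if (nb > 0) {
      bond_lines <- rec[(5 + na):(4 + na + nb)]
      ord_code <- as.integer(substr(bond_lines, 7, 9))
      bonds <- tibble::tibble(
        i = as.integer(substr(bond_lines, 1, 3)),
        j = as.integer(substr(bond_lines, 4, 6)),
        order = c("single", "double", "triple", "aromatic")[ord_code]
      )
    }
    mol <- new_molecule(atoms, bonds, name = if (nzchar(name)) name else "mol")
    out <- c(out, list(.detect_rings(mol)))
  }
  out
}

#' Write molecules to an SDF V2000 file
#'
#' @param mols a `cocryst_molecule` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "cocryst_molecule")) mols <- list(mols)
  con <- file(path, "w"); on.exit(close(con))
  for (mol in mols) {
    na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    writeLines(c(mol$name, "  cocryst", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    for (a in seq_len(na)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         mol$atoms$x[a], mol$atoms$y[a], mol$atoms$z[a],
                         mol$atoms$element[a]), con)
    }
    ord <- match(mol$bonds$order, c("single", "double", "triple", "aromatic"))
    for (b in seq_len(nb)) {
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i[b], mol$bonds$j[b], ord[b]),
                 con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read molecules from a MOL2 file
#'
#' Parses `@<TRIPOS>MOLECULE`, `ATOM` and `BOND` sections; partial charges in
#' column 9 of the atom block are kept when present.
#'
#' @param path MOL2 file path.
#' @return list of `cocryst_molecule`.
#' @export
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  out <- list()
  bounds <- c(mol_starts, length(lines) + 1)
  for (m in seq_along(mol_starts)) {
    sec <- lines[bounds[m]:(bounds[m + 1] - 1)]
    name <- trimws(sec[2])
    a0 <- grep("^@<TRIPOS>ATOM", sec)[1]
    b0 <- grep("^@<TRIPOS>BOND", sec)[1]
    ends <- c(grep("^@<TRIPOS>", sec), length(sec) + 1)
    nxt <- function(s) min(ends[ends > s]) - 1
    atom_lines <- sec[(a0 + 1):nxt(a0)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    tok <- strsplit(trimws(atom_lines), "\\s+")
    atoms <- tibble::tibble(
      element = .normalize_element(sub("\\..*$", "",
                                       vapply(tok, `[[`, "", 6))),
      x = as.numeric(vapply(tok, `[[`, "", 3)),
      y = as.numeric(vapply(tok, `[[`, "", 4)),
      z = as.numeric(vapply(tok, `[[`, "", 5)),
      charge = vapply(tok, function(t) {
        if (length(t) >= 9) as.numeric(t[9]) else 0
      }, numeric(1))
    )
    bonds <- NULL
    if (!is.na(b0)) {
      bond_lines <- sec[(b0 + 1):nxt(b0)]
      bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
      bt <- strsplit(trimws(bond_lines), "\\s+")
      otype <- vapply(bt, `[[`, "", 4)
      bonds <- tibble::tibble(
        i = as.integer(vapply(bt, `[[`, "", 2)),
        j = as.integer(vapply(bt, `[[`, "", 3)),
        order = dplyr::case_match(otype, "1" ~ "single", "2" ~ "double",
                                  "3" ~ "triple", "ar" ~ "aromatic",
                                  "am" ~ "single", .default = "single")
      )
    }
    mol <- new_molecule(atoms, bonds, name = if (nzchar(name)) name else "mol")
    out <- c(out, list(.detect_rings(mol)))
  }
  out
}
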