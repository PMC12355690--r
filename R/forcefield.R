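#' Dreiding-style force-field parameters
#'
#' Parameters for the intermolecular energy model: per-type Lennard-Jones
#' 12-6 well depths `d0` (kcal/mol) and equilibrium distances `r0`
#' (Angstrom), the explicit hydrogen-bond 12-10 well (`d_hb`, kcal/mol;
#' `r_hb`, Angstrom donor-acceptor), the distance-dependent dielectric
#' prefactor `eps0` (so eps(r) = eps0 * r), and the combining rule for
#' unlike LJ pairs ("geometric" or "arithmetic" for r0; well depths always
#' combine geometrically).
#'
#' @param path optional parameter file (see [write_forcefield()]); default
#'   loads the packaged standard Dreiding values.
#' @return a `cocryst_forcefield` list: `types` tibble (`ff_type`, `r0`,
#'   `d0`), `d_hb`, `r_hb`, `eps0`, `combining`, plus H-bond activation
#'   window `hb_rmax` (4.5 A) and `hb_theta_min` (90 degrees).
#' @export
dreiding_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dreiding_params.tsv", package = "cocryst")
  }
  read_forcefield(path)
}

#' Read a force-field parameter file
#' @param path TSV with columns `param`, `ff_type`, `r0`, `d0` (rows with
#'   `param == "lj"` define per-type LJ parameters; `"hbond"`,
#'   `"dielectric"`, `"combining"`, `"hb_window"` rows define the scalars).
#' @return a `cocryst_forcefield`.
#' @export
read_forcefield <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE,
                                            colClasses = c("character", "character",
                                                           "numeric", "numeric")))
  lj <- tb[tb$param == "lj", c("ff_type", "r0", "d0")]
  hb <- tb[tb$param == "hbond", ]
  die <- tb[tb$param == "dielectric", ]
  comb <- tb[tb$param == "combining", ]
  win <- tb[tb$param == "hb_window", ]
  stopifnot(nrow(lj) > 0, nrow(hb) == 1, nrow(die) == 1, nrow(comb) == 1)
  ff <- structure(list(
    types = lj,
    r_hb = hb$r0, d_hb = hb$d0,
    eps0 = die$r0,
    combining = comb$ff_type,
    hb_rmax = if (nrow(win)) win$r0 else 4.5,
    hb_theta_min = if (nrow(win)) win$d0 else 90
  ), class = "cocryst_forcefield")
  stopifnot(all(ff$types$r0 > 0), all(ff$types$d0 > 0),
            ff$d_hb > 0, ff$r_hb > 0, ff$eps0 > 0,
            ff$combining %in% c("geometric", "arithmetic"))
  ff
}

#' Write a force-field parameter file
#' @param ff a `cocryst_forcefield`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_forcefield <- function(ff, path) {
  tb <- rbind(
    data.frame(param = "lj", ff_type = ff$types$ff_type,
               r0 = ff$types$r0, d0 = ff$types$d0),
    data.frame(param = "hbond", ff_type = "", r0 = ff$r_hb, d0 = ff$d_hb),
    data.frame(param = "dielectric", ff_type = "", r0 = ff$eps0, d0 = 0),
    data.frame(param = "combining", ff_type = ff$combining, r0 = 0, d0 = 0),
    data.frame(param = "hb_window", ff_type = "", r0 = ff$hb_rmax,
               d0 = ff$hb_theta_min)
  )
  utils::write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cocryst_forcefield <- function(x, ...) {
  cat(sprintf("<cocryst_forcefield: %d LJ types, D_hb=%.3g kcal/mol, R_hb=%.3g A, eps0=%.3g, %s combining>\n",
              nrow(x$types), x$d_hb, x$r_hb, x$eps0, x$combining))
  invisible(x)
}

# per-atom LJ parameter lookup, with error naming missing types
.ff_atom_params <- function(ff, types) {
  idx <- match(types, ff$types$ff_type)
  if (anyNA(idx)) {
    stop("missing force-field parameters for type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  list(r0 = ff$types$r0[idx], d0 = ff$types$d0[idx])
}
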