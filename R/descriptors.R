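#' Bounding-box shape descriptors of a molecule
#'
#' The molecule is aligned to the principal axes of its atomic point cloud
#' (PCA frame, so the result is rotation/translation invariant) and enclosed
#' in a rectangular box inflated by the van der Waals radii of the extreme
#' atoms along each axis: the extent along axis u is
#' `max_i(proj_i + r_i) - min_i(proj_i - r_i)`. Axes are sorted long >=
#' medium >= short. A single atom gives all axes `2 r_vdw`; a strictly
#' planar molecule's short axis is carried by the vdW radii alone.
#'
#' @param mol a `cocryst_molecule` with coordinates and vdW radii.
#' @return a tibble with one row: `s_axis` (Angstrom), `s_over_l`, `m_over_l`,
#'   plus the raw `l_axis`, `m_axis`.
#' @export
bounding_box_descriptors <- function(mol) {
  xyz <- coords(mol)
  r <- mol$atoms$vdw_radius
  cen <- colMeans(xyz)
  xc <- sweep(xyz, 2, cen)
  if (nrow(xyz) == 1) {
    axes_ext <- rep(2 * r[1], 3)
  } else {
    sv <- svd(xc)
    proj <- xc %*% sv$v   # principal-axis frame
    axes_ext <- vapply(1:3, function(k) {
      max(proj[, k] + r) - min(proj[, k] - r)
    }, numeric(1))
  }
  sorted <- sort(axes_ext, decreasing = TRUE)
  tibble::tibble(
    s_axis = sorted[3],
    s_over_l = sorted[3] / sorted[1],
    m_over_l = sorted[2] / sorted[1],
    l_axis = sorted[1],
    m_axis = sorted[2]
  )
}

#' Polarity descriptors: N+O fraction and dipole moment
#'
#' `no_fraction` is the fraction of nitrogen and oxygen among heavy atoms by
#' default (set `denominator = "all"` for an all-atom denominator). The
#' dipole is `|sum q_i r_i|` in Debye about the centre of charge; for a
#' net-charged molecule the dipole is origin-dependent, so it is computed
#' about the centre of mass with a warning.
#'
#' @param mol a typed `cocryst_molecule` with partial charges.
#' @param denominator "heavy" (default) or "all".
#' @return a tibble with one row: `no_fraction`, `dipole` (Debye).
#' @export
polarity_descriptors <- function(mol, denominator = c("heavy", "all")) {
  denominator <- match.arg(denominator)
  el <- mol$atoms$element
  n_no <- sum(el %in% c("N", "O"))
  denom <- if (denominator == "heavy") sum(el != "H") else length(el)
  q <- mol$atoms$charge
  xyz <- coords(mol)
  net <- sum(q)
  if (abs(net) > 1e-6) {
    warning("net-charged molecule: dipole is origin-dependent, ",
            "computed about the centre of mass", call. = FALSE)
    mass <- atomic_mass(el)
    origin <- colSums(xyz * mass) / sum(mass)
  } else if (any(abs(q) > 0)) {
    # centre of charge (absolute-charge weighted)
    origin <- colSums(xyz * abs(q)) / sum(abs(q))
  } else {
    origin <- colMeans(xyz)
  }
  mu <- colSums(sweep(xyz, 2, origin) * q)
  tibble::tibble(
    no_fraction = if (denom > 0) n_no / denom else 0,
    dipole = sqrt(sum(mu^2)) * .DEBYE_PER_EA
  )
}

#' All five molecular-complementarity descriptors
#'
#' @param mol a typed `cocryst_molecule`.
#' @inheritParams polarity_descriptors
#' @return one-row tibble: `s_axis`, `s_over_l`, `m_over_l`, `no_fraction`,
#'   `dipole`.
#' @export
mc_descriptors <- function(mol, denominator = "heavy") {
  dplyr::bind_cols(
    bounding_box_descriptors(mol)[, c("s_axis", "s_over_l", "m_over_l")],
    polarity_descriptors(mol, denominator)
  )
}

#' Default molecular-complementarity PASS windows
#'
#' Difference windows per descriptor: a coformer PASSes a descriptor when
#' `|descriptor(target) - descriptor(coformer)| <= window`. These package
#' defaults are deliberately conservative, auditable values; override them
#' with your own table (same columns) or file for calibrated screening.
#'
#' @param path optional TSV with columns `descriptor`, `window` overriding
#'   the packaged defaults.
#' @return tibble with columns `descriptor`, `window`.
#' @export
mc_default_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mc_thresholds.tsv", package = "cocryst")
  }
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tb)
}

#' Stage-1 molecular-complementarity screen
#'
#' Evaluates the five descriptors for the target and every library molecule
#' and flags each descriptor PASS when the absolute difference lies inside
#' the configured window; `overall` is PASS iff all five PASS. Library order
#' is preserved. Entries whose descriptor evaluation fails are marked
#' UNEVALUATED and the run continues.
#'
#' @param target a typed `cocryst_molecule`.
#' @param library list of typed `cocryst_molecule`.
#' @param thresholds threshold tibble (see [mc_default_thresholds()]).
#' @param denominator passed to [polarity_descriptors()].
#' @return tibble: one row per coformer with both molecules' descriptors,
#'   per-descriptor `pass_*` flags, and `overall` ("PASS"/"FAIL"/
#'   "UNEVALUATED").
#' @export
mc_screen <- function(target, library, thresholds = mc_default_thresholds(),
                      denominator = "heavy") {
  desc_names <- c("s_axis", "s_over_l", "m_over_l", "no_fraction", "dipole")
  stopifnot(all(desc_names %in% thresholds$descriptor))
  win <- stats::setNames(thresholds$window, thresholds$descriptor)[desc_names]
  dt <- mc_descriptors(target, denominator)
  rows <- purrr::imap(library, function(cf, k) {
    dc <- tryCatch(mc_descriptors(cf, denominator), error = function(e) NULL)
    if (is.null(dc)) {
      return(tibble::tibble(target = target$name, coformer = cf$name,
                            overall = "UNEVALUATED"))
    }
    flags <- abs(unlist(dt[desc_names]) - unlist(dc[desc_names])) <= win
    out <- tibble::tibble(target = target$name, coformer = cf$name)
    for (d in desc_names) {
      out[[paste0("target_", d)]] <- dt[[d]]
      out[[paste0("coformer_", d)]] <- dc[[d]]
    }
    for (d in desc_names) out[[paste0("pass_", d)]] <- unname(flags[d])
    out$overall <- if (all(flags)) "PASS" else "FAIL"
    out
  })
  dplyr::bind_rows(rows)
}
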