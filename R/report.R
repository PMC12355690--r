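#' Molecular weight from a chemical formula
#'
#' @param formula a formula string like "C15H10O7" or "H2O".
#' @return molecular weight in g/mol (standard atomic weights).
#' @export
molecular_weight <- function(formula) {
  vapply(formula, function(f) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    toks <- toks[nzchar(toks)]
    if (!length(toks) || paste(toks, collapse = "") != f) {
      stop("cannot parse formula: ", f, call. = FALSE)
    }
    total <- 0
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      cnt <- gsub("[^0-9]", "", t)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      total <- total + atomic_mass(el) * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' Theoretical mass fraction of a leaving component
#'
#' For a multi-component solid with stoichiometric counts, the mass
#' percentage of the component lost on heating:
#' `100 * count * MW(leaving) / sum(count_i * MW_i)`.
#'
#' @param components data frame with columns `name`, `formula`, `count`.
#' @param leaving the `name` of the leaving component.
#' @return mass fraction in percent.
#' @export
stoichiometric_mass_fraction <- function(components, leaving) {
  components <- tibble::as_tibble(components)
  stopifnot(all(c("name", "formula", "count") %in% names(components)))
  if (!leaving %in% components$name) {
    stop("leaving component '", leaving, "' not among: ",
         paste(components$name, collapse = ", "), call. = FALSE)
  }
  mw <- molecular_weight(components$formula)
  tot <- sum(components$count * mw)
  k <- match(leaving, components$name)
  100 * components$count[k] * mw[k] / tot
}

#' Printed reference synthon table (shipped fixture)
#'
#' The six strongest synthons of the quercetin-imidazole cocrystal as
#' printed (type, centroid distance in Angstrom, interaction energy in
#' kcal/mol, percent of lattice energy), for use as input to
#' [aggregate_by_type()] and the report builders.
#'
#' @return tibble with columns `synthon`, `molecules`, `type_label`,
#'   `centroid_distance`, `e_total`, `percent_of_lattice`.
#' @export
reference_synthon_table <- function() {
  path <- system.file("extdata", "table3_synthons.tsv", package = "cocryst")
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Printed reference coformer ranking scores (shipped fixture)
#'
#' The published positive multicomponent hydrogen-bond-propensity scores of
#' the quercetin coformer screen, as input for [rank_coformers()].
#'
#' @return tibble with columns `rank`, `coformer`, `delta`.
#' @export
reference_mchbp_scores <- function() {
  path <- system.file("extdata", "table1_mchbp_scores.tsv", package = "cocryst")
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Assemble publication-style result tables from stage outputs
#'
#' Produces stable-column tables mirroring the screening-ranking, synthon
#' and facet-report layouts; energies are carried in both kcal/mol and
#' kJ/mol (factor 4.184 exactly). Empty inputs yield header-only tables;
#' the call is idempotent.
#'
#' @param hbp ranked coformer tibble (from [rank_coformers()]), or NULL.
#' @param synthons synthon ranking (from [rank_synthons()]), or NULL.
#' @param facets facet/surface report (from [surface_report()] or
#'   [facet_energies()]), or NULL.
#' @return named list of tibbles: `ranking`, `synthons`, `facets`.
#' @export
aggregate_tables <- function(hbp = NULL, synthons = NULL, facets = NULL) {
  ranking <- if (is.null(hbp) || nrow(hbp) == 0) {
    tibble::tibble(rank = integer(), coformer = character(), delta = numeric())
  } else {
    tibble::tibble(rank = hbp$rank, coformer = hbp$coformer, delta = hbp$delta)
  }
  syn <- if (is.null(synthons) || nrow(synthons) == 0) {
    tibble::tibble(rank = integer(), type_label = character(),
                   centroid_distance = numeric(), e_total_kcal = numeric(),
                   e_total_kj = numeric(), percent_of_lattice = numeric())
  } else {
    tibble::tibble(rank = synthons$rank, type_label = synthons$type_label,
                   centroid_distance = synthons$centroid_distance,
                   e_total_kcal = synthons$e_total,
                   e_total_kj = synthons$e_total * .KJ_PER_KCAL,
                   percent_of_lattice = synthons$percent_of_lattice)
  }
  fac <- if (is.null(facets) || nrow(facets) == 0) {
    tibble::tibble(label = character(), aromatic_density = numeric(),
                   e_att_nonpolar_kj = numeric(), hbd_density = numeric(),
                   hba_density = numeric(), e_att_polar_kj = numeric())
  } else {
    cols <- intersect(c("label", "h", "k", "l", "aromatic_density",
                        "e_att_nonpolar_kj", "hbd_density", "hba_density",
                        "e_att_polar_kj", "rugosity"), names(facets))
    tibble::as_tibble(facets[, cols])
  }
  list(ranking = ranking, synthons = syn, facets = fac)
}

#' Run the full in-silico cocrystal workflow on one configuration
#'
#' Stages run in order: molecular-complementarity screen, propensity-
#' difference ranking, synthon energy analysis, attachment-energy
#' morphology, facet surface chemistry. Any stage failure is recorded in
#' the manifest and later stages are skipped. All randomness is controlled
#' by `config$seed`, so a rerun with the same configuration reproduces the
#' outputs (the manifest records a hash per output).
#'
#' @param config a list: `seed` (default 1); `target`, `library` (molecules;
#'   defaults generated), `propensities` (long table; default generated),
#'   `crystal` (a `cocryst_crystal`; default ribbon fixture), `params`
#'   (force field), `cutoff` (Angstrom, default 20), `max_index` (default
#'   1), `stages` (character subset of mc/hbp/energy/morphology/surface).
#' @return list: `manifest` tibble (stage, status, hash, seconds) and one
#'   entry per completed stage (`mc`, `hbp`, `synthons`, `habit`,
#'   `surface`), plus `tables` from [aggregate_tables()].
#' @export
run_workflow <- function(config = list()) {
  cfg <- utils::modifyList(list(
    seed = 1, cutoff = 20, max_index = 1,
    stages = c("mc", "hbp", "energy", "morphology", "surface")
  ), config)
  set.seed(cfg$seed)
  if (is.null(cfg$params)) cfg$params <- dreiding_params()
  out <- list()
  manifest <- list()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed || !(name %in% cfg$stages)) {
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        stage = name, status = if (failed) "skipped" else "disabled",
        hash = NA_character_, seconds = NA_real_)
      return(NULL)
    }
    t0 <- proc.time()[3]
    res <- tryCatch(fun(), error = function(e) e)
    secs <- proc.time()[3] - t0
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest[[length(manifest) + 1]] <<- tibble::tibble(
        stage = name, status = paste("failed:", conditionMessage(res)),
        hash = NA_character_, seconds = secs)
      return(NULL)
    }
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = name, status = "ok", hash = rlang::hash(res), seconds = secs)
    res
  }
  out$mc <- run_stage("mc", function() {
    if (is.null(cfg$library)) {
      gen <- make_coformer_library(seed = cfg$seed)
      cfg$target <<- gen$target
      cfg$library <<- gen$library
    }
    if (is.null(cfg$target)) cfg$target <<- make_planar_donor_molecule(3, 2)
    mc_screen(cfg$target, cfg$library)
  })
  out$hbp <- run_stage("hbp", function() {
    if (is.null(cfg$propensities)) {
      cfg$propensities <<- make_propensity_table(seed = cfg$seed)$table
    }
    rank_coformers(score_propensity_table(cfg$propensities, "target"))
  })
  out$synthons <- run_stage("energy", function() {
    if (is.null(cfg$crystal)) cfg$crystal <<- make_ribbon_crystal(seed = cfg$seed)
    rank_synthons(cfg$crystal, cfg$params, cutoff = cfg$cutoff)
  })
  out$habit <- run_stage("morphology", function() {
    fe <- facet_energies(cfg$crystal, cfg$params, max_index = cfg$max_index,
                         cutoff = cfg$cutoff)
    list(facet_energies = fe, habit = wulff_habit(fe, cfg$crystal$cell))
  })
  out$surface <- run_stage("surface", function() {
    facets <- out$habit$habit$facets
    surface_report(cfg$crystal, facets, cfg$params, cutoff = cfg$cutoff,
                   grid_spacing = 0.4)
  })
  out$tables <- aggregate_tables(hbp = out$hbp, synthons = out$synthons,
                                 facets = out$surface)
  out$manifest <- dplyr::bind_rows(manifest)
  out$config <- cfg[setdiff(names(cfg), c("library", "crystal", "params"))]
  out
}
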