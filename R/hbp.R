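#' Hydrogen-bond-propensity difference for one target/coformer pair
#'
#' The score is `delta = max(p_het) - max(max(p_tt), max(p_cc))`: the best
#' heteromeric donor-acceptor propensity between target and coformer minus
#' the best homomeric propensity of either component. Positive values favour
#' cocrystallization. Empty homomeric sets are treated as propensity 0 (the
#' most permissive convention). Ties among heteromeric maxima are reported
#' in full.
#'
#' @param p_het numeric heteromeric propensities in `[0, 1]` (non-empty), or
#'   a data frame with columns `propensity` and optionally `donor_group`,
#'   `acceptor_group` for tie reporting.
#' @param p_tt,p_cc homomeric propensities of target and coformer (may be
#'   empty).
#' @param coformer coformer name carried into the result.
#' @return one-row tibble: `coformer`, `p_het_max`, `p_homo_max`, `delta`,
#'   and a list-column `best_pairs` with all maximizing heteromeric pairs.
#' @export
delta_hbp <- function(p_het, p_tt = numeric(), p_cc = numeric(),
                      coformer = "coformer") {
  het_df <- if (is.data.frame(p_het)) p_het else
    tibble::tibble(propensity = as.numeric(p_het))
  vals <- function(x) if (is.data.frame(x)) x$propensity else as.numeric(x)
  p_tt <- vals(p_tt); p_cc <- vals(p_cc)
  all_p <- c(het_df$propensity, p_tt, p_cc)
  if (length(het_df$propensity) == 0) {
    stop("heteromeric propensity set must be non-empty", call. = FALSE)
  }
  if (any(all_p < 0 | all_p > 1)) {
    stop("propensities must lie in [0, 1]", call. = FALSE)
  }
  p_het_max <- max(het_df$propensity)
  p_homo_max <- max(c(p_tt, 0), c(p_cc, 0))
  best <- het_df[abs(het_df$propensity - p_het_max) < 1e-12, , drop = FALSE]
  tibble::tibble(
    coformer = coformer,
    p_het_max = p_het_max,
    p_homo_max = p_homo_max,
    delta = p_het_max - p_homo_max,
    best_pairs = list(tibble::as_tibble(best))
  )
}

#' Score every coformer in a long-format propensity table
#'
#' The table holds one row per donor-group/acceptor-group pair with columns
#' `mol_a`, `mol_b`, `propensity` (and optionally `donor_group`,
#' `acceptor_group`). Heteromeric rows are those pairing `target` with the
#' coformer; homomeric rows pair a molecule with itself.
#'
#' @param table propensity table (long format).
#' @param target target molecule name as it appears in `mol_a`/`mol_b`.
#' @return tibble of [delta_hbp()] rows, one per coformer found.
#' @export
score_propensity_table <- function(table, target) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("mol_a", "mol_b", "propensity") %in% names(table)))
  others <- setdiff(unique(c(table$mol_a, table$mol_b)), target)
  p_tt <- table$propensity[table$mol_a == target & table$mol_b == target]
  rows <- purrr::map(others, function(cf) {
    het <- table[(table$mol_a == target & table$mol_b == cf) |
                 (table$mol_a == cf & table$mol_b == target), , drop = FALSE]
    p_cc <- table$propensity[table$mol_a == cf & table$mol_b == cf]
    if (nrow(het) == 0) return(NULL)
    delta_hbp(het, p_tt, p_cc, coformer = cf)
  })
  dplyr::bind_rows(rows)
}

#' Rank scored coformers by hydrogen-bond-propensity difference
#'
#' Sorts descending by `delta` with a stable tie-break on coformer name, and
#' reports the positive/zero/negative partition.
#'
#' @param scores tibble with columns `coformer`, `delta` (e.g. from
#'   [delta_hbp()] or [score_propensity_table()]).
#' @param zero_tol scores with `|delta| <= zero_tol` count as zero
#'   (default 1e-12; the partition uses strict inequalities beyond it).
#' @return the input sorted with a `rank` column; attributes `n_positive`,
#'   `n_zero`, `n_negative` carry the partition counts.
#' @export
rank_coformers <- function(scores, zero_tol = 1e-12) {
  scores <- tibble::as_tibble(scores)
  out <- dplyr::arrange(scores, dplyr::desc(.data$delta), .data$coformer)
  out$rank <- seq_len(nrow(out))
  attr(out, "n_positive") <- sum(out$delta > zero_tol)
  attr(out, "n_zero") <- sum(abs(out$delta) <= zero_tol)
  attr(out, "n_negative") <- sum(out$delta < -zero_tol)
  out
}

#' Logistic surrogate hydrogen-bond propensity
#'
#' A configurable logistic model `p = 1/(1 + exp(-(b0 + beta . x)))` over
#' functional-group pair features, standing in for database-trained
#' propensity models so the pipeline runs end-to-end on synthetic data.
#'
#' @param features numeric vector or matrix (rows = pairs) of features.
#' @param coefficients numeric vector: intercept first, then one slope per
#'   feature column.
#' @return propensities in `(0, 1)`.
#' @export
logistic_propensity <- function(features, coefficients) {
  x <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (length(coefficients) != ncol(x) + 1) {
    stop("coefficient length ", length(coefficients),
         " does not match 1 + ", ncol(x), " features", call. = FALSE)
  }
  eta <- coefficients[1] + drop(x %*% coefficients[-1])
  stats::plogis(eta)
}

#' Fit the logistic surrogate propensity model
#'
#' Ordinary logistic regression (glm, binomial) of observed hydrogen-bond
#' formation outcomes on functional-group pair features.
#'
#' @param data data frame with an `outcome` column (0/1) and feature columns.
#' @param formula model formula (default `outcome ~ .`).
#' @return an object of class `cocryst_hbp_fit` wrapping the glm fit.
#' @export
fit_propensity_model <- function(data, formula = outcome ~ .) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  structure(list(fit = fit), class = "cocryst_hbp_fit")
}

#' @export
print.cocryst_hbp_fit <- function(x, ...) {
  cat("<cocryst_hbp_fit: logistic surrogate propensity model>\n")
  print(stats::coef(x$fit))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy cocryst_hbp_fit
#' @export
tidy.cocryst_hbp_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2],
    statistic = s[, 3], p.value = s[, 4]
  )
}

#' @method glance cocryst_hbp_fit
#' @export
glance.cocryst_hbp_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    null.deviance = f$null.deviance, df.null = f$df.null,
    deviance = f$deviance, df.residual = f$df.residual,
    AIC = stats::AIC(f), nobs = length(f$y)
  )
}

#' @export
predict.cocryst_hbp_fit <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata = newdata, type = "response")
}
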