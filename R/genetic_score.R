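#' Compute a weighted or unweighted genetic score from allele dosages
#'
#' The raw genetic score for individual `j` is `sum_i beta_i * d_ij`, where
#' `beta_i` is the per-allele exposure effect from the instrument panel and
#' `d_ij` the effect-allele dosage in `[0, 2]`. The unweighted variant sets
#' all weights to 1 (a simple allele count), used as a sensitivity analysis.
#'
#' Missing dosages are handled per `missing_policy`: `"impute_eaf"` (default)
#' replaces a missing dosage with its Hardy-Weinberg expectation `2 * eaf`
#' from the panel; `"fail"` raises an error. Individuals with *all* dosages
#' missing are never imputed: their score is `NA` and a warning is emitted so
#' they can be excluded downstream.
#'
#' @param dosages Numeric matrix or data frame, individuals x SNPs, with
#'   columns named by rsid. Values in `[0, 2]` or `NA`.
#' @param panel Instrument panel tibble (see [read_panel()]); every panel rsid
#'   must have a dosage column.
#' @param weighted Use the panel's `beta_exposure` weights (default) or plain
#'   allele counts.
#' @param missing_policy `"impute_eaf"` or `"fail"`.
#' @return Numeric vector of raw scores, one per row of `dosages`.
#' @examples
#' panel <- tibble::tibble(rsid = c("rs1", "rs2", "rs3"),
#'                         effect_allele = "A", other_allele = "G",
#'                         eaf = 0.5, beta_exposure = c(0.1, 0.2, 0.3),
#'                         se_exposure = 0.01)
#' d <- matrix(c(2, 1, 0), nrow = 1, dimnames = list(NULL, panel$rsid))
#' compute_gs(d, panel)  # 0.1*2 + 0.2*1 + 0.3*0 = 0.4
#' @export
compute_gs <- function(dosages, panel, weighted = TRUE,
                       missing_policy = c("impute_eaf", "fail")) {
  missing_policy <- match.arg(missing_policy)
  d <- as.matrix(dosages)
  storage.mode(d) <- "double"
  miss_cols <- setdiff(panel$rsid, colnames(d))
  if (length(miss_cols)) {
    stop("dosage matrix lacks panel SNP(s): ", paste(miss_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- d[, panel$rsid, drop = FALSE]
  rng <- range(d, na.rm = TRUE)
  if (!all(is.na(d)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }

  all_missing <- rowSums(!is.na(d)) == 0L
  if (anyNA(d)) {
    if (missing_policy == "fail") stop("missing dosages with missing_policy = 'fail'", call. = FALSE)
    exp_dose <- 2 * panel$eaf
    na_idx <- which(is.na(d), arr.ind = TRUE)
    d[na_idx] <- exp_dose[na_idx[, 2L]]
  }

  w <- if (weighted) panel$beta_exposure else rep(1, nrow(panel))
  gs <- as.numeric(d %*% w)
  if (any(all_missing)) {
    warning(sum(all_missing), " individual(s) with all dosages missing; score set to NA",
            call. = FALSE)
    gs[all_missing] <- NA_real_
  }
  gs
}

#' Calibrate a raw genetic score to exposure units
#'
#' The raw score is on an arbitrary scale (a sum of per-allele effects). To
#' express it in the exposure's units (kg/m^2 for a BMI score), the observed
#' exposure is regressed on the raw score among controls by ordinary least
#' squares, `exposure ~ beta0 + beta1 * GS + error`, and the fitted line is
#' applied to every individual: `calibrated = beta0 + beta1 * GS`. The
#' calibrated score is a linear transform of the raw score, so the two are
#' perfectly correlated; calibration changes the units of downstream effect
#' estimates, not their z-statistics.
#'
#' @param gs Numeric vector of raw scores for all individuals.
#' @param exposure Observed exposure values (controls typically; `NA` where
#'   unmeasured, e.g. masked case values).
#' @param controls Optional logical/index vector selecting the calibration
#'   subset (e.g. controls). Default: all individuals with a non-missing
#'   exposure and score.
#' @return An object of class `gs_calibration`: a list with `beta0`, `beta1`,
#'   `n_fit` (individuals in the fit), `r_squared`, and `calibrated`, the
#'   calibrated score for all of `gs`.
#' @examples
#' gs <- c(1, 2, 3, 4)
#' calibrate_score(gs, 5 + 2 * gs)$beta1  # exactly 2
#' # applying published constants: 18.99 + 0.451 * 10 = 23.5
#' apply_calibration(list(beta0 = 18.99, beta1 = 0.451), 10)
#' @export
calibrate_score <- function(gs, exposure, controls = NULL) {
  stopifnot(length(gs) == length(exposure))
  sel <- if (is.null(controls)) rep(TRUE, length(gs)) else {
    if (is.logical(controls)) controls else seq_along(gs) %in% controls
  }
  sel <- sel & !is.na(gs) & !is.na(exposure)
  if (sum(sel) < 3L) stop("need at least 3 complete calibration observations", call. = FALSE)
  if (stats::var(gs[sel]) == 0) stop("zero score variance: calibration fit is degenerate", call. = FALSE)

  fit <- stats::lm(exposure[sel] ~ gs[sel])
  beta0 <- unname(stats::coef(fit)[1L])
  beta1 <- unname(stats::coef(fit)[2L])
  structure(
    list(
      beta0 = beta0,
      beta1 = beta1,
      n_fit = sum(sel),
      r_squared = stats::cor(gs[sel], exposure[sel])^2,
      calibrated = beta0 + beta1 * gs
    ),
    class = "gs_calibration"
  )
}

#' @rdname calibrate_score
#' @param calibration A `gs_calibration` object (or any list with `beta0`,
#'   `beta1`).
#' @return For `apply_calibration()`: `beta0 + beta1 * gs`.
#' @export
apply_calibration <- function(calibration, gs) {
  calibration$beta0 + calibration$beta1 * gs
}

#' @export
print.gs_calibration <- function(x, ...) {
  cat(sprintf("Genetic-score calibration (n = %d)\n", x$n_fit))
  cat(sprintf("  intercept beta0 = %.4g, slope beta1 = %.4g\n", x$beta0, x$beta1))
  cat(sprintf("  R^2 = %.4g (%.3g%% of exposure variance)\n", x$r_squared, 100 * x$r_squared))
  invisible(x)
}

#' Fraction of exposure variance explained by the score
#'
#' The coefficient of determination of the linear regression of the observed
#' exposure on the score, i.e. the squared Pearson correlation. Invariant
#' under linear rescaling of the score, so raw and calibrated scores give the
#' same value.
#'
#' @inheritParams calibrate_score
#' @return R-squared in `[0, 1]`.
#' @export
variance_explained <- function(gs, exposure) {
  ok <- !is.na(gs) & !is.na(exposure)
  if (sum(ok) < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (stats::var(gs[ok]) == 0) stop("zero score variance", call. = FALSE)
  stats::cor(gs[ok], exposure[ok])^2
}

#' Bin a calibrated score into ordinal exposure categories
#'
#' Categories are left-closed, right-open intervals defined by ascending
#' cutpoints, with an open-ended top group; the lowest interval (below the
#' first cutpoint) is the reference. With the default cutpoints the groups
#' are `<25.5`, `[25.5,26)`, `[26,26.5)` and `>=26.5` kg/m^2 — a deliberately
#' narrow grid, because a polygenic score predicts only a narrow slice of the
#' BMI range.
#'
#' @param calibrated Numeric vector of calibrated scores (exposure units).
#' @param cutpoints Strictly ascending numeric cutpoints.
#' @return A factor whose first level is the reference (lowest) group.
#' @examples
#' categorize_score(c(24, 25.5, 26.0, 30))
#' @export
categorize_score <- function(calibrated, cutpoints = c(25.5, 26.0, 26.5)) {
  if (length(cutpoints) == 0L) stop("cutpoints must be non-empty", call. = FALSE)
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("cutpoints must be strictly ascending", call. = FALSE)
  }
  labs <- c(
    sprintf("<%g", cutpoints[1L]),
    if (length(cutpoints) > 1L) {
      sprintf("[%g,%g)", cutpoints[-length(cutpoints)], cutpoints[-1L])
    },
    sprintf(">=%g", cutpoints[length(cutpoints)])
  )
  cut(calibrated, breaks = c(-Inf, cutpoints, Inf), labels = labs, right = FALSE)
}
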