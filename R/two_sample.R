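#' Per-SNP Wald ratio causal estimates with delta-method standard errors
#'
#' For each harmonized instrument, the causal effect of the exposure on the
#' outcome is the Wald ratio `beta_causal = beta_outcome / beta_exposure`
#' (log odds ratio of the outcome per unit of exposure). Its standard error
#' is propagated by the delta method,
#' `se = sqrt(se_outcome^2 / beta_exposure^2 +
#'            se_exposure^2 * beta_outcome^2 / beta_exposure^4)`;
#' `se_mode = "first_order"` drops the second (exposure-uncertainty) term,
#' the convention of classic summary-statistics IVW where the exposure
#' estimates come from a much larger study.
#'
#' Instruments with `|beta_exposure| / se_exposure < 2` are flagged `weak`
#' but retained.
#'
#' @param pairs Harmonized pairs from [harmonize()] (rows with a dropped
#'   `action` are excluded), or any tibble with columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (and optionally `rsid`).
#' @param se_mode `"delta"` (default) or `"first_order"`.
#' @return A tibble with columns `rsid`, `beta_causal`, `se_causal`, `weak`.
#' @examples
#' pairs <- tibble::tibble(rsid = "rs1", beta_exposure = 0.05, se_exposure = 0.004,
#'                         beta_outcome = -0.02, se_outcome = 0.01)
#' wald_ratio(pairs)
#' @export
wald_ratio <- function(pairs, se_mode = c("delta", "first_order")) {
  se_mode <- match.arg(se_mode)
  x <- tibble::as_tibble(pairs)
  if ("action" %in% names(x)) {
    x <- x[x$action %in% c("unchanged", "sign_flipped"), , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("no usable harmonized pairs", call. = FALSE)
  if (any(x$beta_exposure == 0)) {
    stop("beta_exposure is zero for rsid ",
         paste(x$rsid[x$beta_exposure == 0], collapse = ", "),
         ": Wald ratio undefined", call. = FALSE)
  }
  bx <- x$beta_exposure; sx <- x$se_exposure
  by <- x$beta_outcome; sy <- x$se_outcome
  se2 <- sy^2 / bx^2
  if (se_mode == "delta") se2 <- se2 + sx^2 * by^2 / bx^4
  tibble::tibble(
    rsid = if ("rsid" %in% names(x)) x$rsid else paste0("snp_", seq_len(nrow(x))),
    beta_causal = by / bx,
    se_causal = sqrt(se2),
    weak = abs(bx) / sx < 2
  )
}

#' Inverse-variance weighted combination of Wald ratios
#'
#' Combines the per-instrument causal estimates by fixed-effects
#' inverse-variance weighting (see [fixed_effects_meta()]); the across-
#' instrument Cochran's Q is reported as an instrument-heterogeneity
#' diagnostic.
#'
#' @param estimates Tibble from [wald_ratio()] (columns `beta_causal`,
#'   `se_causal`).
#' @param level Confidence level.
#' @return An `mr_meta` object; `beta` is the combined causal log odds ratio
#'   per unit of exposure.
#' @export
ivw_combine <- function(estimates, level = 0.95) {
  stopifnot(all(c("beta_causal", "se_causal") %in% names(estimates)))
  fixed_effects_meta(estimates$beta_causal, estimates$se_causal, level = level,
                     labels = estimates$rsid)
}

#' Egger regression for directional pleiotropy
#'
#' Weighted linear regression of the outcome effects on the exposure effects,
#' `beta_outcome = a + b * beta_exposure`, with weights `1/se_outcome^2`,
#' after orienting every instrument so `beta_exposure > 0` (sign-flipping
#' `beta_outcome` accordingly). The intercept `a` estimates the average
#' direct (pleiotropic) effect of an instrument on the outcome; under the
#' exclusion restriction it is zero and the slope `b` estimates the causal
#' effect. Standard errors come from the weighted least-squares fit
#' (multiplicative residual scale); p-values are two-sided normal.
#'
#' @param pairs As in [wald_ratio()]; at least 3 usable instruments.
#' @param constrain_intercept If `TRUE`, fit through the origin — the slope
#'   then reproduces the classic first-order IVW estimate exactly (exposed
#'   for verification, not routine use).
#' @return An object of class `mr_egger`: list with `intercept`,
#'   `se_intercept`, `p_intercept`, `slope`, `se_slope`, `p_slope`, `k`,
#'   `sigma` (residual scale).
#' @export
egger_regression <- function(pairs, constrain_intercept = FALSE) {
  x <- tibble::as_tibble(pairs)
  if ("action" %in% names(x)) {
    x <- x[x$action %in% c("unchanged", "sign_flipped"), , drop = FALSE]
  }
  if (nrow(x) < 3L) stop("Egger regression requires at least 3 instruments", call. = FALSE)
  s <- sign(x$beta_exposure)
  if (any(s == 0)) stop("beta_exposure is zero: cannot orient instrument", call. = FALSE)
  bx <- s * x$beta_exposure
  by <- s * x$beta_outcome
  w <- 1 / x$se_outcome^2

  fit <- if (constrain_intercept) {
    stats::lm(by ~ 0 + bx, weights = w)
  } else {
    stats::lm(by ~ bx, weights = w)
  }
  cf <- summary(fit)$coefficients
  slope <- cf["bx", "Estimate"]
  se_slope <- cf["bx", "Std. Error"]
  intercept <- if (constrain_intercept) 0 else cf["(Intercept)", "Estimate"]
  se_intercept <- if (constrain_intercept) NA_real_ else cf["(Intercept)", "Std. Error"]
  structure(
    list(
      intercept = intercept,
      se_intercept = se_intercept,
      p_intercept = if (constrain_intercept) NA_real_ else 2 * stats::pnorm(-abs(intercept / se_intercept)),
      slope = slope,
      se_slope = se_slope,
      p_slope = 2 * stats::pnorm(-abs(slope / se_slope)),
      k = nrow(x),
      sigma = summary(fit)$sigma
    ),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("Egger regression on %d instruments\n", x$k))
  cat(sprintf("  intercept (pleiotropy) = %.4g (se %.3g), p = %.3g\n",
              x$intercept, x$se_intercept, x$p_intercept))
  cat(sprintf("  slope (causal effect)  = %.4g (se %.3g), p = %.3g\n",
              x$slope, x$se_slope, x$p_slope))
  invisible(x)
}

#' Funnel-plot coordinates for per-SNP causal estimates
#'
#' Pass-through transform: each Wald estimate is paired with its precision
#' `1/se` for external plotting of funnel asymmetry (asymmetry suggests
#' directional pleiotropy). No graphics are produced.
#'
#' @param estimates Tibble from [wald_ratio()].
#' @return Tibble with columns `rsid`, `beta_causal`, `precision`.
#' @export
funnel_data <- function(estimates) {
  stopifnot(all(c("beta_causal", "se_causal") %in% names(estimates)))
  if (nrow(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  tibble::tibble(
    rsid = if ("rsid" %in% names(estimates)) estimates$rsid else paste0("snp_", seq_len(nrow(estimates))),
    beta_causal = estimates$beta_causal,
    precision = 1 / estimates$se_causal
  )
}

#' Two-sample Mendelian randomization from summary statistics
#'
#' Convenience wrapper running the full two-sample pipeline: harmonization,
#' per-SNP Wald ratios, IVW combination, Egger regression, and funnel-plot
#' coordinates.
#'
#' @inheritParams harmonize
#' @inheritParams wald_ratio
#' @param per Exposure increment for odds-ratio reporting (e.g. 5 for an OR
#'   per 5 kg/m^2 of BMI).
#' @param level Confidence level.
#' @return An object of class `mr_twosample`: list with elements `pairs`,
#'   `wald`, `ivw` (`mr_meta`), `egger` (`mr_egger`), `funnel`, `per`,
#'   `or_per` (tibble with the IVW OR and CI scaled to `per` exposure units).
#' @examples
#' sim <- simulate_sumstats(sim_config(seed = 1), n_exposure = 5000,
#'                          n_outcome_cases = 1000, n_outcome_controls = 1500)
#' res <- mr_twosample(sim$panel_est, sim$outcome)
#' res$or_per
#' @export
mr_twosample <- function(panel, outcome, palindromic = c("infer", "drop", "keep"),
                         se_mode = c("delta", "first_order"), per = 5, level = 0.95) {
  pairs <- harmonize(panel, outcome, palindromic = match.arg(palindromic))
  wald <- wald_ratio(pairs, se_mode = match.arg(se_mode))
  ivw <- ivw_combine(wald, level = level)
  egger <- if (nrow(wald) >= 3L) egger_regression(pairs) else NULL
  orp <- log_to_or_ci(per * ivw$beta, per * ivw$se, level)
  structure(
    list(pairs = pairs, wald = wald, ivw = ivw, egger = egger,
         funnel = funnel_data(wald), per = per, or_per = orp),
    class = "mr_twosample"
  )
}

#' @export
print.mr_twosample <- function(x, ...) {
  cat(sprintf("Two-sample MR on %d instruments\n", nrow(x$wald)))
  cat(sprintf("  IVW: beta = %.4f (se %.4f), p = %.3g\n", x$ivw$beta, x$ivw$se, x$ivw$p))
  cat(sprintf("  OR per %g exposure units = %.3f [%.3f, %.3f]\n",
              x$per, x$or_per$or, x$or_per$ci_low, x$or_per$ci_high))
  if (!is.null(x$egger)) {
    cat(sprintf("  Egger intercept p = %.3g\n", x$egger$p_intercept))
  }
  invisible(x)
}
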