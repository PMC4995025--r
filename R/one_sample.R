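# One-sample analysis: logistic regression of case status on the calibrated
# genetic score, with covariate adjustment, strata, and per-study combination.

build_model_frame <- function(data, score, covariates) {
  stopifnot(nrow(data) == length(score))
  if (!"case_status" %in% names(data)) stop("data must contain 'case_status'", call. = FALSE)
  cs <- data$case_status
  if (!all(cs %in% c(0, 1), na.rm = TRUE)) stop("case_status must be 0/1", call. = FALSE)
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("covariate column(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- data.frame(.case = cs, .score = score)
  for (v in covariates) {
    col <- data[[v]]
    if (is.character(col) || is.logical(col)) col <- factor(col)
    df[[v]] <- col
  }
  df
}

check_glm_fit <- function(fit) {
  if (!fit$converged) {
    cf <- stats::coef(fit)
    worst <- names(which.max(abs(cf[-1L])))
    stop("logistic fit did not converge (largest coefficient: ", worst,
         "); check for separation", call. = FALSE)
  }
  mu <- stats::fitted(fit)
  if (all(mu > 0.9999) || all(mu < 1e-4)) {
    stop("fitted probabilities degenerate: possible separation", call. = FALSE)
  }
  invisible(fit)
}

assoc_row <- function(label, n, beta, se, per, level) {
  z <- ci_z(level)
  tibble::tibble(
    label = label, n = n, beta = beta, se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    or_per = exp(per * beta),
    ci_low = exp(per * (beta - z * se)),
    ci_high = exp(per * (beta + z * se))
  )
}

#' Logistic association of a calibrated score with case status
#'
#' Maximum-likelihood logistic regression of case status on the calibrated
#' genetic score, adjusted for covariates. For `form = "continuous"` the
#' score enters linearly and the odds ratio is reported per `per` exposure
#' units (per 5 kg/m^2 with the defaults, i.e. `exp(5 * beta)`). For
#' `form = "categorical"` the score is binned by [categorize_score()] and one
#' odds ratio is reported per non-reference bin (`per` is ignored; `or_per`
#' is the plain per-group OR). Confidence intervals and p-values are Wald,
#' from the observed information.
#'
#' @param data Tibble with a 0/1 `case_status` column and any covariate
#'   columns (character/logical covariates are treated as factors).
#' @param score Numeric vector, one calibrated score per row of `data`.
#' @param covariates Character vector of adjustment-covariate column names
#'   (e.g. `c("age", paste0("pc", 1:8), "study")`).
#' @param form `"continuous"` or `"categorical"`.
#' @param per Exposure increment for odds-ratio reporting (continuous form).
#' @param cutpoints Cutpoints for the categorical form.
#' @param level Confidence level.
#' @param label Label attached to the result row(s).
#' @return A tibble with columns `label`, `n`, `beta`, `se`, `p`, `or_per`,
#'   `ci_low`, `ci_high`; one row (continuous) or one per non-reference group
#'   (categorical, with the reference level in `attr(, "reference")`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 2000, n_cases_target = 1000,
#'                                      n_snps = 20, seed = 7))
#' gs <- compute_gs(cohort$dosages, cohort$panel)
#' cal <- calibrate_score(gs, cohort$phenotypes$bmi_observed,
#'                        controls = cohort$phenotypes$case_status == 0)
#' fit_score_outcome(cohort$phenotypes, cal$calibrated, covariates = "age")
#' @export
fit_score_outcome <- function(data, score, covariates = character(),
                              form = c("continuous", "categorical"),
                              per = 5, cutpoints = c(25.5, 26.0, 26.5),
                              level = 0.95, label = "all") {
  form <- match.arg(form)
  df <- build_model_frame(data, score, covariates)
  if (length(unique(stats::na.omit(df$.case))) < 2L) {
    stop("case_status has a single class: cannot fit", call. = FALSE)
  }
  rhs <- paste(c("%s", covariates), collapse = " + ")

  if (form == "continuous") {
    fml <- stats::as.formula(paste(".case ~", sprintf(rhs, ".score")))
    fit <- stats::glm(fml, family = stats::binomial(), data = df)
    check_glm_fit(fit)
    cf <- summary(fit)$coefficients
    return(assoc_row(label, sum(!is.na(df$.case)), cf[".score", "Estimate"],
                     cf[".score", "Std. Error"], per, level))
  }

  df$.bin <- categorize_score(score, cutpoints)
  present <- levels(droplevels(df$.bin))
  if (length(present) < 2L) stop("fewer than 2 occupied score categories", call. = FALSE)
  df$.bin <- droplevels(df$.bin)
  fml <- stats::as.formula(paste(".case ~", sprintf(rhs, ".bin")))
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  check_glm_fit(fit)
  cf <- summary(fit)$coefficients
  groups <- present[-1L]
  rows <- lapply(groups, function(g) {
    nm <- paste0(".bin", g)
    assoc_row(g, sum(df$.bin == g, na.rm = TRUE),
              cf[nm, "Estimate"], cf[nm, "Std. Error"], per = 1, level = level)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "reference") <- present[1L]
  out
}

#' Stratified score-outcome associations with a heterogeneity test
#'
#' Fits [fit_score_outcome()] independently within each level of a stratum
#' variable (menopausal status, hormone-therapy use, receptor status, ...)
#' and tests between-stratum heterogeneity of the log odds ratios with
#' Cochran's Q (equivalent to a two-sample z-test for two strata). Strata
#' below `min_n` individuals are skipped with a warning, to avoid separation
#' noise in small cells.
#'
#' @inheritParams fit_score_outcome
#' @param stratum_var Name of the stratum column in `data`.
#' @param min_n Minimum stratum size, default 100.
#' @return A list with `estimates` (tibble of per-stratum rows) and
#'   `heterogeneity` (list `q`, `df`, `p`, or `NULL` when fewer than two
#'   strata were fitted).
#' @export
stratified_fit <- function(data, score, covariates = character(), stratum_var,
                           min_n = 100, per = 5, level = 0.95) {
  stopifnot(stratum_var %in% names(data))
  strata <- data[[stratum_var]]
  lev <- if (is.factor(strata)) levels(droplevels(strata)) else sort(unique(stats::na.omit(strata)))
  rows <- list()
  for (s in lev) {
    idx <- which(!is.na(strata) & strata == s)
    if (length(idx) < min_n) {
      warning(sprintf("stratum '%s' has %d < %d individuals; skipped", s, length(idx), min_n),
              call. = FALSE)
      next
    }
    rows[[s]] <- fit_score_outcome(data[idx, , drop = FALSE], score[idx],
                                   covariates = covariates, per = per,
                                   level = level, label = as.character(s))
  }
  if (!length(rows)) stop("no stratum met the minimum size", call. = FALSE)
  est <- dplyr::bind_rows(rows)
  het <- if (nrow(est) >= 2L) cochran_q(est$beta, est$se) else NULL
  list(estimates = est, heterogeneity = het)
}

#' Per-study estimates combined by fixed-effects meta-analysis
#'
#' Fits the score-outcome logistic model separately in each study, then
#' combines the per-study log odds ratios with [fixed_effects_meta()] — the
#' meta-analytic counterpart of a pooled fit with study-indicator adjustment.
#' Studies below `min_n` individuals, or with a single outcome class, are
#' skipped with a warning.
#'
#' @inheritParams stratified_fit
#' @param study_var Name of the study-site column in `data`.
#' @return A list with `studies` (tibble of per-study rows) and `summary`
#'   (`mr_meta`; includes the across-study Cochran's Q).
#' @export
per_study_meta <- function(data, score, covariates = character(), study_var = "study",
                           min_n = 100, per = 5, level = 0.95) {
  stopifnot(study_var %in% names(data))
  studies <- data[[study_var]]
  lev <- if (is.factor(studies)) levels(droplevels(studies)) else sort(unique(stats::na.omit(studies)))
  rows <- list()
  for (s in lev) {
    idx <- which(!is.na(studies) & studies == s)
    if (length(idx) < min_n) {
      warning(sprintf("study '%s' has %d < %d individuals; skipped", s, length(idx), min_n),
              call. = FALSE)
      next
    }
    res <- tryCatch(
      fit_score_outcome(data[idx, , drop = FALSE], score[idx], covariates = covariates,
                        per = per, level = level, label = as.character(s)),
      error = function(e) {
        warning(sprintf("study '%s' skipped: %s", s, conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (!is.null(res)) rows[[s]] <- res
  }
  if (!length(rows)) stop("no study could be fitted", call. = FALSE)
  est <- dplyr::bind_rows(rows)
  summary <- fixed_effects_meta(est$beta, est$se, level = level, labels = est$label)
  list(studies = est, summary = summary)
}
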