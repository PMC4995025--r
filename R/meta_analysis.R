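#' Fixed-effects inverse-variance meta-analysis
#'
#' Combines `k` independent estimates with weights `w_j = 1/se_j^2`:
#' `beta = sum(w_j * beta_j) / sum(w_j)`, `se = 1/sqrt(sum(w_j))`, with a
#' normal-theory confidence interval and two-sided p-value. For `k >= 2`,
#' Cochran's Q heterogeneity statistic is attached.
#'
#' @param betas Numeric vector of estimates (log odds ratios here, but any
#'   scale works).
#' @param ses Positive standard errors, same length.
#' @param level Confidence level, default `0.95`.
#' @param labels Optional names for the inputs (carried for printing).
#' @return An object of class `mr_meta`: a list with `beta`, `se`, `ci_low`,
#'   `ci_high`, `p`, `q`, `q_df`, `q_p` (`NA` when `k < 2`), `k`, `level`.
#' @examples
#' fixed_effects_meta(c(-0.07, -0.05), c(0.011, 0.021))
#' @export
fixed_effects_meta <- function(betas, ses, level = 0.95, labels = NULL) {
  if (length(betas) != length(ses)) stop("betas and ses must have equal length", call. = FALSE)
  if (length(betas) < 1L) stop("need at least one estimate", call. = FALSE)
  if (any(!is.finite(betas)) || any(!is.finite(ses)) || any(ses <= 0)) {
    stop("estimates must be finite with positive standard errors", call. = FALSE)
  }
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- ci_z(level)
  het <- if (length(betas) >= 2L) cochran_q(betas, ses) else list(q = NA_real_, df = NA_integer_, p = NA_real_)
  structure(
    list(
      beta = beta, se = se,
      ci_low = beta - z * se, ci_high = beta + z * se,
      p = 2 * stats::pnorm(-abs(beta / se)),
      q = het$q, q_df = het$df, q_p = het$p,
      k = length(betas), level = level, labels = labels
    ),
    class = "mr_meta"
  )
}

#' @export
print.mr_meta <- function(x, ...) {
  ci <- log_to_or_ci(x$beta, x$se, x$level)
  cat(sprintf("Fixed-effects meta-analysis of %d estimate(s)\n", x$k))
  cat(sprintf("  beta = %.4f (se %.4f), %d%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, round(100 * x$level), x$ci_low, x$ci_high, x$p))
  cat(sprintf("  OR = %.3f [%.3f, %.3f]\n", ci$or, ci$ci_low, ci$ci_high))
  if (!is.na(x$q)) {
    cat(sprintf("  Cochran's Q = %.3f on %d df, p = %.3g\n", x$q, x$q_df, x$q_p))
  }
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (beta_j - beta_bar)^2)` with inverse-variance weights and
#' `beta_bar` the fixed-effects combined estimate; under homogeneity Q is
#' chi-square with `k - 1` degrees of freedom.
#'
#' @inheritParams fixed_effects_meta
#' @return A list with `q`, `df`, `p`.
#' @examples
#' cochran_q(c(0, 0.5), c(0.1, 0.1))  # Q = 12.5 on 1 df
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) != length(ses)) stop("betas and ses must have equal length", call. = FALSE)
  if (length(betas) < 2L) stop("heterogeneity requires at least 2 estimates", call. = FALSE)
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  bbar <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - bbar)^2)
  df <- length(betas) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Combine per-SNP estimates from two consortia
#'
#' Row-wise fixed-effects combination of rsid-matched estimates from two
#' sources (already harmonized to the same effect allele). SNPs present in
#' only one source are passed through unchanged and flagged `unreplicated`.
#'
#' @param per_snp_a,per_snp_b Tibbles with columns `rsid`, `beta`, `se`.
#' @param level Confidence level for the combined intervals.
#' @return A tibble with one row per rsid: `rsid`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `q_p` (`NA` for single-source rows) and
#'   `unreplicated`.
#' @export
combine_consortia <- function(per_snp_a, per_snp_b, level = 0.95) {
  for (x in list(per_snp_a, per_snp_b)) {
    stopifnot(all(c("rsid", "beta", "se") %in% names(x)))
    if (anyDuplicated(x$rsid)) {
      stop("duplicate rsid within a source: ",
           paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "), call. = FALSE)
    }
  }
  ids <- union(per_snp_a$rsid, per_snp_b$rsid)
  ia <- match(ids, per_snp_a$rsid)
  ib <- match(ids, per_snp_b$rsid)
  rows <- lapply(seq_along(ids), function(i) {
    bs <- c(per_snp_a$beta[ia[i]], per_snp_b$beta[ib[i]])
    ss <- c(per_snp_a$se[ia[i]], per_snp_b$se[ib[i]])
    keep <- !is.na(bs)
    m <- fixed_effects_meta(bs[keep], ss[keep], level = level)
    tibble::tibble(
      rsid = ids[i], beta = m$beta, se = m$se,
      p = m$p, q_p = m$q_p, unreplicated = sum(keep) < 2L
    )
  })
  out <- dplyr::bind_rows(rows)
  ci <- log_to_or_ci(out$beta, out$se, level)
  out$or <- ci$or
  out$ci_low <- ci$ci_low
  out$ci_high <- ci$ci_high
  out[, c("rsid", "beta", "se", "or", "ci_low", "ci_high", "p", "q_p", "unreplicated")]
}

#' Bonferroni significance threshold
#'
#' @param m Number of comparisons.
#' @param alpha Family-wise error rate, default `0.05`.
#' @return `alpha / m` (e.g. `5.95e-4` for 84 comparisons).
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  stopifnot(is_scalar_number(m), m >= 1, is_scalar_number(alpha), alpha > 0, alpha < 1)
  alpha / m
}
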