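#' Column dialect for summary-statistics files
#'
#' Summary-statistics TSVs come in many column-name dialects. A dialect is a
#' named character vector mapping the canonical names used by this package
#' (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `p`, `n`) to the column names found in the file. Required columns are
#' `rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`;
#' `chrom`, `pos` and `n` are optional.
#'
#' @param ... name-value overrides, e.g. `beta = "Effect"`, `rsid = "SNP"`.
#' @return Named character vector mapping canonical to file column names.
#' @examples
#' sumstats_dialect(rsid = "SNP", eaf = "Freq1")
#' @export
sumstats_dialect <- function(...) {
  d <- c(
    rsid = "rsid", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", p = "p", n = "n"
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad)) stop("unknown dialect field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    d[names(ov)] <- ov
  }
  d
}

required_fields <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "p")

# Read a summary-statistics TSV into canonical character columns, then coerce
# numerics with row-level error reporting (naming rsid and line number).
read_sumstats_raw <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  miss <- setdiff(dialect[required_fields], names(raw))
  if (length(miss)) {
    stop("missing required column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  present <- dialect[dialect %in% names(raw)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)

  numeric_fields <- intersect(c("pos", "eaf", "beta", "se", "p", "n"), names(out))
  for (f in numeric_fields) {
    v <- suppressWarnings(as.numeric(out[[f]]))
    bad <- which(is.na(v) & !is.na(out[[f]]) & out[[f]] != "NA")
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("malformed numeric in column '%s' for rsid %s (file line %d): '%s'",
                   f, out$rsid[i], i + 1L, out[[f]][i]), call. = FALSE)
    }
    out[[f]] <- v
  }
  for (f in intersect(c("effect_allele", "other_allele"), names(out))) {
    out[[f]] <- toupper(out[[f]])
  }
  tibble::as_tibble(out)
}

validate_snp_records <- function(x, what = "panel") {
  if (nrow(x) == 0L) return(invisible(x))
  if (anyDuplicated(x$rsid)) {
    stop(sprintf("duplicate rsid(s) in %s: %s", what,
                 paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", ")), call. = FALSE)
  }
  same <- x$effect_allele == x$other_allele
  if (any(same)) stop("effect and other allele identical for rsid ",
                      paste(x$rsid[same], collapse = ", "), call. = FALSE)
  if (any(x$eaf < 0 | x$eaf > 1, na.rm = TRUE)) {
    stop("eaf outside [0,1] in ", what, call. = FALSE)
  }
  invisible(x)
}

#' Read an instrument panel of exposure summary statistics
#'
#' Reads a tab-separated panel of instrument SNPs with per-allele exposure
#' effects (for a BMI score, kg/m^2 per effect allele), validates invariants
#' (unique rsids, distinct alleles, `eaf` in `[0,1]`, positive standard
#' errors), and returns the records in file order.
#'
#' @param path Path to a TSV file.
#' @param dialect Column-name mapping from [sumstats_dialect()].
#' @return A tibble with columns `rsid`, `chrom`, `pos` (when present),
#'   `effect_allele`, `other_allele`, `eaf`, `beta_exposure`, `se_exposure`,
#'   `p_exposure`.
#' @seealso [read_outcome()], [write_panel()], [harmonize()]
#' @examples
#' path <- system.file("extdata", "synthetic_panel_84.tsv", package = "scoremr")
#' panel <- read_panel(path)
#' nrow(panel)
#' @export
read_panel <- function(path, dialect = sumstats_dialect()) {
  x <- read_sumstats_raw(path, dialect)
  validate_snp_records(x, "panel")
  if (nrow(x) && any(x$se <= 0, na.rm = TRUE)) stop("se_exposure must be > 0", call. = FALSE)
  nm <- names(x)
  nm[nm == "beta"] <- "beta_exposure"
  nm[nm == "se"] <- "se_exposure"
  nm[nm == "p"] <- "p_exposure"
  names(x) <- nm
  x
}

#' Read outcome summary statistics (log odds-ratio scale)
#'
#' As [read_panel()] but for per-SNP outcome associations: `beta` is the
#' natural-log odds ratio for the outcome per effect allele.
#'
#' @inheritParams read_panel
#' @return A tibble with columns `rsid`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta_outcome`, `se_outcome`, `p_outcome` (plus `chrom`/`pos`/`n`
#'   when present).
#' @export
read_outcome <- function(path, dialect = sumstats_dialect()) {
  x <- read_sumstats_raw(path, dialect)
  validate_snp_records(x, "outcome")
  if (nrow(x)) {
    if (any(x$se <= 0, na.rm = TRUE)) stop("se_outcome must be > 0", call. = FALSE)
    if (any(!is.finite(exp(x$beta)))) stop("beta_outcome implies non-finite OR", call. = FALSE)
  }
  nm <- names(x)
  nm[nm == "beta"] <- "beta_outcome"
  nm[nm == "se"] <- "se_outcome"
  nm[nm == "p"] <- "p_outcome"
  names(x) <- nm
  x
}

# Format numbers so that re-reading reproduces the double exactly, preferring
# the shortest representation that round-trips.
format_roundtrip <- function(x) {
  out <- sprintf("%.15g", x)
  full <- sprintf("%.17g", x)
  exact <- !is.na(x) & (as.numeric(out) == x)
  out[!exact] <- full[!exact]
  out[is.na(x)] <- NA_character_
  out
}

write_sumstats <- function(x, path, role) {
  x <- tibble::as_tibble(x)
  nm <- names(x)
  nm[nm == paste0("beta_", role)] <- "beta"
  nm[nm == paste0("se_", role)] <- "se"
  nm[nm == paste0("p_", role)] <- "p"
  names(x) <- nm
  keep <- intersect(c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                      "eaf", "beta", "se", "p", "n"), nm)
  x <- x[, keep, drop = FALSE]
  for (f in intersect(c("eaf", "beta", "se", "p"), keep)) {
    x[[f]] <- format_roundtrip(x[[f]])
  }
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write an instrument panel / outcome associations to TSV
#'
#' Numeric fields are written with round-trip precision: reading the file back
#' reproduces the doubles bit-for-bit.
#'
#' @param panel,outcome Tibbles as returned by [read_panel()] / [read_outcome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) write_sumstats(panel, path, "exposure")

#' @rdname write_panel
#' @export
write_outcome <- function(outcome, path) write_sumstats(outcome, path, "outcome")

#' Convert printed odds ratios with confidence intervals to log scale
#'
#' Published per-SNP results are usually printed as `OR (95% CI)`. To
#' re-meta-analyze such rows the point estimate and standard error are
#' recovered as `beta = log(OR)` and
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)` with `z` the two-sided normal
#' quantile of the confidence level.
#'
#' @param or_value,ci_low,ci_high Positive odds-ratio point estimate and
#'   confidence bounds (vectorized).
#' @param level Confidence level of the interval, default `0.95`.
#' @return A tibble with columns `beta` and `se`.
#' @examples
#' or_ci_to_log(0.93, 0.91, 0.95)
#' @export
or_ci_to_log <- function(or_value, ci_low, ci_high, level = 0.95) {
  if (any(c(or_value, ci_low, ci_high) <= 0, na.rm = TRUE)) {
    stop("odds ratios and confidence bounds must be positive", call. = FALSE)
  }
  if (any(ci_low > or_value | or_value > ci_high, na.rm = TRUE)) {
    stop("require ci_low <= or_value <= ci_high", call. = FALSE)
  }
  z <- ci_z(level)
  tibble::tibble(
    beta = log(or_value),
    se = (log(ci_high) - log(ci_low)) / (2 * z)
  )
}

#' @rdname or_ci_to_log
#' @param beta,se Log odds ratio and its standard error (vectorized).
#' @return For `log_to_or_ci()`: a tibble with columns `or`, `ci_low`, `ci_high`.
#' @export
log_to_or_ci <- function(beta, se, level = 0.95) {
  if (any(se < 0, na.rm = TRUE)) stop("se must be non-negative", call. = FALSE)
  z <- ci_z(level)
  tibble::tibble(
    or = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se)
  )
}

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize outcome associations to the instrument panel's effect alleles
#'
#' Aligns per-SNP outcome summary statistics to the allele orientation of the
#' exposure panel. When the outcome's effect allele is the panel's other
#' allele, the outcome effect is sign-flipped and its frequency reflected
#' (`eaf -> 1 - eaf`). Strand is assumed forward; complement matching is
#' attempted before a pair is declared incompatible. Palindromic SNPs (A/T or
#' G/C) carry no allele information across strands and are resolved by
#' frequency or dropped, per `palindromic`:
#' \describe{
#'   \item{`"infer"`}{(default) drop when either frequency lies inside
#'     `eaf_window` (ambiguous near 0.5), otherwise align so both frequencies
#'     fall on the same side of 0.5;}
#'   \item{`"drop"`}{drop all palindromic SNPs;}
#'   \item{`"keep"`}{always resolve by frequency, however close to 0.5.}
#' }
#'
#' @param panel Tibble from [read_panel()].
#' @param outcome Tibble from [read_outcome()].
#' @param palindromic Policy for palindromic SNPs; see Details.
#' @param eaf_window Ambiguity window around 0.5 used by `"infer"`.
#' @return A tibble of class `mr_harmonized`, one row per rsid present in both
#'   inputs, with the panel's allele orientation, exposure and outcome
#'   effects, and an `action` column in `unchanged`, `sign_flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`. rsids present on only one side
#'   are reported in `attr(, "unmatched")`, not silently discarded.
#' @examples
#' panel <- tibble::tibble(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'                         eaf = 0.3, beta_exposure = 0.1, se_exposure = 0.01)
#' outcome <- tibble::tibble(rsid = "rs1", effect_allele = "G", other_allele = "A",
#'                           eaf = 0.7, beta_outcome = 0.05, se_outcome = 0.02)
#' harmonize(panel, outcome)$action
#' @export
harmonize <- function(panel, outcome, palindromic = c("infer", "drop", "keep"),
                      eaf_window = c(0.42, 0.58)) {
  palindromic <- match.arg(palindromic)
  stopifnot(length(eaf_window) == 2L, eaf_window[1] <= eaf_window[2])

  shared <- intersect(panel$rsid, outcome$rsid)
  unmatched <- list(
    panel_only = setdiff(panel$rsid, outcome$rsid),
    outcome_only = setdiff(outcome$rsid, panel$rsid)
  )

  p <- panel[match(shared, panel$rsid), , drop = FALSE]
  o <- outcome[match(shared, outcome$rsid), , drop = FALSE]

  n <- length(shared)
  action <- character(n)
  beta_o <- o$beta_outcome
  eaf_o <- if ("eaf" %in% names(o)) o$eaf else rep(NA_real_, n)

  in_window <- function(f) !is.na(f) & f >= eaf_window[1] & f <= eaf_window[2]

  for (i in seq_len(n)) {
    pe <- p$effect_allele[i]; po <- p$other_allele[i]
    oe <- o$effect_allele[i]; oo <- o$other_allele[i]
    if (is_palindromic(pe, po)) {
      allele_ok <- (oe == pe && oo == po) || (oe == po && oo == pe)
      if (!allele_ok) {
        action[i] <- "dropped_mismatch"
        next
      }
      if (palindromic == "drop" ||
          (palindromic == "infer" && (in_window(eaf_o[i]) || in_window(p$eaf[i])))) {
        action[i] <- "dropped_palindromic"
        next
      }
      if (is.na(eaf_o[i]) || is.na(p$eaf[i])) {
        action[i] <- "dropped_palindromic"
        next
      }
      # Frequencies on the same side of 0.5 indicate the same allele.
      if ((p$eaf[i] < 0.5) == (eaf_o[i] < 0.5)) {
        action[i] <- "unchanged"
      } else {
        action[i] <- "sign_flipped"
        beta_o[i] <- -beta_o[i]
        eaf_o[i] <- 1 - eaf_o[i]
      }
    } else {
      ce <- unname(ALLELE_COMPLEMENT[oe]); co <- unname(ALLELE_COMPLEMENT[oo])
      if ((oe == pe && oo == po) ||
          (!is.na(ce) && !is.na(co) && ce == pe && co == po)) {
        action[i] <- "unchanged"
      } else if ((oe == po && oo == pe) ||
                 (!is.na(ce) && !is.na(co) && ce == po && co == pe)) {
        action[i] <- "sign_flipped"
        beta_o[i] <- -beta_o[i]
        eaf_o[i] <- 1 - eaf_o[i]
      } else {
        action[i] <- "dropped_mismatch"
      }
    }
  }

  n_mismatch <- sum(action == "dropped_mismatch")
  if (n_mismatch) {
    warning(sprintf("%d SNP(s) dropped for incompatible alleles: %s", n_mismatch,
                    paste(shared[action == "dropped_mismatch"], collapse = ", ")),
            call. = FALSE)
  }

  out <- tibble::tibble(
    rsid = shared,
    effect_allele = p$effect_allele,
    other_allele = p$other_allele,
    eaf_exposure = p$eaf,
    beta_exposure = p$beta_exposure,
    se_exposure = p$se_exposure,
    eaf_outcome = eaf_o,
    beta_outcome = beta_o,
    se_outcome = o$se_outcome,
    action = action
  )
  if ("p_exposure" %in% names(p)) out$p_exposure <- p$p_exposure
  if ("p_outcome" %in% names(o)) out$p_outcome <- o$p_outcome
  attr(out, "unmatched") <- unmatched
  class(out) <- c("mr_harmonized", class(out))
  out
}

#' Report of rsids that could not be paired during harmonization
#'
#' @param x An `mr_harmonized` object from [harmonize()].
#' @return A list with elements `panel_only` and `outcome_only`.
#' @export
unmatched_rsids <- function(x) {
  stopifnot(inherits(x, "mr_harmonized"))
  attr(x, "unmatched")
}
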