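# Shared fixture builders. Everything is generated in code; the only files
# used are the small TSVs bundled under inst/extdata.

extdata <- function(name) system.file("extdata", name, package = "scoremr")

toy_panel <- function(rsid = c("rs1", "rs2", "rs3"),
                      effect = c("A", "C", "G"),
                      other = c("G", "T", "A"),
                      eaf = c(0.3, 0.5, 0.8),
                      beta = c(0.10, 0.20, 0.30),
                      se = 0.01) {
  n <- length(rsid)
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  tibble::tibble(
    rsid = rsid,
    effect_allele = rep_len(effect, n), other_allele = rep_len(other, n),
    eaf = rep_len(eaf, n), beta_exposure = beta, se_exposure = se,
    p_exposure = 2 * stats::pnorm(-abs(beta) / se)
  )
}

toy_outcome <- function(rsid = c("rs1", "rs2", "rs3"),
                        effect = c("A", "C", "G"),
                        other = c("G", "T", "A"),
                        eaf = c(0.3, 0.5, 0.8),
                        beta = c(-0.02, -0.01, 0.01),
                        se = 0.02) {
  n <- length(rsid)
  beta <- rep_len(beta, n); se <- rep_len(se, n)
  tibble::tibble(
    rsid = rsid,
    effect_allele = rep_len(effect, n), other_allele = rep_len(other, n),
    eaf = rep_len(eaf, n), beta_outcome = beta, se_outcome = se,
    p_outcome = 2 * stats::pnorm(-abs(beta) / se)
  )
}

# Harmonized-pair tibble straight from numbers (no allele bookkeeping).
toy_pairs <- function(bx, sx, by, sy) {
  tibble::tibble(
    rsid = paste0("rs", seq_along(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy
  )
}

# Cohort phenotype table for logistic fits built from explicit cell counts of
# a 2x2 table: exposed cases a, exposed controls b, unexposed cases c,
# unexposed controls d.
table2x2_data <- function(a, b, c, d) {
  tibble::tibble(
    case_status = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    exposed = c(rep(1, a + b), rep(0, c + d))
  )
}

is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}
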