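test_that("panel reading validates and round-trips through the writer", {
  panel <- read_panel(extdata("synthetic_panel_84.tsv"))
  expect_equal(nrow(panel), 84L)
  expect_true(all(panel$se_exposure > 0))
  expect_false(anyDuplicated(panel$rsid) > 0)

  # write -> read reproduces every numeric field bit-for-bit
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, tmp)
  back <- read_panel(tmp)
  for (col in c("eaf", "beta_exposure", "se_exposure", "p_exposure")) {
    expect_identical(back[[col]], panel[[col]])
  }

  # header-only file yields an empty collection
  hdr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se", "p"),
                   collapse = "\t"), hdr)
  expect_equal(nrow(read_panel(hdr)), 0L)

  # missing required column is a configuration error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\teaf", "rs1\t0.2"), bad)
  expect_error(read_panel(bad), "missing required column")

  # malformed numerics are reported with rsid and line number
  mal <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsid\teffect_allele\tother_allele\teaf\tbeta\tse\tp",
    "rs1\tA\tG\t0.2\t0.1\t0.01\t0.5",
    "rs2\tA\tG\t0.3\toops\t0.01\t0.5"
  ), mal)
  expect_error(read_panel(mal), "rs2.*line 3|line 3.*rs2")
})

test_that("column dialects remap foreign headers", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "SNP\tA1\tA2\tFreq1\tEffect\tStdErr\tPvalue",
    "rs9\tt\tc\t0.25\t-0.05\t0.02\t0.01"
  ), tmp)
  d <- sumstats_dialect(rsid = "SNP", effect_allele = "A1", other_allele = "A2",
                        eaf = "Freq1", beta = "Effect", se = "StdErr", p = "Pvalue")
  x <- read_outcome(tmp, dialect = d)
  expect_equal(x$rsid, "rs9")
  expect_equal(x$effect_allele, "T")  # upper-cased
  expect_equal(x$beta_outcome, -0.05)
  expect_error(sumstats_dialect(nonsense = "x"), "unknown dialect field")
})

test_that("OR/CI conversion matches the closed form and inverts", {
  expect_equal(or_ci_to_log(1, 1, 1), tibble::tibble(beta = 0, se = 0))

  # printed consortium cell: 0.93 (0.91-0.95) -> (-0.0726, 0.0110) at 3 s.f.
  conv <- or_ci_to_log(0.93, 0.91, 0.95)
  expect_equal(conv$beta, -0.0726, tolerance = 1e-3)
  expect_equal(conv$se, 0.0110, tolerance = 1e-2)
  expect_equal(conv$se, (log(0.95) - log(0.91)) / (2 * qnorm(0.975)), tolerance = 1e-12)

  # re-expanding 0.95 (0.91-0.99) recovers the printed bounds at 2 d.p.
  cc <- or_ci_to_log(0.95, 0.91, 0.99)
  back <- log_to_or_ci(cc$beta, cc$se)
  expect_equal(round(back$ci_low, 2), 0.91)
  expect_equal(round(back$ci_high, 2), 0.99)

  # exact inverse on log-symmetric triples, any level
  set.seed(42)
  for (i in 1:25) {
    beta <- rnorm(1); se <- rexp(1); lv <- runif(1, 0.5, 0.999)
    tri <- log_to_or_ci(beta, se, level = lv)
    rec <- or_ci_to_log(tri$or, tri$ci_low, tri$ci_high, level = lv)
    expect_equal(rec$beta, beta, tolerance = 1e-6)
    expect_equal(rec$se, se, tolerance = 1e-6)
  }

  expect_error(or_ci_to_log(-1, 0.5, 2), "positive")
  expect_error(or_ci_to_log(0.9, 0.95, 1.0), "ci_low <= or_value")
})

test_that("harmonization follows the allele truth table", {
  panel <- toy_panel(
    rsid = c("id", "swap", "comp", "comp_swap", "mismatch"),
    effect = "A", other = "G", eaf = 0.3, beta = 0.1
  )
  outcome <- toy_outcome(
    rsid = c("id", "swap", "comp", "comp_swap", "mismatch"),
    effect = c("A", "G", "T", "C", "A"),
    other = c("G", "A", "C", "T", "C"),
    eaf = rep(0.3, 5),
    beta = rep(0.05, 5),
    se = rep(0.02, 5)
  )
  expect_warning(h <- harmonize(panel, outcome), "incompatible alleles")
  expect_equal(h$action,
               c("unchanged", "sign_flipped", "unchanged", "sign_flipped", "dropped_mismatch"))
  expect_equal(h$beta_outcome[h$rsid == "id"], 0.05)
  expect_equal(h$beta_outcome[h$rsid == "swap"], -0.05)
  expect_equal(h$eaf_outcome[h$rsid == "swap"], 0.7)
  expect_equal(h$beta_outcome[h$rsid == "comp_swap"], -0.05)
})

test_that("palindromic SNPs are resolved per policy", {
  panel <- toy_panel(rsid = c("amb", "inf"), effect = c("A", "C"), other = c("T", "G"),
                     eaf = c(0.50, 0.20), beta = c(0.1, 0.1))
  outcome <- toy_outcome(rsid = c("amb", "inf"), effect = c("A", "C"), other = c("T", "G"),
                         eaf = c(0.50, 0.85), beta = c(0.05, 0.05))
  # ambiguous frequency near 0.5 -> dropped under default and "drop"
  for (pol in c("infer", "drop")) {
    h <- harmonize(panel, outcome, palindromic = pol)
    expect_equal(h$action[h$rsid == "amb"], "dropped_palindromic")
  }
  # informative frequency on opposite sides of 0.5 -> flipped under "infer"
  h <- harmonize(panel, outcome, palindromic = "infer")
  expect_equal(h$action[h$rsid == "inf"], "sign_flipped")
  expect_equal(h$eaf_outcome[h$rsid == "inf"], 0.15)
  # "drop" removes all palindromic SNPs regardless
  h2 <- harmonize(panel, outcome, palindromic = "drop")
  expect_equal(h2$action[h2$rsid == "inf"], "dropped_palindromic")
  # "keep" resolves even the ambiguous one by frequency
  h3 <- harmonize(panel, outcome, palindromic = "keep")
  expect_equal(h3$action[h3$rsid == "amb"], "unchanged")
})

test_that("harmonization is idempotent and double-swap is the identity", {
  panel <- toy_panel()
  outcome <- toy_outcome(effect = c("G", "T", "A"), other = c("A", "C", "G"),
                         eaf = c(0.7, 0.5, 0.15))
  h1 <- harmonize(panel, outcome)
  expect_true(all(h1$action == "sign_flipped"))
  # feed the harmonized outcome back: everything should now be unchanged
  out2 <- tibble::tibble(
    rsid = h1$rsid, effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_outcome, beta_outcome = h1$beta_outcome, se_outcome = h1$se_outcome
  )
  h2 <- harmonize(panel, out2)
  expect_true(all(h2$action == "unchanged"))
  # double swap composed to identity on (beta, eaf)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$eaf_outcome, h1$eaf_outcome)
})

test_that("unmatched rsids are reported, not dropped silently", {
  panel <- toy_panel()
  outcome <- toy_outcome(rsid = c("rs1", "rs2", "rsX"))
  h <- harmonize(panel, outcome)
  rep <- unmatched_rsids(h)
  expect_equal(rep$panel_only, "rs3")
  expect_equal(rep$outcome_only, "rsX")
  expect_equal(nrow(h), 2L)
})
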