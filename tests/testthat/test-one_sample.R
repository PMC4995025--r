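covars_full <- c("age", paste0("pc", 1:8), "study")

test_that("logistic odds ratio on a 2x2 table equals the closed form ad/bc", {
  dat <- table2x2_data(a = 20, b = 80, c = 40, d = 60)
  res <- fit_score_outcome(dat, dat$exposed, per = 1)
  expect_equal(res$or_per, (20 * 60) / (80 * 40), tolerance = 1e-8)
  expect_equal(res$n, 200)
})

test_that("odds-ratio scaling is a deterministic transform of beta", {
  set.seed(31)
  dat <- tibble::tibble(case_status = rbinom(500, 1, 0.5))
  res <- fit_score_outcome(dat, rnorm(500), per = 5)
  expect_equal(res$or_per, exp(5 * res$beta), tolerance = 1e-12)
  expect_equal(res$ci_low, exp(5 * (res$beta - qnorm(0.975) * res$se)), tolerance = 1e-12)
})

test_that("a score unrelated to the outcome yields null estimates", {
  hits <- 0L
  for (i in 1:20) {
    set.seed(400 + i)
    dat <- tibble::tibble(case_status = rbinom(5000, 1, 0.5))
    res <- fit_score_outcome(dat, rnorm(5000, 26, 0.5))
    if (abs(res$beta) < 3 * res$se) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("degenerate outcomes are rejected with a clear message", {
  dat <- tibble::tibble(case_status = rep(1, 50))
  expect_error(fit_score_outcome(dat, rnorm(50)), "single class")
  dat2 <- tibble::tibble(case_status = rep(0:1, 25), x = 1)
  expect_error(fit_score_outcome(dat2, rnorm(50), covariates = "missing_col"),
               "not found")
})

test_that("categorical form returns one OR per non-reference bin", {
  set.seed(8)
  n <- 4000
  score <- rnorm(n, 26, 0.8)
  dat <- tibble::tibble(case_status = rbinom(n, 1, plogis(-0.3 * (score - 26))))
  res <- fit_score_outcome(dat, score, form = "categorical")
  expect_equal(attr(res, "reference"), "<25.5")
  expect_equal(res$label, c("[25.5,26)", "[26,26.5)", ">=26.5"))
  # inverse risk gradient simulated -> top bin clearly protective vs reference
  expect_true(all(res$or_per < 1))
  expect_lt(res$or_per[3], res$or_per[1])
})

test_that("stratified fits report per-stratum estimates and heterogeneity", {
  cfg <- sim_config(n_individuals = 6000, n_cases_target = 3000, n_snps = 20, seed = 55)
  co <- simulate_cohort(cfg)
  gs <- compute_gs(co$dosages, co$panel)
  cal <- calibrate_score(gs, co$phenotypes$bmi_observed,
                         controls = co$phenotypes$case_status == 0)
  sf <- stratified_fit(co$phenotypes, cal$calibrated, covariates = "age",
                       stratum_var = "menopausal")
  expect_equal(nrow(sf$estimates), 2L)
  expect_true(sf$heterogeneity$p > 0 && sf$heterogeneity$p <= 1)
  expect_equal(sf$heterogeneity$df, 1L)

  # a single stratum has no heterogeneity to report
  one <- co$phenotypes[co$phenotypes$menopausal == "postmenopausal", ]
  sf1 <- stratified_fit(one, cal$calibrated[co$phenotypes$menopausal == "postmenopausal"],
                        stratum_var = "menopausal")
  expect_null(sf1$heterogeneity)

  # undersized strata are skipped with a warning (mix cases and controls:
  # the cohort lists cases first)
  idx <- c(1:75, 3001:3075)
  small <- co$phenotypes[idx, ]
  small$grp <- rep(c("big", "tiny"), times = c(140, 10))
  expect_warning(
    sf2 <- stratified_fit(small, cal$calibrated[idx], stratum_var = "grp", min_n = 50),
    "skipped"
  )
  expect_equal(sf2$estimates$label, "big")
})

test_that("stratum heterogeneity p-values are uniform under a shared model", {
  ps <- numeric(100)
  for (i in 1:100) {
    cfg <- sim_config(n_individuals = 2000, n_cases_target = 1000, n_snps = 15,
                      seed = 9000 + i)
    co <- simulate_cohort(cfg)
    gs <- compute_gs(co$dosages, co$panel)
    cal <- calibrate_score(gs, co$phenotypes$bmi_observed,
                           controls = co$phenotypes$case_status == 0)
    sf <- stratified_fit(co$phenotypes, cal$calibrated, stratum_var = "menopausal")
    ps[i] <- sf$heterogeneity$p
  }
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("per-study meta summarizes study fits by fixed effects", {
  cfg <- sim_config(n_individuals = 10000, n_cases_target = 5000, n_snps = 30,
                    n_studies = 5, seed = 77)
  co <- simulate_cohort(cfg)
  gs <- compute_gs(co$dosages, co$panel)
  cal <- calibrate_score(gs, co$phenotypes$bmi_observed,
                         controls = co$phenotypes$case_status == 0)
  psm <- per_study_meta(co$phenotypes, cal$calibrated, covariates = "age")
  expect_equal(nrow(psm$studies), 5L)
  # summary is exactly the fixed-effects meta of the study rows
  m <- fixed_effects_meta(psm$studies$beta, psm$studies$se)
  expect_equal(psm$summary$beta, m$beta, tolerance = 1e-12)
  expect_equal(psm$summary$se, m$se, tolerance = 1e-12)
  # same truth in every study: heterogeneity should not scream
  expect_gt(psm$summary$q_p, 0.001)

  # pooled fit with study adjustment agrees with the meta within 15%
  pooled <- fit_score_outcome(co$phenotypes, cal$calibrated,
                              covariates = c("age", "study"))
  expect_equal(sign(pooled$beta), sign(psm$summary$beta))
  expect_lt(abs(pooled$beta - psm$summary$beta), 0.15 * abs(psm$summary$beta))

  # a single usable study collapses the meta onto that study
  sub <- co$phenotypes$study == "study_1"
  suppressWarnings(
    one <- per_study_meta(co$phenotypes[sub, ], cal$calibrated[sub], covariates = "age")
  )
  expect_equal(one$summary$beta, one$studies$beta[1], tolerance = 1e-12)
})
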