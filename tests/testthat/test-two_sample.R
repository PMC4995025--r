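test_that("Wald ratio handles the degenerate limits exactly", {
  # null numerator: estimate 0, se = se_outcome / |beta_exposure|
  p0 <- toy_pairs(bx = -0.5, sx = 0.1, by = 0, sy = 0.03)
  w0 <- wald_ratio(p0)
  expect_equal(w0$beta_causal, 0)
  expect_equal(w0$se_causal, 0.03 / 0.5)

  # deterministic instrument: delta SE collapses to first-order
  p1 <- toy_pairs(bx = 0.2, sx = 0, by = -0.04, sy = 0.01)
  expect_equal(wald_ratio(p1)$se_causal, 0.01 / 0.2)
  expect_equal(wald_ratio(p1, "first_order")$se_causal, 0.01 / 0.2)

  # zero exposure effect is undefined
  expect_error(wald_ratio(toy_pairs(0, 0.1, 0.1, 0.1)), "undefined")

  # weak-instrument flag
  pw <- toy_pairs(bx = c(0.01, 0.5), sx = c(0.01, 0.01), by = 0, sy = 0.02)
  expect_equal(wald_ratio(pw)$weak, c(TRUE, FALSE))
})

test_that("delta-method SE matches Monte-Carlo ratio dispersion", {
  bx <- 0.05; sx <- 0.004; by <- -0.02; sy <- 0.01
  w <- wald_ratio(toy_pairs(bx, sx, by, sy))
  set.seed(99)
  mc <- rnorm(1e6, by, sy) / rnorm(1e6, bx, sx)
  expect_equal(w$se_causal, sd(mc), tolerance = 0.05)
  expect_equal(w$beta_causal, by / bx)
})

test_that("IVW combination obeys its algebraic laws", {
  # single estimate passes through
  w1 <- tibble::tibble(rsid = "a", beta_causal = 0.3, se_causal = 0.1)
  m1 <- ivw_combine(w1)
  expect_equal(m1$beta, 0.3)
  expect_equal(m1$se, 0.1)

  # k identical copies shrink the SE by sqrt(k)
  wk <- tibble::tibble(rsid = letters[1:4], beta_causal = 0.3, se_causal = 0.1)
  mk <- ivw_combine(wk)
  expect_equal(mk$beta, 0.3, tolerance = 1e-12)
  expect_equal(mk$se, 0.1 / 2, tolerance = 1e-12)

  # equals WLS of outcome on exposure effects through the origin
  pairs <- toy_pairs(bx = c(0.05, -0.08, 0.12, 0.06, -0.1),
                     sx = c(0.01, 0.012, 0.009, 0.011, 0.01),
                     by = c(-0.01, 0.02, -0.03, 0.005, 0.015),
                     sy = c(0.02, 0.025, 0.018, 0.022, 0.02))
  w <- wald_ratio(pairs)
  ivw <- ivw_combine(w)
  wls <- lm(pairs$beta_outcome ~ 0 + pairs$beta_exposure,
            weights = 1 / (pairs$beta_exposure^2 * w$se_causal^2))
  expect_equal(ivw$beta, unname(coef(wls)), tolerance = 1e-10)

  # with exact instruments it reduces to the classic summary IVW formula
  w0 <- wald_ratio(toy_pairs(pairs$beta_exposure, 0, pairs$beta_outcome, pairs$se_outcome))
  classic <- sum(pairs$beta_exposure * pairs$beta_outcome / pairs$se_outcome^2) /
    sum(pairs$beta_exposure^2 / pairs$se_outcome^2)
  expect_equal(ivw_combine(w0)$beta, classic, tolerance = 1e-10)
})

test_that("exposure rescaling rescales the estimate and preserves z-scores", {
  pairs <- toy_pairs(bx = c(0.05, -0.08, 0.12), sx = c(0.01, 0.012, 0.009),
                     by = c(-0.01, 0.02, -0.03), sy = c(0.02, 0.025, 0.018))
  c_ <- 2.5
  scaled <- pairs
  scaled$beta_exposure <- c_ * scaled$beta_exposure
  scaled$se_exposure <- c_ * scaled$se_exposure
  m <- ivw_combine(wald_ratio(pairs))
  ms <- ivw_combine(wald_ratio(scaled))
  expect_equal(ms$beta, m$beta / c_, tolerance = 1e-12)
  expect_equal(ms$beta / ms$se, m$beta / m$se, tolerance = 1e-12)
})

test_that("Egger regression guards its degrees of freedom and nests IVW", {
  expect_error(egger_regression(toy_pairs(c(0.1, 0.2), 0.01, c(0, 0), 0.02)),
               "at least 3")
  pairs <- toy_pairs(bx = c(0.05, -0.08, 0.12, 0.06, -0.1),
                     sx = c(0.01, 0.012, 0.009, 0.011, 0.01),
                     by = c(-0.01, 0.02, -0.03, 0.005, 0.015),
                     sy = c(0.02, 0.025, 0.018, 0.022, 0.02))
  # intercept constrained to zero reproduces first-order IVW exactly
  e0 <- egger_regression(pairs, constrain_intercept = TRUE)
  ivw_fo <- ivw_combine(wald_ratio(pairs, "first_order"))
  expect_equal(e0$slope, ivw_fo$beta, tolerance = 1e-10)
  expect_equal(e0$intercept, 0)

  e <- egger_regression(pairs)
  expect_true(is.finite(e$intercept) && is.finite(e$se_intercept))
  expect_true(e$p_intercept > 0 && e$p_intercept <= 1)
  expect_equal(e$k, 5L)
})

test_that("funnel coordinates conserve rows and invert the SE", {
  w <- tibble::tibble(rsid = c("a", "b"), beta_causal = c(0.1, -0.2),
                      se_causal = c(0.05, 0.4))
  f <- funnel_data(w)
  expect_equal(nrow(f), 2L)
  expect_equal(f$precision, c(20, 2.5))
  expect_true(all(f$precision > 0))
  set.seed(1)
  wr <- tibble::tibble(beta_causal = rnorm(40), se_causal = rexp(40) + 0.01)
  expect_equal(nrow(funnel_data(wr)), 40L)
  expect_error(funnel_data(wr[0, ]), "no estimates")
})

test_that("two-sample pipeline recovers the generative causal odds ratio", {
  theta <- log(0.65) / 5
  covered <- 0L
  n_seeds <- 20
  for (i in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 6100 + i)
    ss <- simulate_sumstats(cfg, n_exposure = 60000,
                            n_outcome_cases = 5000, n_outcome_controls = 7500)
    res <- mr_twosample(ss$panel_est, ss$outcome)
    if (res$ivw$ci_low <= theta && theta <= res$ivw$ci_high) covered <- covered + 1L
  }
  expect_gte(covered, round(0.8 * n_seeds))
})

test_that("doubling the outcome study roughly halves the IVW variance", {
  ratios <- numeric(8)
  for (i in 1:8) {
    cfg <- sim_config(seed = 6500 + i)
    s1 <- simulate_sumstats(cfg, n_exposure = 40000,
                            n_outcome_cases = 2500, n_outcome_controls = 3750)
    s2 <- simulate_sumstats(cfg, n_exposure = 40000,
                            n_outcome_cases = 5000, n_outcome_controls = 7500)
    v1 <- ivw_combine(wald_ratio(harmonize(s1$panel_est, s1$outcome)))$se^2
    v2 <- ivw_combine(wald_ratio(harmonize(s2$panel_est, s2$outcome)))$se^2
    ratios[i] <- v1 / v2
  }
  expect_equal(mean(ratios), 2, tolerance = 0.15)
})
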