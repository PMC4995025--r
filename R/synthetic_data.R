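# Seeded generator for case-control cohorts and two-sample summary statistics
# with the statistical structure the MR analysis assumes: independent
# biallelic SNPs in Hardy-Weinberg equilibrium, a polygenic score explaining a
# configurable fraction of BMI variance, a logistic disease model on BMI, an
# unmeasured confounder affecting both BMI and disease, and optional
# directional pleiotropy.

#' Simulation configuration
#'
#' Collects and validates the parameters of the synthetic-data generator. The
#' defaults emulate the design of a large breast-cancer case-control
#' consortium at desk scale: 84 independent instruments whose weighted score
#' explains 1.23% of BMI variance, a true causal odds ratio of 0.65 per
#' 5 kg/m^2 of BMI, multi-site sampling, and case oversampling from a
#' population with 10% risk.
#'
#' @param n_individuals Cohort size after case-control ascertainment.
#' @param n_cases_target Number of cases to oversample into the cohort.
#' @param n_snps,eaf_range,r2_target Instrument panel: number of SNPs,
#'   effect-allele frequency range, and fraction of exposure variance the
#'   true score explains (see [simulate_panel()]).
#' @param bmi_mean,bmi_sd Marginal mean and SD of BMI (kg/m^2).
#' @param theta True causal log odds ratio per kg/m^2 of BMI
#'   (default `log(0.65)/5`).
#' @param prevalence Population disease risk before ascertainment.
#' @param confounder_bmi Effect of the standard-normal unmeasured confounder
#'   on BMI (kg/m^2 per SD).
#' @param confounder_logit Effect of the confounder on the disease logit.
#'   Nonzero defaults make the naive BMI-outcome regression biased while the
#'   genetic instruments remain valid.
#' @param pleiotropy_mean,pleiotropy_sd Direct per-allele SNP effects on the
#'   disease logit, drawn `N(pleiotropy_mean, pleiotropy_sd)`; zero by
#'   default (exclusion restriction holds).
#' @param n_studies Number of study sites.
#' @param prop_postmenopausal,prop_ht_ever,prop_er_pos,prop_pr_pos Stratum
#'   proportions: postmenopausal fraction, hormone-therapy-ever among
#'   postmenopausal, ER-positive and PR-positive among cases.
#' @param mask_case_bmi Mask observed BMI in cases (`NA`), mirroring designs
#'   where BMI is measured after diagnosis and therefore unusable.
#' @param dosage_mode `"hard"` (integer genotypes 0/1/2, default) or
#'   `"fractional"` (imputation-style dosages, hard calls plus truncated
#'   noise).
#' @param panel Optional pre-built instrument panel (tibble as from
#'   [simulate_panel()] or [read_panel()]); `NULL` to simulate one.
#' @param seed Root seed; every operation derives its own substream from it,
#'   so e.g. adding SNPs does not perturb the phenotype draws.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000, n_cases_target = 10000,
                       n_snps = 84, eaf_range = c(0.1, 0.9), r2_target = 0.0123,
                       bmi_mean = 26.5, bmi_sd = 4.5,
                       theta = log(0.65) / 5, prevalence = 0.10,
                       confounder_bmi = 1.0, confounder_logit = 0.2,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       n_studies = 5,
                       prop_postmenopausal = 0.7, prop_ht_ever = 0.5,
                       prop_er_pos = 0.8, prop_pr_pos = 0.7,
                       mask_case_bmi = TRUE,
                       dosage_mode = c("hard", "fractional"),
                       panel = NULL, seed = NULL) {
  cfg <- list(
    n_individuals = n_individuals, n_cases_target = n_cases_target,
    n_snps = n_snps, eaf_range = eaf_range, r2_target = r2_target,
    bmi_mean = bmi_mean, bmi_sd = bmi_sd, theta = theta,
    prevalence = prevalence,
    confounder_bmi = confounder_bmi, confounder_logit = confounder_logit,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    n_studies = n_studies,
    prop_postmenopausal = prop_postmenopausal, prop_ht_ever = prop_ht_ever,
    prop_er_pos = prop_er_pos, prop_pr_pos = prop_pr_pos,
    mask_case_bmi = mask_case_bmi,
    dosage_mode = match.arg(dosage_mode),
    panel = panel, seed = seed
  )
  stopifnot(
    cfg$n_individuals >= 2, cfg$n_cases_target >= 1,
    cfg$n_cases_target < cfg$n_individuals,
    cfg$n_snps >= 1,
    length(cfg$eaf_range) == 2L, all(cfg$eaf_range > 0), all(cfg$eaf_range < 1),
    cfg$r2_target >= 0, cfg$r2_target < 1,
    cfg$bmi_sd > 0,
    cfg$prevalence > 0, cfg$prevalence < 1,
    cfg$n_studies >= 1,
    all(c(cfg$prop_postmenopausal, cfg$prop_ht_ever, cfg$prop_er_pos, cfg$prop_pr_pos) >= 0),
    all(c(cfg$prop_postmenopausal, cfg$prop_ht_ever, cfg$prop_er_pos, cfg$prop_pr_pos) <= 1)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an instrument panel
#'
#' Draws `n_snps` independent biallelic SNPs with effect-allele frequencies
#' uniform over `eaf_range` and per-allele exposure effects rescaled so that
#' the population variance of the weighted score,
#' `sum(beta_i^2 * 2 * p_i * (1 - p_i))`, equals `r2_target * bmi_sd^2`
#' exactly. Reported standard errors and p-values are those an external
#' exposure GWAS of `n_gwas` individuals would attach to the true effects.
#' Allele pairs are non-complementary by default, emulating a curated,
#' strand-resolved panel.
#'
#' @inheritParams sim_config
#' @param bmi_sd Exposure SD used to translate `r2_target` into a score
#'   variance.
#' @param n_gwas Nominal sample size of the external exposure GWAS, used only
#'   to attach realistic standard errors.
#' @param allow_palindromic Permit A/T and C/G allele pairs.
#' @return A panel tibble as from [read_panel()], with the generative betas
#'   in `beta_exposure`.
#' @export
simulate_panel <- function(n_snps = 84, eaf_range = c(0.1, 0.9), r2_target = 0.0123,
                           bmi_sd = 4.5, n_gwas = 339224,
                           allow_palindromic = FALSE, seed = NULL) {
  stopifnot(n_snps >= 1, r2_target >= 0)
  if (r2_target >= 1) stop("r2_target must be < 1: the score cannot explain all exposure variance", call. = FALSE)
  with_seed(seed, {
    eaf <- stats::runif(n_snps, eaf_range[1], eaf_range[2])
    se <- bmi_sd / sqrt(n_gwas * 2 * eaf * (1 - eaf))
    # Instrument panels are selected at genome-wide significance in the
    # exposure GWAS, so true effect magnitudes are bounded away from zero:
    # draw |beta| at or above the discovery threshold z * se, right-skewed,
    # then rescale exactly to the target score variance.
    z_gws <- stats::qnorm(1 - 2.5e-8)
    b <- sample(c(-1, 1), n_snps, replace = TRUE) *
      se * (z_gws + 1.5 * abs(stats::rnorm(n_snps)))
    if (r2_target == 0) {
      b <- rep(0, n_snps)
    } else {
      target_var <- r2_target * bmi_sd^2
      b <- b * sqrt(target_var / sum(b^2 * 2 * eaf * (1 - eaf)))
    }
    pairs <- cbind(
      c("A", "A", "G", "T", "C", "T", "G", "C"),
      c("G", "C", "A", "G", "A", "C", "T", "T")
    )
    if (allow_palindromic) pairs <- rbind(pairs, c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pick <- sample.int(nrow(pairs), n_snps, replace = TRUE)
    tibble::tibble(
      rsid = sprintf("snp_%04d", seq_len(n_snps)),
      chrom = as.character(sample.int(22, n_snps, replace = TRUE)),
      pos = sample.int(1e8, n_snps, replace = TRUE),
      effect_allele = pairs[pick, 1L],
      other_allele = pairs[pick, 2L],
      eaf = eaf,
      beta_exposure = b,
      se_exposure = se,
      p_exposure = pmax(2 * stats::pnorm(-abs(b) / se), .Machine$double.xmin)
    )
  })
}

# Genotype matrix under HWE: n x m, column j ~ Binomial(2, eaf_j).
draw_genotypes <- function(n, eaf) {
  m <- length(eaf)
  matrix(stats::rbinom(n * m, 2L, rep(eaf, each = n)), nrow = n, ncol = m)
}

# Solve the logistic intercept so the expected case fraction over the
# simulated population equals `prevalence`.
solve_intercept <- function(lin, prevalence) {
  f <- function(a) mean(stats::plogis(a + lin)) - prevalence
  out <- tryCatch(stats::uniroot(f, c(-40, 40), tol = 1e-10), error = function(e) NULL)
  if (is.null(out)) {
    stop("case fraction ", prevalence, " unreachable within the intercept search bounds",
         call. = FALSE)
  }
  out$root
}

# Simulate the latent population: genotypes, confounder, BMI, disease.
simulate_population <- function(cfg, panel, n_pop, seed_tag) {
  beta <- panel$beta_exposure
  eaf <- panel$eaf
  g <- with_seed(derive_seed(cfg$seed %||% 0, paste0(seed_tag, "_genotypes")),
                 draw_genotypes(n_pop, eaf))
  score_c <- as.numeric(g %*% beta) - sum(2 * eaf * beta)
  var_score <- sum(beta^2 * 2 * eaf * (1 - eaf))
  var_eps <- cfg$bmi_sd^2 - var_score - cfg$confounder_bmi^2
  if (var_eps <= 0) {
    stop("bmi_sd too small for the requested score and confounder variance", call. = FALSE)
  }
  ph <- with_seed(derive_seed(cfg$seed %||% 0, paste0(seed_tag, "_phenotype")), {
    u <- stats::rnorm(n_pop)
    bmi <- cfg$bmi_mean + score_c + cfg$confounder_bmi * u +
      stats::rnorm(n_pop, sd = sqrt(var_eps))
    # Directional pleiotropy: direct outcome effects oriented relative to the
    # exposure-raising allele (sign of beta), the frame Egger regression uses.
    alpha <- if (cfg$pleiotropy_mean != 0 || cfg$pleiotropy_sd != 0) {
      orient <- ifelse(beta < 0, -1, 1)
      orient * stats::rnorm(length(beta), cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    } else {
      rep(0, length(beta))
    }
    lin <- cfg$theta * bmi + cfg$confounder_logit * u +
      if (any(alpha != 0)) as.numeric(g %*% alpha) else 0
    a0 <- solve_intercept(lin, cfg$prevalence)
    case <- stats::rbinom(n_pop, 1L, stats::plogis(a0 + lin))
    list(u = u, bmi = bmi, case = case, alpha0 = a0, pleiotropy = alpha)
  })
  list(g = g, bmi = ph$bmi, case = ph$case, alpha0 = ph$alpha0, pleiotropy = ph$pleiotropy)
}

#' Simulate a case-control cohort with genotypes, BMI and covariates
#'
#' Simulates a latent population under the generative model (HWE genotypes,
#' `BMI = mean + score + confounder + noise`, disease risk
#' `expit(alpha0 + theta * BMI + confounder effect [+ pleiotropy])` with
#' `alpha0` solved numerically to hit the target prevalence), then
#' oversamples cases to `n_cases_target` — the ascertainment that produces
#' case-control data. Study site, principal components, age, menopausal
#' status, hormone-therapy use, and tumor receptor status are attached as
#' covariates/strata; cases' observed BMI is masked by default.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `mr_cohort` with elements `phenotypes` (tibble:
#'   `individual_id`, `case_status`, `bmi_observed`, `age`, `pc1`..`pc8`,
#'   `study`, `menopausal`, `ht_use`, `er_status`, `pr_status`), `dosages`
#'   (individuals x SNPs matrix, columns named by rsid), `panel`, and
#'   `params` (realized generative parameters, including `alpha0`).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_individuals = 500, n_cases_target = 250,
#'                                      n_snps = 10, seed = 1))
#' table(cohort$phenotypes$case_status)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  panel <- cfg$panel %||% simulate_panel(
    n_snps = cfg$n_snps, eaf_range = cfg$eaf_range, r2_target = cfg$r2_target,
    bmi_sd = cfg$bmi_sd, seed = derive_seed(cfg$seed %||% 0, "panel")
  )
  n_cases <- cfg$n_cases_target
  n_controls <- cfg$n_individuals - n_cases
  n_pop <- ceiling(1.4 * max(n_cases / cfg$prevalence, n_controls / (1 - cfg$prevalence)))
  pop <- simulate_population(cfg, panel, n_pop, "cohort")

  sel <- with_seed(derive_seed(cfg$seed %||% 0, "cohort_sampling"), {
    case_idx <- which(pop$case == 1L)
    ctrl_idx <- which(pop$case == 0L)
    if (length(case_idx) < n_cases || length(ctrl_idx) < n_controls) {
      stop(sprintf("population yielded %d cases / %d controls; need %d / %d — raise prevalence or lower n_cases_target",
                   length(case_idx), length(ctrl_idx), n_cases, n_controls), call. = FALSE)
    }
    c(sample(case_idx, n_cases), sample(ctrl_idx, n_controls))
  })

  n <- length(sel)
  cov <- with_seed(derive_seed(cfg$seed %||% 0, "cohort_covariates"), {
    post <- stats::rbinom(n, 1L, cfg$prop_postmenopausal) == 1L
    age <- ifelse(post, stats::rnorm(n, 62, 6), stats::rnorm(n, 45, 5))
    pcs <- matrix(stats::rnorm(n * 8L), n, 8L, dimnames = list(NULL, paste0("pc", 1:8)))
    study <- factor(paste0("study_", sample.int(cfg$n_studies, n, replace = TRUE)))
    ht <- ifelse(post, ifelse(stats::rbinom(n, 1L, cfg$prop_ht_ever) == 1L, "ever", "never"), NA)
    er <- ifelse(stats::rbinom(n, 1L, cfg$prop_er_pos) == 1L, "positive", "negative")
    pr <- ifelse(stats::rbinom(n, 1L, cfg$prop_pr_pos) == 1L, "positive", "negative")
    frac_noise <- stats::rnorm(n * nrow(panel), sd = 0.08)
    list(post = post, age = age, pcs = pcs, study = study, ht = ht, er = er,
         pr = pr, frac_noise = frac_noise)
  })

  case_status <- pop$case[sel]
  bmi_obs <- pop$bmi[sel]
  if (cfg$mask_case_bmi) bmi_obs[case_status == 1L] <- NA_real_

  dosages <- pop$g[sel, , drop = FALSE]
  if (cfg$dosage_mode == "fractional") {
    dosages <- pmin(pmax(dosages + matrix(cov$frac_noise, n), 0), 2)
  }
  storage.mode(dosages) <- "double"
  ids <- sprintf("id_%06d", seq_len(n))
  dimnames(dosages) <- list(ids, panel$rsid)

  phenotypes <- dplyr::bind_cols(
    tibble::tibble(
      individual_id = ids,
      case_status = case_status,
      bmi_observed = bmi_obs,
      age = cov$age
    ),
    tibble::as_tibble(cov$pcs),
    tibble::tibble(
      study = cov$study,
      menopausal = factor(ifelse(cov$post, "postmenopausal", "premenopausal")),
      ht_use = factor(cov$ht),
      er_status = factor(ifelse(case_status == 1L, cov$er, NA)),
      pr_status = factor(ifelse(case_status == 1L, cov$pr, NA))
    )
  )

  structure(
    list(phenotypes = phenotypes, dosages = dosages, panel = panel,
         params = list(alpha0 = pop$alpha0, theta = cfg$theta,
                       pleiotropy = pop$pleiotropy, config = cfg)),
    class = "mr_cohort"
  )
}

#' @export
print.mr_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d individuals (%d cases), %d SNPs\n",
              nrow(x$phenotypes), sum(x$phenotypes$case_status), ncol(x$dosages)))
  invisible(x)
}

# Fast per-SNP simple linear regression of y on each genotype column.
per_snp_ols <- function(g, y) {
  n <- length(y)
  yc <- y - mean(y)
  cm <- colMeans(g)
  sxx <- colSums(g^2) - n * cm^2
  sxy <- as.numeric(crossprod(g, yc))
  b <- sxy / sxx
  rss <- sum(yc^2) - b^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  list(beta = b, se = se, p = 2 * stats::pnorm(-abs(b / se)))
}

# Fast per-SNP logistic regression of case status on a hard-call genotype,
# via the aggregated genotype-by-status table (exact MLE, since the
# single-covariate model is saturated on at most 3 genotype classes).
per_snp_logistic <- function(g, case) {
  m <- ncol(g)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    idx <- g[, j] + 1L + 3L * case
    cnt <- tabulate(idx, nbins = 6L)
    ctrl <- cnt[1:3]; cas <- cnt[4:6]
    keep <- (ctrl + cas) > 0L
    fit <- stats::glm(cbind(cas[keep], ctrl[keep]) ~ c(0, 1, 2)[keep],
                      family = stats::binomial())
    cf <- summary(fit)$coefficients
    beta[j] <- cf[2L, "Estimate"]
    se[j] <- cf[2L, "Std. Error"]
  }
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se)))
}

#' Simulate matched two-sample GWAS summary statistics
#'
#' Draws an exposure study (continuous BMI, per-SNP ordinary least squares)
#' and an independent outcome study (case-control sampled from a population
#' under the logistic disease model, per-SNP logistic regression) with no
#' sample overlap — the two-sample MR design. Optional directional
#' pleiotropy adds direct per-allele SNP effects to the outcome model.
#'
#' @param config A [sim_config()] object (`theta`, `pleiotropy_*`, panel
#'   settings and `prevalence` are used).
#' @param n_exposure Exposure-study sample size.
#' @param n_outcome_cases,n_outcome_controls Outcome-study sample sizes.
#' @return A list of class `mr_sumstats` with `panel_est` (panel tibble whose
#'   `beta_exposure`/`se_exposure`/`p_exposure`/`eaf` are the exposure-study
#'   estimates), `outcome` (tibble of per-SNP outcome log odds ratios), and
#'   `truth` (the generative panel, `theta`, and realized pleiotropy).
#' @export
simulate_sumstats <- function(config, n_exposure = 20000,
                              n_outcome_cases = 8000, n_outcome_controls = 12000) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  panel <- cfg$panel %||% simulate_panel(
    n_snps = cfg$n_snps, eaf_range = cfg$eaf_range, r2_target = cfg$r2_target,
    bmi_sd = cfg$bmi_sd, seed = derive_seed(cfg$seed %||% 0, "panel")
  )
  beta <- panel$beta_exposure
  eaf <- panel$eaf
  var_score <- sum(beta^2 * 2 * eaf * (1 - eaf))
  var_eps <- cfg$bmi_sd^2 - var_score - cfg$confounder_bmi^2
  if (var_eps <= 0) stop("bmi_sd too small for the requested score and confounder variance", call. = FALSE)

  # Exposure study: continuous BMI, no ascertainment.
  expo <- with_seed(derive_seed(cfg$seed %||% 0, "exposure_study"), {
    g <- draw_genotypes(n_exposure, eaf)
    score_c <- as.numeric(g %*% beta) - sum(2 * eaf * beta)
    u <- stats::rnorm(n_exposure)
    bmi <- cfg$bmi_mean + score_c + cfg$confounder_bmi * u +
      stats::rnorm(n_exposure, sd = sqrt(var_eps))
    est <- per_snp_ols(g, bmi)
    list(est = est, eaf_hat = colMeans(g) / 2)
  })

  # Outcome study: independent population, case-control ascertainment.
  n_pop <- ceiling(1.4 * max(n_outcome_cases / cfg$prevalence,
                             n_outcome_controls / (1 - cfg$prevalence)))
  pop <- simulate_population(cfg, panel, n_pop, "outcome_study")
  out <- with_seed(derive_seed(cfg$seed %||% 0, "outcome_sampling"), {
    case_idx <- which(pop$case == 1L)
    ctrl_idx <- which(pop$case == 0L)
    if (length(case_idx) < n_outcome_cases || length(ctrl_idx) < n_outcome_controls) {
      stop("outcome population yielded too few cases or controls; raise prevalence", call. = FALSE)
    }
    sel <- c(sample(case_idx, n_outcome_cases), sample(ctrl_idx, n_outcome_controls))
    g <- pop$g[sel, , drop = FALSE]
    case <- pop$case[sel]
    est <- per_snp_logistic(g, case)
    list(est = est, eaf_hat = colMeans(g) / 2)
  })

  panel_est <- panel
  panel_est$eaf <- expo$eaf_hat
  panel_est$beta_exposure <- expo$est$beta
  panel_est$se_exposure <- expo$est$se
  panel_est$p_exposure <- expo$est$p

  outcome <- tibble::tibble(
    rsid = panel$rsid,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    eaf = out$eaf_hat,
    beta_outcome = out$est$beta,
    se_outcome = out$est$se,
    p_outcome = out$est$p
  )

  structure(
    list(panel_est = panel_est, outcome = outcome,
         truth = list(panel = panel, theta = cfg$theta, pleiotropy = pop$pleiotropy)),
    class = "mr_sumstats"
  )
}
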