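# Config-driven orchestration: simulate -> score -> onesample -> twosample ->
# meta, with a reproducibility manifest (config hash, seed, file digests).

PIPELINE_STAGES <- c("simulate", "score", "onesample", "twosample", "meta")

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list", call. = FALSE)
  known <- c("seed", PIPELINE_STAGES)
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!any(PIPELINE_STAGES %in% names(config))) {
    stop("config enables no stage; provide at least one of: ",
         paste(PIPELINE_STAGES, collapse = ", "), call. = FALSE)
  }
  config
}

# All file paths a config refers to, for existence checks and input digests.
config_input_paths <- function(config) {
  stage <- function(name, field) {
    s <- config[[name]]
    if (is.list(s)) s[[field]] else NULL
  }
  paths <- c(
    stage("score", "dosages"), stage("score", "phenotypes"), stage("score", "panel"),
    stage("twosample", "panel"), stage("twosample", "outcome"),
    unlist(stage("meta", "sources"))
  )
  unique(as.character(paths %||% character()))
}

write_stage_tsv <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_tsv(x, path, progress = FALSE)
  path
}

# Per-SNP estimates from a TSV that carries either (beta, se) columns or
# printed (or, ci_low, ci_high) columns.
read_meta_source <- function(path, level = 0.95) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"rsid" %in% names(x)) stop("meta source lacks 'rsid': ", path, call. = FALSE)
  if (all(c("beta", "se") %in% names(x))) {
    tibble::tibble(rsid = x$rsid, beta = x$beta, se = x$se)
  } else if (all(c("or", "ci_low", "ci_high") %in% names(x))) {
    conv <- or_ci_to_log(x$or, x$ci_low, x$ci_high, level = level)
    tibble::tibble(rsid = x$rsid, beta = conv$beta, se = conv$se)
  } else {
    stop("meta source needs (beta, se) or (or, ci_low, ci_high) columns: ", path,
         call. = FALSE)
  }
}

#' Run the analysis pipeline from a single configuration
#'
#' Executes the enabled stages in dependency order — `simulate` (synthetic
#' cohort + matched summary statistics), `score` (genetic-score construction
#' and calibration), `onesample` (logistic score-outcome analysis with
#' per-study meta and strata), `twosample` (Wald/IVW/Egger from summary
#' statistics), `meta` (cross-consortium per-SNP combination) — writing one
#' TSV per stage plus a JSON manifest with the config hash, seed, input and
#' output digests, and package version. Identical config + seed + inputs
#' reproduce identical output digests. On a stage failure the partial
#' manifest is written before the error propagates.
#'
#' Config keys (YAML file or list): optional `seed`; then any of
#' \describe{
#'   \item{simulate}{[sim_config()] arguments plus `n_exposure`,
#'     `n_outcome_cases`, `n_outcome_controls`.}
#'   \item{score}{`weighted`, `missing_policy`; when not simulating:
#'     `dosages`, `phenotypes`, `panel` file paths.}
#'   \item{onesample}{`covariates` (default age, pc1-pc8, study), `strata`
#'     (stratum column names), `per`, `min_n`.}
#'   \item{twosample}{`panel`/`outcome` paths (default: the simulated pair),
#'     `palindromic`, `se_mode`, `per`.}
#'   \item{meta}{`sources`: two per-SNP TSVs with `beta`/`se` or printed
#'     `or`/`ci_low`/`ci_high` columns.}
#' }
#'
#' @param config Path to a YAML config or an equivalent named list.
#' @param out_dir Output directory (created; refuses to overwrite a previous
#'   run unless `overwrite = TRUE`).
#' @param seed Root seed; overrides the config's `seed`.
#' @param overwrite Allow writing into a directory holding a previous run.
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, overwrite = FALSE) {
  config <- read_pipeline_config(config)
  seed <- seed %||% config$seed %||% 1L

  inputs <- config_input_paths(config)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("referenced input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("out_dir already holds a run (manifest.json present); use overwrite = TRUE",
         call. = FALSE)
  }

  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file), add = TRUE)
  yaml::write_yaml(config, cfg_file)

  manifest <- list(
    package = "scoremr",
    package_version = as.character(utils::packageVersion("scoremr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    input_digests = as.list(tools::md5sum(inputs)),
    stages = character(),
    output_digests = list()
  )
  outputs <- character()
  state <- new.env(parent = emptyenv())

  finish_stage <- function(name, paths) {
    manifest$stages <<- c(manifest$stages, name)
    outputs <<- c(outputs, paths)
  }
  run_stage <- function(name, fn) {
    if (is.null(config[[name]]) && !(name %in% names(config))) return(invisible())
    tryCatch(fn(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$output_digests <<- as.list(tools::md5sum(outputs))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    sc <- config$simulate
    if (isTRUE(sc)) sc <- list()
    sumargs <- sc[intersect(names(sc), c("n_exposure", "n_outcome_cases", "n_outcome_controls"))]
    sc <- sc[setdiff(names(sc), names(sumargs))]
    cfg <- do.call(sim_config, c(sc, list(seed = seed)))
    state$cohort <- simulate_cohort(cfg)
    state$sumstats <- do.call(simulate_sumstats, c(list(config = cfg), sumargs))
    p1 <- write_panel(state$cohort$panel, file.path(out_dir, "panel.tsv"))
    p2 <- write_stage_tsv(state$cohort$phenotypes, out_dir, "cohort_phenotypes.tsv")
    dos <- tibble::as_tibble(state$cohort$dosages)
    dos <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(state$cohort$dosages)), dos)
    p3 <- write_stage_tsv(dos, out_dir, "cohort_dosages.tsv")
    p4 <- write_panel(state$sumstats$panel_est, file.path(out_dir, "panel_estimated.tsv"))
    p5 <- write_outcome(state$sumstats$outcome, file.path(out_dir, "outcome.tsv"))
    finish_stage("simulate", c(p1, p2, p3, p4, p5))
  })

  run_stage("score", function() {
    sc <- config$score
    if (isTRUE(sc)) sc <- list()
    if (is.null(state$cohort)) {
      need <- c("dosages", "phenotypes", "panel")
      if (!all(need %in% names(sc))) {
        stop("score stage without simulate needs 'dosages', 'phenotypes', 'panel' paths")
      }
      panel <- read_panel(sc$panel)
      dos <- readr::read_tsv(sc$dosages, show_col_types = FALSE, progress = FALSE)
      dmat <- as.matrix(dos[, setdiff(names(dos), "individual_id"), drop = FALSE])
      rownames(dmat) <- dos$individual_id
      phen <- readr::read_tsv(sc$phenotypes, show_col_types = FALSE, progress = FALSE)
      state$cohort <- list(phenotypes = phen, dosages = dmat, panel = panel)
    }
    gs <- compute_gs(state$cohort$dosages, state$cohort$panel,
                     weighted = sc$weighted %||% TRUE,
                     missing_policy = sc$missing_policy %||% "impute_eaf")
    phen <- state$cohort$phenotypes
    cal <- calibrate_score(gs, phen$bmi_observed, controls = phen$case_status == 0)
    state$score <- cal$calibrated
    state$calibration <- cal
    p1 <- write_stage_tsv(
      tibble::tibble(individual_id = phen$individual_id, gs_raw = gs,
                     score_calibrated = cal$calibrated),
      out_dir, "scores.tsv"
    )
    p2 <- write_stage_tsv(
      tibble::tibble(beta0 = cal$beta0, beta1 = cal$beta1, n_fit = cal$n_fit,
                     r_squared = cal$r_squared),
      out_dir, "calibration.tsv"
    )
    finish_stage("score", c(p1, p2))
  })

  run_stage("onesample", function() {
    if (is.null(state$score)) stop("onesample stage requires the score stage")
    oc <- config$onesample
    if (isTRUE(oc)) oc <- list()
    covs <- unlist(oc$covariates) %||% c("age", paste0("pc", 1:8), "study")
    per <- oc$per %||% 5
    min_n <- oc$min_n %||% 100
    phen <- state$cohort$phenotypes
    rows <- fit_score_outcome(phen, state$score, covariates = covs, per = per,
                              label = "pooled")
    rows$analysis <- "pooled"
    psm <- per_study_meta(phen, state$score,
                          covariates = setdiff(covs, "study"),
                          study_var = "study", min_n = min_n, per = per)
    meta_row <- tibble::tibble(
      label = "fixed_effects_summary", n = sum(psm$studies$n),
      beta = psm$summary$beta, se = psm$summary$se, p = psm$summary$p,
      or_per = exp(per * psm$summary$beta),
      ci_low = exp(per * psm$summary$ci_low),
      ci_high = exp(per * psm$summary$ci_high),
      analysis = "meta"
    )
    psm$studies$analysis <- "per_study"
    out <- dplyr::bind_rows(rows, psm$studies, meta_row)
    for (sv in unlist(oc$strata) %||% character()) {
      sf <- stratified_fit(phen, state$score, covariates = setdiff(covs, sv),
                           stratum_var = sv, min_n = min_n, per = per)
      sf$estimates$analysis <- paste0("strata_", sv)
      out <- dplyr::bind_rows(out, sf$estimates)
    }
    finish_stage("onesample", write_stage_tsv(out, out_dir, "onesample.tsv"))
  })

  run_stage("twosample", function() {
    tc <- config$twosample
    if (isTRUE(tc)) tc <- list()
    panel <- if (!is.null(tc$panel)) read_panel(tc$panel) else state$sumstats$panel_est
    outcome <- if (!is.null(tc$outcome)) read_outcome(tc$outcome) else state$sumstats$outcome
    if (is.null(panel) || is.null(outcome)) {
      stop("twosample stage needs 'panel' and 'outcome' paths (or the simulate stage)")
    }
    res <- mr_twosample(panel, outcome,
                        palindromic = tc$palindromic %||% "infer",
                        se_mode = tc$se_mode %||% "delta",
                        per = tc$per %||% 5)
    per_snp <- tibble::tibble(
      row_type = "WALD", rsid = res$wald$rsid,
      beta = res$wald$beta_causal, se = res$wald$se_causal,
      p = 2 * stats::pnorm(-abs(res$wald$beta_causal / res$wald$se_causal))
    )
    summ <- tibble::tibble(
      row_type = c("IVW", "EGGER_SLOPE", "EGGER_INTERCEPT"),
      rsid = NA_character_,
      beta = c(res$ivw$beta, res$egger$slope, res$egger$intercept),
      se = c(res$ivw$se, res$egger$se_slope, res$egger$se_intercept),
      p = c(res$ivw$p, res$egger$p_slope, res$egger$p_intercept)
    )
    finish_stage("twosample",
                 write_stage_tsv(dplyr::bind_rows(per_snp, summ), out_dir, "twosample.tsv"))
  })

  run_stage("meta", function() {
    mc <- config$meta
    srcs <- unlist(mc$sources)
    if (length(srcs) != 2L) stop("meta stage needs exactly two 'sources'")
    a <- read_meta_source(srcs[1L])
    b <- read_meta_source(srcs[2L])
    finish_stage("meta",
                 write_stage_tsv(combine_consortia(a, b), out_dir, "meta_combined.tsv"))
  })

  manifest$output_digests <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
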