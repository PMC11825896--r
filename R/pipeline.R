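# Pipeline orchestration: generate or load a cohort, filter, impute,
# standardize, fit the latent model per analysis population, estimate
# effects with every requested estimator, and write tables, fit files and a
# run manifest.

#' Pipeline configuration
#'
#' @param input Either `list(type = "synthetic", n_visits =, generator =)`
#'   (a [generator_config()]; built from `n_visits` if omitted) or
#'   `list(type = "csv", path =, sample_end_date =)`.
#' @param populations Analysis populations: `"overall"` and/or presentation
#'   labels.
#' @param outcomes Outcome indicators to report (default all nine).
#' @param estimators Subset of `c("unadjusted", "latent", "ipw", "gcomp")`.
#' @param em Named overrides for [em_control()].
#' @param boot_B Bootstrap resamples for comparator standard errors.
#' @param subgroups Compute the subgroup table (30-day outcomes, overall
#'   population)?
#' @param out_dir Output directory.
#' @param seed Global seed; every stage's stream is derived from it.
#' @param alpha Significance level (confidence level is `1 - alpha`).
#' @param min_population Populations smaller than this are estimated but
#'   flagged imprecise in the manifest.
#' @return List of class `ed_pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "synthetic", n_visits = 5000),
                            populations = "overall",
                            outcomes = ed_outcome_cols,
                            estimators = c("unadjusted", "latent"),
                            em = list(), boot_B = 200, subgroups = TRUE,
                            out_dir = "ed_pipeline_out", seed = 1,
                            alpha = 0.05, min_population = 200) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!length(estimators)) stop("at least one estimator must be selected")
  if (!length(outcomes)) stop("at least one outcome must be selected")
  estimators <- match.arg(estimators,
                          c("unadjusted", "latent", "ipw", "gcomp"),
                          several.ok = TRUE)
  stopifnot(all(outcomes %in% ed_outcome_cols),
            all(populations %in% c("overall", ed_presentations)))
  structure(list(input = input, populations = populations,
                 outcomes = outcomes, estimators = estimators, em = em,
                 boot_B = boot_B, subgroups = subgroups, out_dir = out_dir,
                 seed = as.integer(seed), alpha = alpha,
                 min_population = min_population),
            class = "ed_pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; the keys mirror the arguments of
#'   [pipeline_config()].
#' @return An `ed_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Stages: acquire data (synthetic generation with missingness, or CSV) ->
#' cohort filters -> outcome indicators, imputation, standardization ->
#' per-population latent-model fits and effect estimates for every
#' requested estimator -> subgroup effects -> tables, fit files, filter
#' report and manifest under `config$out_dir`.
#'
#' Every random stage draws its seed deterministically from `config$seed`,
#' so a rerun with the same configuration reproduces the outputs exactly.
#'
#' @param config An [pipeline_config()] object.
#' @return The run manifest, invisibly; side effect: files in
#'   `config$out_dir` (`effects.csv`, `table_<outcome>.csv`,
#'   `subgroups.csv`, `filter_report.json`, `fit_<population>.json`,
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ed_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  level <- 1 - config$alpha
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  warn <- character(0)

  # --- data stage
  if (config$input$type == "synthetic") {
    gen <- config$input$generator
    if (is.null(gen))
      gen <- generator_config(n_visits = config$input$n_visits)
    cohort <- generate_cohort(gen, seed = config$seed)
    data <- inject_missingness(cohort$data, gen$missingness_rates,
                               seed = config$seed + 1L)
    truth <- cohort$truth
    sample_end <- gen$sample_period[2]
  } else {
    cohort <- read_cohort(config$input$path)
    data <- cohort$data
    truth <- cohort$truth
    sample_end <- as.Date(config$input$sample_end_date)
  }
  timings$data <- proc.time()[["elapsed"]] - t0

  # --- preprocessing stage
  t1 <- proc.time()[["elapsed"]]
  prep <- tryCatch(preprocess_cohort(data, sample_end),
                   error = function(e) stop("preprocessing stage: ",
                                            conditionMessage(e)))
  design <- prep$design
  timings$preprocess <- proc.time()[["elapsed"]] - t1

  # --- estimation stage
  t2 <- proc.time()[["elapsed"]]
  effects <- list()
  fits <- list()
  for (pop in config$populations) {
    idx <- if (pop == "overall") rep(TRUE, design$n) else
      design$presentation == pop
    dpop <- subset_design(design, idx)
    if (dpop$n < config$min_population)
      warn <- c(warn, paste0("population ", pop, " has ", dpop$n,
                             " visits; estimates flagged imprecise"))
    if (dpop$n < 2 || length(unique(dpop$admitted)) < 2) {
      warn <- c(warn, paste0("population ", pop, " skipped: no contrast"))
      next
    }
    fit <- NULL
    if ("latent" %in% config$estimators) {
      emc <- do.call(em_control,
                     modifyList(list(seed = config$seed + 100L),
                                config$em))
      fit <- tryCatch(fit_em(dpop, emc),
                      error = function(e) stop("fit stage (", pop, "): ",
                                               conditionMessage(e)))
      fits[[pop]] <- fit
    }
    for (oc in config$outcomes) {
      if ("unadjusted" %in% config$estimators)
        effects[[length(effects) + 1]] <-
          unadjusted_rd(dpop, oc, level, population = pop)
      if ("latent" %in% config$estimators)
        effects[[length(effects) + 1]] <-
          estimate_ate(fit, dpop, oc, level, population = pop)
      if ("ipw" %in% config$estimators)
        effects[[length(effects) + 1]] <-
          ipw_rd(dpop, oc, boot_B = config$boot_B,
                 seed = config$seed + 200L, level = level,
                 population = pop)
      if ("gcomp" %in% config$estimators)
        effects[[length(effects) + 1]] <-
          g_computation_rd(dpop, oc, boot_B = config$boot_B,
                           seed = config$seed + 300L, level = level,
                           population = pop)
    }
  }
  effects <- do.call(rbind, effects)
  timings$estimation <- proc.time()[["elapsed"]] - t2

  # --- subgroup stage (overall latent fit, 30-day outcomes)
  sub_tab <- NULL
  if (isTRUE(config$subgroups) && "latent" %in% config$estimators &&
      "overall" %in% names(fits)) {
    t3 <- proc.time()[["elapsed"]]
    rows <- list()
    oc30 <- intersect(config$outcomes,
                      paste0("y_", ed_outcome_families, "_30"))
    for (sg in names(default_subgroups(design))) {
      sel <- default_subgroups(design)[[sg]]
      for (oc in oc30)
        rows[[length(rows) + 1]] <- withCallingHandlers(
          estimate_subgroup_ate(fits$overall, design, oc, sel, label = sg,
                                level = level),
          warning = function(w) {
            warn <<- c(warn, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
    }
    sub_tab <- do.call(rbind, rows)
    timings$subgroups <- proc.time()[["elapsed"]] - t3
  }

  # --- reporting stage
  write.csv(effects, file.path(config$out_dir, "effects.csv"),
            row.names = FALSE)
  for (oc in config$outcomes) {
    tab <- render_effect_table(effects[effects$outcome == oc, ], "main")
    write.csv(tab, file.path(config$out_dir, paste0("table_", oc, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(sub_tab)) {
    write.csv(render_effect_table(sub_tab, "subgroup"),
              file.path(config$out_dir, "subgroups.csv"), row.names = FALSE)
    write.csv(sub_tab, file.path(config$out_dir, "subgroup_effects.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(n_input = prep$filter_report$n_input,
         n_retained = prep$filter_report$n_retained,
         exclusions = as.list(prep$filter_report$exclusions)),
    file.path(config$out_dir, "filter_report.json"), auto_unbox = TRUE)
  for (pop in names(fits))
    write_fit_json(fits[[pop]],
                   file.path(config$out_dir, paste0("fit_", pop, ".json")))

  manifest <- list(
    package_version = as.character(utils::packageVersion("edlatent")),
    r_version = R.version.string,
    seed = config$seed,
    config_hash = config_hash(config),
    n_input = prep$filter_report$n_input,
    n_retained = prep$filter_report$n_retained,
    populations = config$populations, estimators = config$estimators,
    warnings = warn, timings = timings,
    true_ate = if (!is.null(truth)) as.list(truth$true_ate) else NULL)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(manifest = manifest, effects = effects,
                 subgroups = sub_tab, fits = fits, design = design,
                 truth = truth, filter_report = prep$filter_report,
                 scaling = prep$scaling))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(config)), f)
  unname(tools::md5sum(f))
}

write_fit_json <- function(fit, path) {
  p <- fit$params
  jsonlite::write_json(
    list(eta = as.list(p$eta),
         proxies = lapply(p$proxies$continuous, function(pr)
           list(alpha = pr$alpha, lambda = pr$lambda,
                kappa = as.list(pr$kappa), sigma = pr$sigma)),
         acuity = as.list(p$proxies$acuity),
         threshold = list(boundary_a = p$threshold$boundary_a,
                          start_w0 = p$threshold$start_w0,
                          delta = as.list(p$threshold$delta)),
         outcomes = lapply(p$outcomes, as.list),
         loglik = fit$loglik, loglik_trace = fit$loglik_trace,
         converged = fit$converged, n_iterations = fit$n_iterations,
         best_of_restarts = fit$best_of_restarts, flags = fit$flags),
    path, auto_unbox = TRUE, digits = NA)
}

#' Render an effect table in the reporting style
#'
#' Risk differences are reported in percentage points with one decimal and
#' the confidence interval as `"(lo to hi)"`, e.g. `"5.8 (5.0 to 6.5)"`.
#' Rounding is round-half-even on the percentage scale. The main layout has
#' one row per population and one column per estimator; the subgroup layout
#' one row per subgroup and one column per outcome family.
#'
#' @param estimates An `ed_effect` data.frame.
#' @param layout `"main"` or `"subgroup"`.
#' @return A data.frame of formatted strings.
#' @export
render_effect_table <- function(estimates, layout = c("main", "subgroup")) {
  layout <- match.arg(layout)
  if (!nrow(estimates)) stop("no estimates to render")
  if (length(unique(estimates$window)) > 1)
    stop("mixed windows in one table")
  if (layout == "main") {
    pops <- unique(estimates$population)
    ests <- unique(estimates$estimator)
    tab <- data.frame(population = pops, stringsAsFactors = FALSE)
    for (e in ests)
      tab[[paste0("rd_", e)]] <- vapply(pops, function(p) {
        r <- estimates[estimates$population == p & estimates$estimator == e, ]
        if (nrow(r) != 1) NA_character_ else
          format_rd_ci(r$rd, r$ci_low, r$ci_high)
      }, character(1))
  } else {
    pops <- unique(estimates$population)
    fams <- unique(estimates$family)
    tab <- data.frame(subgroup = pops, stringsAsFactors = FALSE)
    for (fm in fams)
      tab[[fm]] <- vapply(pops, function(p) {
        r <- estimates[estimates$population == p & estimates$family == fm, ]
        if (nrow(r) != 1) NA_character_ else
          format_rd_ci(r$rd, r$ci_low, r$ci_high)
      }, character(1))
  }
  tab
}

#' @rdname render_effect_table
#' @param rd,lo,hi Risk difference and interval bounds on the probability
#'   scale.
#' @export
format_rd_ci <- function(rd, lo, hi) {
  if (any(!is.finite(c(lo, hi)))) return(pct1(rd))
  sprintf("%s (%s to %s)", pct1(rd), pct1(lo), pct1(hi))
}

# percentage points, one decimal, round-half-even
pct1 <- function(x) formatC(round(100 * x, 1), format = "f", digits = 1)
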