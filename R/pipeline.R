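#' Pipeline configuration
#'
#' A single configuration object pins every under-specified constant of the
#' analysis (grids, folds, seeds, sample sizes) so a run is fully
#' reproducible. Exactly one of `input` (a survey CSV path) or `simulation`
#' (a [sim_config()]) must be given.
#'
#' @param input path to a survey CSV, or `NULL`.
#' @param simulation a `sim_config`, or `NULL`.
#' @param codebook a `bll_codebook`.
#' @param threshold elevated-BLL cutoff, µg/dL (> 0).
#' @param model_area area the risk-factor model is fit on (`"exposed"`,
#'   matching a study design where the reference area serves only the
#'   descriptive comparison), or `NULL` to model all records.
#' @param cv list of tuning controls: `k`, `n_lambda`, `lambda_min_ratio`,
#'   `seed`.
#' @param stability list with `N` (vector of replicate sizes), `B`,
#'   `seed`, and `scenarios`; `NULL` skips the stability stage.
#' @param output_dir directory for artifacts, or `NULL` to skip writing.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            codebook = default_codebook(), threshold = 10,
                            model_area = "exposed",
                            cv = list(k = 10, n_lambda = 100,
                                      lambda_min_ratio = 0.001, seed = 1L),
                            stability = list(N = c(150, 200, 250), B = 100,
                                             seed = 1L,
                                             scenarios = c("bootstrap",
                                                           "permutation")),
                            output_dir = NULL) {
  if (is.null(input) == is.null(simulation)) {
    stop_invalid("exactly one of 'input' and 'simulation' must be given")
  }
  if (!is.numeric(threshold) || threshold <= 0) {
    stop_invalid("threshold must be > 0")
  }
  structure(list(input = input, simulation = simulation, codebook = codebook,
                 threshold = threshold, model_area = model_area,
                 cv = utils::modifyList(
                   list(k = 10, n_lambda = 100, lambda_min_ratio = 0.001,
                        seed = 1L), cv %||% list()),
                 stability = stability, output_dir = output_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate the survey; descriptive
#' epidemiology; dummy-encode with group structure; CV-tuned group-Lasso
#' fit; unpenalized logistic reference fit; stability validation. Stage
#' failures abort with a stage-named error. Identical configs produce
#' identical reports.
#'
#' @param config a [pipeline_config()].
#' @return an `bll_report` list: provenance, descriptive tables, CV
#'   summary, penalized coefficients with odds ratios, the reference fit
#'   table, and stability frequencies.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cb <- config$codebook

  survey <- run_stage("load", {
    if (!is.null(config$input)) read_survey_csv(config$input, cb)
    else generate_survey(config$simulation)
  })

  describe <- run_stage("describe", {
    if (length(unique(survey$area[!is.na(survey$area)])) == 2) {
      describe_survey(survey, config$threshold)
    } else NULL
  })

  model_data <- survey
  if (!is.null(config$model_area) &&
      config$model_area %in% unique(as.character(survey$area))) {
    model_data <- survey[survey$area == config$model_area, , drop = FALSE]
  }
  enc <- run_stage("encode",
                   encode_survey(model_data, cb, config$threshold))

  cv <- run_stage("cv_fit", cv_grplasso(
    enc, k = config$cv$k, n_lambda = config$cv$n_lambda,
    lambda_min_ratio = config$cv$lambda_min_ratio, seed = config$cv$seed))
  fit <- cv$selected_fit

  reference <- run_stage("reference_fit", fit_logistic_mle(enc))

  stability <- NULL
  if (!is.null(config$stability)) {
    stability <- run_stage("stability", {
      st <- config$stability
      res <- list()
      for (scen in st$scenarios) {
        for (N in st$N) {
          fun <- if (scen == "bootstrap") bootstrap_stability
                 else permutation_stability
          res[[sprintf("%s_N%d", scen, N)]] <-
            fun(model_data, N = N, B = st$B, seed = st$seed,
                threshold = config$threshold, codebook = cb,
                k = config$cv$k, n_lambda = config$cv$n_lambda,
                lambda_min_ratio = config$cv$lambda_min_ratio)
        }
      }
      res
    })
  }

  penalized <- data.frame(term = names(fit$beta),
                          group = fit$group_names[fit$group],
                          coefficient = unname(fit$beta),
                          or = exp(unname(fit$beta)), row.names = NULL)
  report <- list(
    provenance = list(package = "bllasso",
                      version = as.character(utils::packageVersion("bllasso")),
                      config_hash = config_hash(config),
                      threshold = config$threshold,
                      seeds = list(simulation = config$simulation$seed,
                                   cv = config$cv$seed,
                                   stability = config$stability$seed),
                      n_records = nrow(survey), n_model = enc$n),
    descriptives = describe,
    cv = list(selected_lambda = cv$selected_lambda,
              selected_deviance = cv$selected_deviance,
              n_folds = cv$n_folds, curve = cv_table(cv)),
    selected_groups = fit$active_groups,
    penalized = penalized,
    reference = reference$table,
    stability = if (!is.null(stability)) {
      do.call(stability_table, unname(stability))
    },
    objects = list(survey = survey, encoded = enc, cv = cv,
                   reference = reference, stability = stability)
  )
  class(report) <- "bll_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

config_hash <- function(config) {
  x <- config
  x$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::serializeJSON(x, digits = 15)), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.bll_report <- function(x, ...) {
  cat("Analysis report\n")
  cat(sprintf("  records: %d total, %d modeled\n",
              x$provenance$n_records, x$provenance$n_model))
  cat(sprintf("  CV: lambda = %.4g, deviance = %.4g\n",
              x$cv$selected_lambda, x$cv$selected_deviance))
  cat(sprintf("  selected groups: %s\n",
              if (length(x$selected_groups))
                paste(x$selected_groups, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Write report artifacts
#'
#' Writes `report.json` (everything serializable), `cv_curve.csv`,
#' `coefficient_path.csv` and, when present, `stability.csv` under `dir`.
#'
#' @param report a `bll_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- report[setdiff(names(report), c("objects", "descriptives"))]
  json$descriptives <- if (!is.null(report$descriptives)) {
    d <- report$descriptives
    list(bll_summary = d$bll_summary, elevated_by_area = d$elevated_by_area,
         area_t_p = d$area_t_test$p_value, ancova_p = d$area_ancova$p_value)
  }
  paths <- character(0)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "cv_curve.csv")
  write.csv(report$cv$curve, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "coefficient_path.csv")
  write.csv(path_table(report$objects$cv$path), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$stability)) {
    p <- file.path(dir, "stability.csv")
    write.csv(report$stability, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
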