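# End-to-end orchestration: a validated run configuration names the input
# CSVs per stage and the estimator/test options; run_pipeline() executes the
# stages in dependency order and returns a report whose JSON serialization
# is byte-identical across reruns of the same configuration.

config_keys <- list(
  top = c("inputs", "options", "stages", "seed"),
  inputs = c("elutriation", "histogram", "decay", "uptake", "aa_panel",
             "lifespan", "strains"),
  options = c("max_budded", "window", "birth_method", "bandwidth",
              "vref_label", "q", "n_initial", "control", "treated",
              "variables", "predictors", "adjust")
)

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file) with keys `inputs`
#' (paths per stage), `options` (estimator and test options), `stages`
#' (which stages to run; defaults to every stage whose inputs are present)
#' and `seed`. Unknown keys anywhere are rejected before anything runs.
#'
#' @param config A named list, or the path to a YAML file.
#' @return The validated configuration list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort(sprintf("config file not found: %s", config),
            class = "g1span_io_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("config must be a named list or a YAML file path.",
          class = "g1span_config_error")
  }
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      abort(sprintf("unknown %s key(s): %s.", where,
                    paste(extra, collapse = ", ")),
            class = "g1span_config_error")
    }
  }
  reject_unknown(config, config_keys$top, "config")
  reject_unknown(config$inputs, config_keys$inputs, "inputs")
  reject_unknown(config$options, config_keys$options, "options")
  known_stages <- c("g1", "sizecontrol", "decay", "uptake", "aa",
                    "lifespan", "cohort")
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, known_stages)
    if (length(bad) > 0) {
      abort(sprintf("unknown stage(s): %s.", paste(bad, collapse = ", ")),
            class = "g1span_config_error")
    }
  }
  config
}

stage_inputs <- list(
  g1 = c("elutriation", "histogram"),
  sizecontrol = character(),   # depends on the g1 stage, not on a file
  decay = "decay",
  uptake = "uptake",
  aa = "aa_panel",
  lifespan = "lifespan",
  cohort = "strains"
)

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order: `g1` (per-strain
#' birth size, growth rate, critical size, G1 summary), `sizecontrol`
#' (slope of kT_G1 on log normalized birth size, fed by `g1`), `decay`
#' (half-life per labelled chase series), `uptake`, `aa` (amino-acid
#' percent changes), `lifespan` (survival summaries, percent extension,
#' log-rank and Wang-Allison tests) and `cohort` (LL/NLL comparisons and
#' logistic predictor ranking). A failing stage is recorded in the report
#' and its dependents are skipped.
#'
#' @param config A configuration list or YAML path; see
#'   [validate_config()].
#' @return A `pipeline_report`: a list with one element per executed stage
#'   (each carrying `status` and `result` or `error`) and a `provenance`
#'   block (config hash, seed, package version).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  opts <- config$options %||% list()
  inputs <- config$inputs %||% list()
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  stages <- config$stages %||% {
    avail <- names(inputs)
    s <- names(stage_inputs)[vapply(stage_inputs,
                                    function(req) all(req %in% avail),
                                    logical(1))]
    # sizecontrol only makes sense downstream of g1
    if (!"g1" %in% s) s <- setdiff(s, "sizecontrol")
    s
  }
  report <- list()
  g1_table <- NULL

  run_stage <- function(name, fun) {
    tryCatch(
      list(status = "ok", result = fun()),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e))
    )
  }

  for (st in intersect(names(stage_inputs), stages)) {
    if (st == "sizecontrol" && is.null(g1_table)) {
      report[[st]] <- list(status = "skipped",
                           error = "upstream g1 stage unavailable")
      next
    }
    res <- switch(st,
      g1 = run_stage(st, function() {
        el <- read_g1span_table(inputs$elutriation, "elutriation")
        hi <- read_g1span_table(inputs$histogram, "histogram")
        estimate_g1_panel(
          el, hi,
          max_budded = opts$max_budded %||% 0.5,
          window = opts$window %||% c(0.1, 0.9),
          birth_method = opts$birth_method %||% "smallest_mode",
          bandwidth = opts$bandwidth
        )
      }),
      sizecontrol = run_stage(st, function() {
        vref <- if (!is.null(opts$vref_label)) {
          g1_table$vb_fl[g1_table$label == opts$vref_label][1]
        } else NULL
        fit <- size_control_fit(g1_table, birth_size = .data$vb_fl,
                                kt_g1 = .data$kt_g1, vref = vref)
        list(fit = fit, label = classify_size_control(fit))
      }),
      decay = run_stage(st, function() {
        d <- read_g1span_table(inputs$decay, "decay")
        purrr::map_dfr(unique(d$label), function(lab) {
          f <- fit_decay(d[d$label == lab, ])
          tibble(label = lab, lambda = f$lambda, t_half = f$t_half,
                 r_squared = f$r_squared, n_points = f$n_points,
                 no_decay = f$no_decay)
        })
      }),
      uptake = run_stage(st, function() {
        uptake_summary(read_g1span_table(inputs$uptake, "uptake"),
                       n_initial = opts$n_initial %||% 3)
      }),
      aa = run_stage(st, function() {
        amino_acid_percent_change(
          read_g1span_table(inputs$aa_panel, "aa_panel"))
      }),
      lifespan = run_stage(st, function() {
        d <- read_g1span_table(inputs$lifespan, "lifespan")
        list(
          summary = lifespan_summary(d),
          percent_extension = percent_extension(d, opts$control,
                                                opts$treated),
          logrank = logrank_test(d, opts$control, opts$treated),
          wang_allison = wang_allison_test(d, opts$control, opts$treated,
                                           q = opts$q %||% 0.9),
          curves = survival_curve(d)
        )
      }),
      cohort = run_stage(st, function() {
        d <- read_g1span_table(inputs$strains, "strains")
        vars <- opts$variables %||% c("fitness", "mean_size_fl",
                                      "birth_size_fl", "g1_dna_fraction")
        list(
          comparisons = compare_groups(d, variables = vars,
                                       adjust = opts$adjust %||% "none"),
          logistic = logistic_rank(d, predictors = opts$predictors %||% vars)
        )
      })
    )
    if (st == "g1" && res$status == "ok") g1_table <- res$result
    report[[st]] <- res
  }

  report$provenance <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("g1span"))
  )
  class(report) <- "pipeline_report"
  report
}

# Convert a report (fit objects, tibbles, tables) into plain lists for JSON.
report_to_list <- function(x) {
  if (inherits(x, "g1span_fit")) {
    x <- purrr::discard(unclass(x), ~ inherits(.x, "data.frame"))
  }
  if (inherits(x, "table")) {
    return(list(dimnames = dimnames(x),
                counts = unclass(as.matrix(x))[seq_along(x)]))
  }
  if (inherits(x, "data.frame")) return(as.list(as.data.frame(x)))
  if (is.list(x)) return(purrr::map(x, report_to_list))
  x
}

#' Write a pipeline report to JSON
#'
#' Floats are serialized at 6 significant digits so that identical
#' configurations produce byte-identical report files.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  jsonlite::write_json(report_to_list(unclass(report)), path,
                       auto_unbox = TRUE, digits = 6, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
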