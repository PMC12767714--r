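#' Read or write the unit-record CSV interchange schema
#'
#' Columns: `record_id` (optional), `country_id`, `weight`, the indicator
#' columns, then covariates; missing values are empty fields; header row
#' required; UTF-8.
#'
#' @param path CSV path.
#' @param data Tibble to write.
#' @return `read_unit_records()` returns a tibble; `write_unit_records()`
#'   returns `path` invisibly.
#' @export
read_unit_records <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_unit_records
#' @export
write_unit_records <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or path to a YAML file) with exactly one
#' of `simulate` (a [rmnch_config()] argument list) or `input` (a list with
#' `records` and optionally `countries` CSV paths), plus optional blocks
#' `selection` (`K_range`, `M_range`, `criterion`), `estimation` (`n_starts`,
#' `tol`, `max_iter`), `imputation` (`enabled`, `cycles`, `m`), `structural`
#' (`indiv_covariates`, `group_covariates`, `random_intercept`), `equity`
#' (`dimensions`, `B`, `level`, `outcome`), `sensitivity` (`enabled`), and
#' top-level `seed` and `out_dir`.
#'
#' @param config Named list or YAML path.
#' @return The validated config list, with defaults filled in.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("`config` must be a list or a YAML path.")
  has_sim <- !is.null(config$simulate); has_input <- !is.null(config$input)
  if (has_sim == has_input)
    abort("Exactly one of `simulate` or `input` must be present.")
  defaults <- list(
    selection = list(K_range = 1:3, M_range = 1:2, criterion = "BIC"),
    estimation = list(n_starts = 10L, tol = 1e-8, max_iter = 500L),
    imputation = list(enabled = FALSE, cycles = 10L, m = 5L),
    structural = list(indiv_covariates = character(),
                      group_covariates = character(),
                      random_intercept = FALSE),
    equity = list(dimensions = NULL, B = 200L, level = 0.95, outcome = "posterior"),
    sensitivity = list(enabled = FALSE),
    seed = 1L, out_dir = NULL)
  for (nm in names(defaults)) {
    config[[nm]] <- if (is.list(defaults[[nm]]))
      modifyList(defaults[[nm]], config[[nm]] %||% list()) else
        config[[nm]] %||% defaults[[nm]]
  }
  config$selection$K_range <- as.integer(unlist(config$selection$K_range))
  config$selection$M_range <- as.integer(unlist(config$selection$M_range))
  if (!length(config$selection$K_range) || !length(config$selection$M_range))
    abort("Class-count ranges must be non-empty.")
  config
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order: data acquisition (simulation or CSV input), indicator
#' harmonization when raw count fields are present, weighted descriptive
#' summaries, optional chained-equations imputation (the measurement model is
#' then fitted to every completed dataset and class proportions averaged),
#' sequential class-count selection, the measurement fit at the chosen
#' `(K, M)`, the two-step structural regressions, the random-intercept
#' logistic summary, the equity table, and the indicator-subset sensitivity
#' refits. A single master seed drives every stochastic stage through one
#' stream-splitting rule, so identical configurations give identical reports.
#'
#' @param config Configuration list or YAML path (see [pipeline_config()]).
#' @param seed Optional master seed overriding the config's.
#' @param out_dir Optional output directory; when set, [write_report()] is
#'   called on completion.
#' @return A `pipeline_report` list with the stage outputs and provenance.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- out_dir %||% config$out_dir
  seeds <- split_seed(config$seed, 6L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }

  sim <- NULL
  data <- stage("data", {
    if (!is.null(config$simulate)) {
      args <- config$simulate
      args$seed <- args$seed %||% seeds[1]
      sim <- do.call(rmnch_config, args[intersect(names(args),
                                                  names(formals(rmnch_config)))])
      sim <- simulate_rmnch(sim)
      sim$data
    } else read_unit_records(config$input$records)
  })
  country_data <- if (!is.null(sim)) sim$country_data else
    if (!is.null(config$input$countries)) read_unit_records(config$input$countries)

  data <- stage("prep", {
    if ("anc_visits" %in% names(data)) harmonize_indicators(data) else data
  })
  summaries <- stage("summaries", weighted_summaries(data))

  completed <- stage("imputation", {
    if (isTRUE(config$imputation$enabled) &&
        anyNA(data[intersect(rmnch_indicators(), names(data))])) {
      chained_impute(data, cycles = config$imputation$cycles,
                     m = config$imputation$m, seed = seeds[2])
    } else list(data)
  })

  est <- config$estimation
  selection <- stage("selection", {
    select_structure(completed[[1L]],
                     K_range = config$selection$K_range,
                     M_range = config$selection$M_range,
                     criterion = config$selection$criterion,
                     n_starts = est$n_starts, tol = est$tol,
                     max_iter = est$max_iter, seed = seeds[3])
  })
  K <- selection$chosen[["K"]]; M <- selection$chosen[["M"]]
  fit <- selection$fits[[sprintf("K%d_M%d", K, M)]]

  class_tables <- stage("measurement", {
    tabs <- lapply(completed, function(d) {
      f <- if (identical(d, completed[[1L]])) fit else
        fit_mlca(d, K = K, M = M, n_starts = est$n_starts, tol = est$tol,
                 max_iter = est$max_iter, seed = seeds[3])
      summarize_classes(f$posteriors)
    })
    if (length(tabs) == 1L) tabs[[1L]] else average_class_tables(tabs)
  })

  structural <- or_table <- NULL
  if (length(config$structural$indiv_covariates) ||
      length(config$structural$group_covariates)) {
    structural <- stage("structural", {
      fit_two_step(completed[[1L]], fit$params,
                   indiv_covariates = config$structural$indiv_covariates,
                   group_covariates = config$structural$group_covariates,
                   country_data = country_data)
    })
    or_table <- odds_ratio_table(structural)
  }
  random_intercept <- NULL
  if (isTRUE(config$structural$random_intercept)) {
    random_intercept <- stage("random_intercept", {
      d <- completed[[1L]]
      d$map_optimal <- as.integer(fit$posteriors$map_indiv == 1L)
      fit_random_intercept_logistic(
        d, "map_optimal",
        covariates = config$structural$indiv_covariates, ci = "none")
    })
  }

  equity <- NULL
  if (!is.null(config$equity$dimensions)) {
    equity <- stage("equity", {
      d <- completed[[1L]]
      d$optimal <- if (identical(config$equity$outcome, "map"))
        as.numeric(fit$posteriors$map_indiv == 1L) else
          fit$posteriors$indiv_post[, 1L]
      equity_table(d, "optimal", config$equity$dimensions,
                   B = config$equity$B, level = config$equity$level,
                   seed = seeds[4])
    })
  }

  sensitivity <- NULL
  if (isTRUE(config$sensitivity$enabled)) {
    sensitivity <- stage("sensitivity", {
      res <- sensitivity_subsets(completed[[1L]], K = K, M = M,
                                 n_starts = est$n_starts, tol = est$tol,
                                 max_iter = est$max_iter, seed = seeds[5])
      res[c("models", "agreement")]
    })
  }

  report <- structure(
    list(selection = selection$table, chosen = selection$chosen,
         params = fit$params, fit = fit, class_tables = class_tables,
         summaries = summaries, or_table = or_table,
         random_intercept = random_intercept, equity = equity,
         sensitivity = sensitivity,
         provenance = list(seed = config$seed, config = config,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                           package_version = as.character(utils::packageVersion("rmnchlca")))),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

average_class_tables <- function(tabs) {
  avg <- function(extract, keys) {
    dplyr::bind_rows(lapply(tabs, extract)) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(share = mean(.data$share), .groups = "drop")
  }
  list(higher = avg(function(t) t$higher, "class"),
       lower_given_higher = avg(function(t) t$lower_given_higher,
                                c("higher_class", "lower_class")),
       lower = avg(function(t) t$lower, "class"),
       assignments = tabs[[1L]]$assignments)
}

#' Write a pipeline report to CSV/JSON artifacts with a manifest
#'
#' Emits one file per populated report section (CSV for tables, JSON for the
#' measurement parameters and scalar summaries) plus `manifest.json` listing
#' every file with its MD5 checksum; absent optional sections are marked
#' absent in the manifest rather than written.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(dir, 2L) != 0L) abort(sprintf("Directory '%s' is not writable.", dir))
  files <- character(0)
  put_csv <- function(tab, name) {
    if (is.null(tab)) return(invisible(NULL))
    path <- file.path(dir, name)
    readr::write_csv(tab, path, na = "")
    files <<- c(files, name)
  }
  put_json <- function(obj, name) {
    if (is.null(obj)) return(invisible(NULL))
    path <- file.path(dir, name)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  put_csv(report$selection, "selection.csv")
  put_json(list(pi = report$params$pi, tau = report$params$tau,
                rho = report$params$rho), "measurement_params.json")
  put_csv(report$class_tables$higher, "class_higher.csv")
  put_csv(report$class_tables$lower_given_higher, "class_lower_given_higher.csv")
  put_csv(report$class_tables$lower, "class_lower.csv")
  put_csv(report$class_tables$assignments, "class_assignments.csv")
  put_csv(report$summaries$indicators, "summary_indicators.csv")
  put_csv(report$summaries$countries, "summary_countries.csv")
  put_csv(report$or_table, "or_table.csv")
  if (!is.null(report$random_intercept)) {
    ri <- report$random_intercept
    put_json(list(sigma2 = ri$sigma2, ICC = ri$ICC, MOR = ri$MOR,
                  loglik = ri$loglik), "random_intercept.json")
    put_csv(ri$fixed, "random_intercept_fixed.csv")
  }
  put_csv(report$equity, "equity.csv")
  if (!is.null(report$sensitivity)) {
    put_csv(report$sensitivity$models, "sensitivity_models.csv")
    put_csv(report$sensitivity$agreement, "sensitivity_agreement.csv")
  }
  sections <- c("selection", "class_tables", "summaries", "or_table",
                "random_intercept", "equity", "sensitivity")
  manifest <- list(
    files = lapply(files, function(f)
      list(name = f, md5 = unname(tools::md5sum(file.path(dir, f))))),
    sections = setNames(lapply(sections, function(s) !is.null(report[[s]])),
                        sections),
    provenance = report$provenance[c("seed", "timestamp", "package_version")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report: chosen K = %d, M = %d (seed %d)\n",
              x$chosen[["K"]], x$chosen[["M"]], x$provenance$seed))
  sections <- c("or_table", "random_intercept", "equity", "sensitivity")
  present <- sections[!vapply(x[sections], is.null, logical(1))]
  cat("Sections:", paste(c("selection", "class_tables", "summaries", present),
                         collapse = ", "), "\n")
  invisible(x)
}
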