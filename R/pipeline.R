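#' Configure the end-to-end analysis pipeline
#'
#' Collects every stage parameter up front so a run is fully resolvable (and
#' reproducible) before execution. Unknown arguments are rejected.
#'
#' @param cohort a [cohort_config()] used to simulate the input cohort, or
#'   `NULL` when `panel_path` is given.
#' @param panel_path,covariates_path optional CSV inputs (see
#'   [read_panel()]); covariates need a `child_id` column.
#' @param apply_miss simulate missingness on the generated cohort?
#' @param min_waves inclusion rule (non-missing waves per process).
#' @param n_starts,tol,max_iter,seed passed to [fit_parallel()].
#' @param models named list of right-hand-side formulas for the three-step
#'   regressions, e.g. `list(sex = ~sex)`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), panel_path = NULL,
                            covariates_path = NULL, apply_miss = TRUE,
                            min_waves = 3, n_starts = 10, tol = 1e-8,
                            max_iter = 5000, seed = 1L,
                            models = list(sex = ~sex)) {
  structure(
    list(
      cohort = cohort, panel_path = panel_path,
      covariates_path = covariates_path, apply_miss = apply_miss,
      min_waves = min_waves, n_starts = n_starts, tol = tol,
      max_iter = max_iter, seed = as.integer(seed), models = models
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages of the published analysis: obtain (or simulate) the
#' panel and covariates, apply the both-process inclusion rule, fit the
#' parallel-process model, collapse to composite groups, and fit the
#' bias-adjusted three-step regressions. Deterministic given the config's
#' seeds. Any stage failure propagates with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list with `prevalence`, `joint_table`,
#'   `composite_shares`, `regression` (tibble of OR rows plus omnibus
#'   p-values), the fitted objects, and a `log` of seeds and convergence
#'   diagnostics.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  inputs <- stage("input", {
    if (!is.null(config$panel_path)) {
      panel <- read_panel(config$panel_path)
      covariates <- if (!is.null(config$covariates_path)) {
        readr::read_csv(config$covariates_path, show_col_types = FALSE, progress = FALSE)
      } else {
        NULL
      }
      list(panel = panel, covariates = covariates)
    } else {
      cohort <- generate_cohort(config$cohort)
      if (config$apply_miss) {
        cohort$panel <- apply_missingness(cohort$panel, config$cohort)
      }
      cohort
    }
  })
  prevalence <- stage("prevalence", marginal_prevalence_table(inputs$panel))
  filtered <- stage("filter", apply_inclusion_filter(inputs$panel, config$min_waves, "both"))
  fit <- stage("fit-parallel", fit_parallel(
    filtered, n_starts = config$n_starts, tol = config$tol,
    max_iter = config$max_iter, seed = config$seed
  ))
  composite <- stage("collapse", collapse_posterior(fit))
  D <- stage("error-matrix", error_matrix(composite))
  regression <- stage("regress", {
    if (length(config$models) == 0 || is.null(inputs$covariates)) {
      tibble::tibble(
        model = character(), term = character(), class = character(),
        estimate = double(), std.error = double(), or = double(),
        conf.low = double(), conf.high = double(), omnibus_p = double()
      )
    } else {
      purrr::imap(config$models, function(fml, nm) {
        ts <- fit_threestep(inputs$covariates, fml, composite, D)
        ors <- wald_intervals(ts)
        omni <- purrr::map_dfr(ts$term_labels, ~omnibus_test(ts, .x))
        ors$model <- nm
        ors$omnibus_p <- omni$p.value[match(
          vapply(ors$term, function(t) {
            hit <- which(vapply(omni$term, function(x) startsWith(t, x), TRUE))
            if (length(hit)) omni$term[max(hit)] else NA_character_
          }, ""), omni$term
        )]
        dplyr::select(ors, "model", dplyr::everything())
      }) %>% dplyr::bind_rows()
    }
  })
  structure(
    list(
      prevalence = prevalence,
      joint_table = joint_class_table(fit),
      composite_shares = 100 * composite_proportions(fit$joint_weights),
      regression = regression,
      fit = fit,
      composite = composite,
      error_matrix = D,
      log = tibble::tibble(
        key = c("seed", "n_children", "converged", "entropy", "loglik",
                "start_logliks"),
        value = c(config$seed, fit$n_children, fit$converged,
                  round(fit$entropy, 4), fit$loglik,
                  paste(round(fit$start_logliks, 2), collapse = ";"))
      )
    ),
    class = "pipeline_result"
  )
}

schema_version <- "v1"

#' Write and read pipeline result files
#'
#' Writes the machine-readable stage outputs as comma-separated text, each
#' with a versioned schema header line (`#schema=llca.<name>.v1`), plus a
#' human-readable `report.txt` mirroring the prevalence, joint-distribution
#' and risk-factor tables. `read_result()` refuses files whose schema header
#' does not match.
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param path a file written by `write_results()`.
#' @param name expected schema name (e.g. `"joint_table"`).
#' @return `write_results()` returns the file paths invisibly;
#'   `read_result()` a tibble.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) abort(paste0("directory not writable: ", dir))
  write_one <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(paste0("#schema=llca.", name, ".", schema_version), con)
    close(con)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
    path
  }
  jt <- tibble::as_tibble(bundle$joint_table, rownames = "constipation_class")
  shares <- tibble::tibble(
    composite = names(bundle$composite_shares),
    percent = unname(bundle$composite_shares)
  )
  weights <- dplyr::bind_rows(
    tibble::tibble(process = "soiling",
                   class = colnames(bundle$joint_table)[1:4],
                   weight = colSums(bundle$fit$joint_weights)),
    tibble::tibble(process = "constipation",
                   class = rownames(bundle$joint_table)[1:4],
                   weight = rowSums(bundle$fit$joint_weights))
  )
  paths <- c(
    write_one(bundle$prevalence, "prevalence"),
    write_one(jt, "joint_table"),
    write_one(shares, "composite_shares"),
    write_one(weights, "class_weights"),
    write_one(bundle$regression, "regression"),
    write_one(bundle$log, "run_log")
  )
  report <- file.path(dir, "report.txt")
  lines <- c(
    "Longitudinal classes of constipation and soiling: pipeline report",
    "",
    "Per-wave prevalence (%) by nested sample:",
    utils::capture.output(print(as.data.frame(bundle$prevalence), digits = 3)),
    "",
    "Joint class distribution (%, constipation rows x soiling columns):",
    utils::capture.output(print(bundle$joint_table)),
    "",
    "Composite group shares (%):",
    utils::capture.output(print(round(bundle$composite_shares, 1))),
    "",
    "Risk factors (OR, 95% CI, omnibus p):",
    utils::capture.output(print(as.data.frame(bundle$regression), digits = 3))
  )
  writeLines(lines, report)
  invisible(c(paths, report))
}

#' @rdname write_results
#' @export
read_result <- function(path, name) {
  header <- readLines(path, n = 1)
  expected <- paste0("#schema=llca.", name, ".", schema_version)
  if (!identical(header, expected)) {
    abort(paste0("schema mismatch in ", path, ": found '", header,
                 "', expected '", expected, "'"))
  }
  readr::read_csv(path, skip = 1, show_col_types = FALSE, progress = FALSE)
}
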