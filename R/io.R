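#' Read a delimited response file
#'
#' Reads respondent-by-item ordinal responses: a header row of item ids,
#' one respondent per row, integer category codes, empty cells = missing.
#' When an instrument is supplied the header is checked against its item
#' ids and every cell against the item's admissible code range.
#'
#' @param path Path to a CSV file (a `respondent_id` column is allowed and
#'   preserved).
#' @param instrument Optional `instrument` for validation.
#' @return A tibble of integer responses with `NA` for missing cells.
#' @export
read_responses <- function(path, instrument = NULL) {
  if (!file.exists(path)) abort(paste0("No such response file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          comment = "#")
  item_cols <- setdiff(names(data), c("respondent_id", ".id"))
  for (j in item_cols) {
    v <- data[[j]]
    if (is.character(v)) {
      v <- suppressWarnings(as.numeric(trimws(v)))
      if (any(is.na(v) & !is.na(data[[j]]) & trimws(data[[j]]) != "")) {
        abort(paste0("Non-numeric cell(s) in column '", j, "'."))
      }
    }
    if (any(!is.na(v) & v != round(v))) {
      abort(paste0("Non-integer category code(s) in column '", j, "'."))
    }
    data[[j]] <- as.integer(v)
  }
  if (!is.null(instrument)) {
    unknown <- setdiff(item_cols, instrument$id)
    if (length(unknown) > 0L) {
      abort(paste0("Unknown item id(s) in header: ",
                   paste(unknown, collapse = ", ")))
    }
    inst <- instrument_subset(instrument, item_cols)
    validate_codes(as.matrix(data[item_cols]), inst)
  }
  data
}

#' Run the full short-form construction and validation pipeline
#'
#' Orchestrates the workflow in its natural order: simulate (optional) or
#' read data, impute, GA item selection, reliability, factor structure,
#' IRT treatment-management scaling (optional), validity, sample-size
#' planning. Every requested stage's tabular output is written as CSV to
#' `out_dir` together with a log recording resolved parameters, seeds and
#' stage timings. One global seed expands deterministically into
#' per-stage seeds.
#'
#' @param config A named list or path to a YAML file with entries:
#'   `responses` (path) or `simulate = TRUE`; `instrument` (path, default
#'   the packaged CLCF-SF); `covariates`/`groups` (optional paths keyed by
#'   `respondent_id`); `stages` (character subset of `select`,
#'   `reliability`, `efa`, `irt`, `validity`, `samplesize`); `core`
#'   (item ids; default the instrument's core flags); `ga` (list of
#'   [ga_params()] overrides); `seed`; `out_dir`.
#' @return A named list of stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(
    simulate = FALSE,
    stages = c("reliability"),
    seed = 1L,
    out_dir = "shortscale-run",
    level = 0.95,
    ga = list()
  )
  cfg <- modifyList(defaults, config)

  # pre-flight: every referenced path must exist before any stage runs
  for (key in c("responses", "instrument", "covariates", "groups")) {
    p <- cfg[[key]]
    if (is.character(p) && !file.exists(p)) {
      abort(paste0("Pre-flight: config path `", key, "` does not exist: ", p))
    }
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$responses)) {
    abort("Pre-flight: need either `responses` or `simulate: true`.")
  }
  if ("validity" %in% cfg$stages &&
      is.null(cfg$covariates) && is.null(cfg$groups) && !isTRUE(cfg$simulate)) {
    abort("Pre-flight: validity stage needs `covariates` and/or `groups`.")
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 8L)
  names(seeds) <- c("simulate", "impute", "select", "reliability", "efa",
                    "irt", "validity", "samplesize")
  log_path <- file.path(cfg$out_dir, "run.log")
  log_lines <- c(
    paste0("shortscale run ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", cfg$seed),
    paste0("stage seeds: ",
           paste(names(seeds), seeds, sep = "=", collapse = " ")),
    paste0("config: ", paste(deparse(cfg[setdiff(names(cfg), "ga")]),
                             collapse = " "))
  )
  say <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  timer <- function(stage, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    say(sprintf("stage %-12s %.2fs", stage,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  results <- list()

  instrument <- if (is.null(cfg$instrument)) clcf_sf() else read_instrument(cfg$instrument)

  if (isTRUE(cfg$simulate)) {
    spec_args <- cfg$cohort %||% list()
    spec_args$instrument <- instrument
    spec_args$seed <- seeds[["simulate"]]
    spec <- do.call(cohort_spec, spec_args)
    sim <- timer("simulate", simulate_cohort(spec))
    responses <- sim$responses
    covariates <- sim$covariates
    groups <- sim$groups
    readr::write_csv(responses, file.path(cfg$out_dir, "responses.csv"))
    readr::write_csv(covariates, file.path(cfg$out_dir, "covariates.csv"))
    readr::write_csv(groups, file.path(cfg$out_dir, "groups.csv"))
    truth <- tibble(respondent_id = responses$respondent_id,
                    theta = sim$truth$theta)
    readr::write_csv(truth, file.path(cfg$out_dir, "truth.csv"))
    results$simulate <- sim
  } else {
    responses <- read_responses(cfg$responses, instrument)
    covariates <- if (!is.null(cfg$covariates)) {
      readr::read_csv(cfg$covariates, show_col_types = FALSE, progress = FALSE)
    }
    groups <- if (!is.null(cfg$groups)) {
      readr::read_csv(cfg$groups, show_col_types = FALSE, progress = FALSE)
    }
  }

  item_cols <- intersect(instrument$id, names(responses))
  completed <- timer("impute", impute_median(responses, item_cols))
  results$imputation <- imputation_report(completed)
  readr::write_csv(
    results$imputation %>% select(-"per_item_medians"),
    file.path(cfg$out_dir, "imputation_report.csv")
  )

  core <- cfg$core %||% instrument$id[instrument$core]
  selected_items <- item_cols

  if ("select" %in% cfg$stages) {
    ga_args <- cfg$ga
    ga_args$seed <- ga_args$seed %||% seeds[["select"]]
    params <- do.call(ga_params, ga_args)
    fit <- timer("select", ga_evolve(completed[item_cols],
                                     core = intersect(core, item_cols),
                                     params = params))
    results$select <- fit
    selected_items <- fit$best$items[[1L]]
    readr::write_csv(fit$trace, file.path(cfg$out_dir, "fitness_trace.csv"))
    readr::write_csv(
      instrument %>% filter(.data$id %in% selected_items) %>% as_tibble(),
      file.path(cfg$out_dir, "selected_instrument.csv")
    )
    say("selected items: ", paste(selected_items, collapse = ", "))
  }

  if ("reliability" %in% cfg$stages) {
    rep <- timer("reliability",
                 reliability_report(completed, instrument, selected_items,
                                    level = cfg$level))
    results$reliability <- rep
    readr::write_csv(glance(rep), file.path(cfg$out_dir, "reliability_scale.csv"))
    readr::write_csv(tidy(rep), file.path(cfg$out_dir, "reliability_items.csv"))
  }

  if ("efa" %in% cfg$stages) {
    pc <- timer("efa", polychoric(completed, selected_items))
    ef <- efa_ml(pc, n_factors = cfg$n_factors %||% 1)
    results$efa <- ef
    results$unidimensionality <- check_unidimensionality(ef)
    readr::write_csv(tidy(ef), file.path(cfg$out_dir, "efa_loadings.csv"))
    readr::write_csv(
      tibble(eigenvalue = ef$eigenvalues),
      file.path(cfg$out_dir, "efa_eigenvalues.csv")
    )
    readr::write_csv(results$unidimensionality,
                     file.path(cfg$out_dir, "unidimensionality.csv"))
  }

  if ("irt" %in% cfg$stages && !is.null(cfg$irt_responses)) {
    irt_data <- read_responses(cfg$irt_responses)
    fit <- timer("irt", fit_rsm(irt_data))
    results$irt <- fit
    readr::write_csv(tidy(fit), file.path(cfg$out_dir, "rsm_difficulties.csv"))
    readr::write_csv(person_scores(fit), file.path(cfg$out_dir, "rsm_persons.csv"))
  }

  if ("validity" %in% cfg$stages) {
    scores <- sum_score(completed, instrument, selected_items)
    vd <- scores
    if (!is.null(covariates)) vd <- left_join(vd, covariates, by = "respondent_id")
    if (!is.null(groups)) vd <- left_join(vd, groups, by = "respondent_id")
    covariate_cols <- setdiff(names(covariates %||% tibble()), "respondent_id")
    group_cols <- setdiff(names(groups %||% tibble()), "respondent_id")
    rep <- timer("validity",
                 validity_battery(vd, "total", covariate_cols, group_cols))
    results$validity <- rep
    if (nrow(rep$correlations) > 0L) {
      readr::write_csv(rep$correlations,
                       file.path(cfg$out_dir, "validity_correlations.csv"))
    }
    if (nrow(rep$group_comparisons) > 0L) {
      readr::write_csv(rep$group_comparisons,
                       file.path(cfg$out_dir, "validity_groups.csv"))
    }
  }

  if ("samplesize" %in% cfg$stages) {
    plan <- timer("samplesize",
                  precision_plan(k = length(selected_items),
                                 half_width = cfg$half_width %||% 0.1,
                                 level = cfg$level))
    results$samplesize <- plan
    readr::write_csv(plan$alpha_plan, file.path(cfg$out_dir, "precision_plan.csv"))
  }

  writeLines(log_lines, log_path)
  invisible(results)
}
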