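#' Build and validate a pipeline run configuration
#'
#' Collects the paths and the fixed algorithm parameters of a cohort
#' run: the 500-pixel neighbor-edge threshold, the 20-cell minimum
#' fragment size, the summary quantile, the sub-window discard margin
#' and the pseudo-point spacing.
#'
#' @param cells_dir directory of per-slide cell tables
#'   (`<slide_id>.csv`).
#' @param out_dir output directory (created if missing).
#' @param metadata_path optional CSV with `slide_id`, `diagnosis_group`,
#'   `pfi_time`, `pfi_event` enabling the cohort statistics stage.
#' @param max_edge_len,min_component_size,quantile,margin,pseudo_spacing
#'   algorithm parameters (see [count_layers()], [plan_tiles()],
#'   [generate_pseudo_points()]).
#' @param seed integer seed recorded in the manifest and used for any
#'   stochastic step.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return validated list of class `"run_config"`.
#' @export
run_config <- function(cells_dir, out_dir, metadata_path = NULL,
                       max_edge_len = 500, min_component_size = 20,
                       quantile = 0.5, margin = 50, pseudo_spacing = 60,
                       seed = 1L, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (max_edge_len <= 0) stop("max_edge_len must be positive", call. = FALSE)
  if (min_component_size < 1)
    stop("min_component_size must be >= 1", call. = FALSE)
  if (quantile <= 0 || quantile >= 1)
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  if (margin < 0 || margin >= 250)
    stop("margin must lie in [0, 250)", call. = FALSE)
  if (pseudo_spacing <= 0)
    stop("pseudo_spacing must be positive", call. = FALSE)
  structure(list(cells_dir = cells_dir, out_dir = out_dir,
                 metadata_path = metadata_path,
                 max_edge_len = max_edge_len,
                 min_component_size = min_component_size,
                 quantile = quantile, margin = margin,
                 pseudo_spacing = pseudo_spacing,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys mirror the
#'   [run_config()] arguments.
#' @param ... overrides applied on top of the file values.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
          else yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the per-slide counting pipeline over a cohort
#'
#' For every `*.csv` cell table in `cells_dir`: count layers
#' ([count_layers()]) and write the per-slide result (CSV + JSON
#' sidecar). Failures are isolated per slide: a slide that errors is
#' logged and listed in the summary while the rest of the cohort
#' proceeds. Slide summaries are collected into `cohort.csv`; when
#' metadata is available, the group comparison and median-split survival
#' analysis run and land in `report.json`. A `manifest.json` records
#' parameters, seed, package version and MD5 hashes of inputs and
#' outputs (no timestamps, so reruns are byte-identical).
#'
#' @param config a [run_config()].
#' @return list with `cohort` (data.frame), `failures` (named character
#'   vector of error messages), `report` (list or `NULL`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$log_level != "quiet") message(...)
  files <- sort(list.files(config$cells_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop("no cell tables (*.csv) found in '", config$cells_dir, "'",
         call. = FALSE)

  rows <- list()
  failures <- character()
  outputs <- character()
  for (f in files) {
    sid <- sub("\\.csv$", "", basename(f))
    res <- tryCatch({
      cells <- read_cell_table(f)
      r <- count_layers(cells,
                        max_edge_len = config$max_edge_len,
                        min_component_size = config$min_component_size,
                        quantile = config$quantile)
      out_csv <- file.path(config$out_dir,
                           paste0(sid, "_layers.csv"))
      write_layer_result(r, out_csv)
      outputs <- c(outputs, out_csv, paste0(out_csv, ".json"))
      say("slide ", sid, ": median ", r$median_layers,
          " (n_inner ", r$n_inner, ")")
      r
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      say("slide ", sid, " FAILED: ", conditionMessage(res))
    } else {
      rows[[sid]] <- data.frame(slide_id = sid,
                                median_layers = res$median_layers,
                                sd_layers = res$sd_layers,
                                n_inner = res$n_inner)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  report <- NULL
  if (!is.null(config$metadata_path) && !is.null(cohort)) {
    meta <- utils::read.csv(config$metadata_path,
                            stringsAsFactors = FALSE)
    cohort <- merge(cohort, meta, by = "slide_id", sort = TRUE)
    report <- list()
    if ("diagnosis_group" %in% names(cohort)) {
      cmp <- compare_groups(cohort, "median_layers")
      cmp_sd <- compare_groups(cohort, "sd_layers")
      report$anova_median <- list(f = cmp$f_statistic, p = cmp$p_value)
      report$anova_sd <- list(f = cmp_sd$f_statistic, p = cmp_sd$p_value)
    }
    if (all(c("pfi_time", "pfi_event") %in% names(cohort))) {
      sv <- survival_split(cohort)
      report$survival <- list(
        split_threshold = sv$split_threshold,
        n_low = as.integer(sv$group_sizes["low"]),
        n_high = as.integer(sv$group_sizes["high"]),
        hazard_ratio = sv$hazard_ratio,
        p_wald = sv$p_wald, p_lrt = sv$p_lrt)
    }
  }

  cohort_csv <- file.path(config$out_dir, "cohort.csv")
  if (!is.null(cohort)) {
    utils::write.csv(cohort, cohort_csv, row.names = FALSE, quote = FALSE)
    outputs <- c(outputs, cohort_csv)
  }
  if (!is.null(report)) {
    report_json <- file.path(config$out_dir, "report.json")
    jsonlite::write_json(report, report_json, auto_unbox = TRUE,
                         digits = NA, na = "null")
    outputs <- c(outputs, report_json)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("onionpeel")),
    parameters = config[c("max_edge_len", "min_component_size",
                          "quantile", "margin", "pseudo_spacing")],
    seed = config$seed,
    inputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                     basename(files))),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(sort(outputs))), basename(sort(outputs)))),
    failures = as.list(failures))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(cohort = cohort, failures = failures, report = report,
       manifest = manifest)
}
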