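## End-to-end orchestration: preprocess -> home/places -> features ->
## labels -> (optionally) cross-validated evaluation, in memory via
## process_cohort() or on disk via run_pipeline() with a resolved config.

#' Process a cohort from raw traces to the labeled feature table
#'
#' Runs preprocessing, home inference and recentering, feature extraction
#' and week labeling for every participant.
#'
#' @param traces Combined raw trace tibble (`participant`, `t`, `x`, `y`).
#' @param qids Combined QIDS response tibble.
#' @param params [preprocess_params()].
#' @param tz Timezone for all clock-time rules.
#' @param d,l Stationary speed threshold (km/h) and cluster separation (km).
#' @param seed Seed for cluster initialization.
#' @param alpha,alpha_grid Daily-exclusion multiplier / optional grid.
#' @param min_day_coverage,min_days Week sufficiency rule.
#' @return List with `grids` (recentered grid traces), `homes` (inferred
#'   home per participant), `features`, `labels` and `data` (features
#'   joined with labels, labeled weeks only).
#' @export
process_cohort <- function(traces, qids, params = preprocess_params(),
                           tz = params$tz, d = 1.5, l = 0.4, seed = 1L,
                           alpha = 1, alpha_grid = NULL,
                           min_day_coverage = 0.5, min_days = 4) {
  pids <- unique(traces$participant)
  grids <- list()
  homes <- list()
  removed <- integer(length(pids))
  for (i in seq_along(pids)) {
    g <- preprocess_trace(traces[traces$participant == pids[i], ], params)
    removed[i] <- attr(g, "n_removed")
    h <- infer_home(g, tz = tz)
    homes[[i]] <- tibble::tibble(participant = pids[i],
                                 x = h$home[["x"]], y = h$home[["y"]])
    grids[[i]] <- h$grid
  }
  grids <- dplyr::bind_rows(grids)
  features <- extract_feature_table(grids, tz = tz, d = d, l = l, seed = seed,
                                    alpha = alpha, alpha_grid = alpha_grid,
                                    min_day_coverage = min_day_coverage,
                                    min_days = min_days)
  labels <- label_weeks(qids, tz = tz)
  data <- dplyr::inner_join(features, labels,
                            by = c("participant", "week_start")) |>
    dplyr::filter(!is.na(.data$score))
  list(grids = grids, homes = dplyr::bind_rows(homes), features = features,
       labels = labels, data = data,
       log = tibble::tibble(participant = pids, fixes_removed = removed))
}

#' Default pipeline configuration
#'
#' A single nested list mirroring the stage parameters (every named
#' threshold of the method surfaced with its default), serializable to
#' YAML. `run_pipeline()` writes the resolved config beside its outputs.
#'
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = "geomood-run") {
  list(
    seed = seed,
    out_dir = out_dir,
    tz = "UTC",
    simulate = unclass(synthetic_config(seed = seed)),
    preprocess = unclass(preprocess_params()),
    places = list(d = 1.5, l = 0.4),
    features = list(alpha = 1, band_h = c(23.5, 24.5), n_freq = 25,
                    min_day_coverage = 0.5, min_days = 4),
    label = list(threshold = 11),
    evaluate = list(model = "qda", scheme = "lopo", M = 100,
                    features = c("HS_base", "NENT_base", "NC_base",
                                 "TD_base", "DMD_base"))
  )
}

#' Run the full pipeline to disk
#'
#' simulate -> preprocess/places/featurize/label -> evaluate, writing
#' per-stage outputs (`features.csv`, `labels.csv`, `report.json`) and the
#' resolved configuration (`config.yaml`) under `config$out_dir`. Stages
#' whose outputs already exist and are newer than their inputs are skipped.
#'
#' @param config List from [default_config()] (possibly edited), or a path
#'   to a YAML file of the same shape.
#' @param input_dir Optional directory of real `*_trace.csv` /
#'   `*_qids.csv` files; when absent, the simulate stage generates a
#'   synthetic cohort there first.
#' @return The evaluation report, invisibly; all outputs on disk.
#' @export
run_pipeline <- function(config = default_config(), input_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out, "config.yaml"))
  sim_dir <- input_dir %||% file.path(out, "cohort")
  if (is.null(input_dir) && !file.exists(file.path(sim_dir, "truth.json"))) {
    message("simulate: generating synthetic cohort")
    sim_cfg <- do.call(synthetic_config, config$simulate[
      setdiff(names(config$simulate), character(0))])
    write_cohort(generate_cohort(sim_cfg), sim_dir)
  }
  trace_files <- list.files(sim_dir, pattern = "_trace\\.csv$", full.names = TRUE)
  qids_files <- list.files(sim_dir, pattern = "_qids\\.csv$", full.names = TRUE)
  if (length(trace_files) == 0) stop("no trace CSVs found in ", sim_dir, call. = FALSE)
  feat_path <- file.path(out, "features.csv")
  lab_path <- file.path(out, "labels.csv")
  newest_input <- max(file.mtime(c(trace_files, qids_files)))
  if (!file.exists(feat_path) || file.mtime(feat_path) < newest_input) {
    message("preprocess/places/featurize: ", length(trace_files), " participants")
    traces <- purrr::map_dfr(trace_files, function(f)
      read_trace_csv(f, participant = sub("_trace$", "", tools::file_path_sans_ext(basename(f)))))
    qids <- purrr::map_dfr(qids_files, function(f)
      read_qids_csv(f, participant = sub("_qids$", "", tools::file_path_sans_ext(basename(f)))))
    pp <- do.call(preprocess_params, config$preprocess)
    res <- process_cohort(traces, qids, params = pp, tz = config$tz,
                          d = config$places$d, l = config$places$l,
                          seed = config$seed, alpha = config$features$alpha,
                          min_day_coverage = config$features$min_day_coverage,
                          min_days = config$features$min_days)
    readr::write_csv(res$features, feat_path, progress = FALSE)
    readr::write_csv(res$labels, lab_path, progress = FALSE)
  } else {
    message("featurize: outputs up to date, skipping")
  }
  features <- readr::read_csv(feat_path, show_col_types = FALSE)
  labels <- readr::read_csv(lab_path, show_col_types = FALSE)
  features$week_start <- as.POSIXct(features$week_start, tz = "UTC")
  labels$week_start <- as.POSIXct(labels$week_start, tz = "UTC")
  ev <- config$evaluate
  cv <- run_cv(features, labels, ev$features, model = ev$model,
               scheme = ev$scheme, M = ev$M, seed = config$seed)
  report <- list(
    n_participants = length(trace_files),
    n_weeks = cv$n_weeks,
    model = ev$model, scheme = ev$scheme, features = ev$features,
    summary = if (cv$task == "classification")
      as.list(setNames(cv$summary$median, cv$summary$metric))
    else list(mae = cv$mae, mae_baseline = cv$mae_baseline)
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  message("report written to ", file.path(out, "report.json"))
  invisible(cv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a participant's trace or grid trace
#'
#' @param trace Trace or grid-trace tibble (one participant).
#' @param ... Unused.
#' @return A ggplot object: the planar path, colored by time.
#' @export
plot_trace <- function(trace, ...) {
  obs <- trace[!is.na(trace$x), ]
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$t)) +
    ggplot2::geom_path(alpha = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "km east of home", y = "km north of home") +
    ggplot2::theme_minimal()
}

#' Feature distributions split by depression label
#'
#' Boxplots of each requested feature column for depressed vs non-depressed
#' weeks.
#'
#' @param data Joined feature/label tibble (e.g. `process_cohort()$data`).
#' @param features Feature columns to show.
#' @return A ggplot object.
#' @export
plot_feature_distributions <- function(data,
                                       features = paste0(FEATURE_NAMES, "_base")) {
  long <- data |>
    dplyr::select(dplyr::all_of(c(features, "depressed"))) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$depressed, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 4) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "depressed week (QIDS >= 11)", y = NULL) +
    ggplot2::theme_minimal()
}
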