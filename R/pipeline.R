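## Reproducible pipeline: strict YAML config, staged execution
## (simulate -> process -> screen -> infer -> features -> cluster) and a
## run manifest with seeds and artifact checksums.

#' Default pipeline configuration
#'
#' All stage parameters with their defaults: 20 frames/s acquisition,
#' 7-px ROIs, 5-frame moving average, 25-s drift blocks, 10th-percentile F0,
#' 0.8% dF/F0 detection threshold with a 1-s decay constant, 1-s burst rule
#' and k = 8 groups.
#'
#' @return Nested named list (sections `seed`, `simulate`, `process`,
#'   `screen`, `infer`, `features`, `cluster`).
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_per_class = list(low = 120, intermediate = 64, high = 16, inactive = 38),
      fps = 20, duration_s = 600, um_per_px = 4.40, roi_size_px = 7,
      baseline = 100, noise_sd = 0.125, amplitude_pct = 1.0, tau_s = 1.0
    ),
    process = list(window_frames = 5, block_s = 25, f0_percentile = 10,
                   detection_threshold = 0, min_separation_px = 7),
    screen = list(threshold_pct = NULL, n_rounds = 50, n_labeled_per_class = 100),
    infer = list(threshold_pct = 0.8, tau_s = 1.0, amplitude_pct = 1.0,
                 min_duration_frames = 2),
    features = list(max_isi_s = 1.0),
    cluster = list(k = 8, n_restarts = 50)
  )
}

check_range <- function(value, key, lower = -Inf, strict = FALSE,
                        allow_null = FALSE) {
  if (is.null(value)) {
    if (allow_null) return(invisible(NULL))
    stop_config(key, "is missing")
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_config(key, "must be a single finite number")
  }
  if (strict && value <= lower) stop_config(key, paste("must be >", lower))
  if (!strict && value < lower) stop_config(key, paste("must be >=", lower))
  invisible(value)
}

stop_config <- function(key, msg) {
  stop(errorCondition(paste0("config error at `", key, "`: ", msg),
                      class = c("caltrace_config_error", "error")))
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) stop_config(full, "unknown key")
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "n_per_class") {
      if (!is.list(user[[key]])) stop_config(full, "must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list), fills unset keys with the
#' defaults of [default_config()], rejects unknown keys and range-checks
#' every stage parameter before any stage runs.
#'
#' @param config Path to a YAML file, a nested list, or `NULL` for pure
#'   defaults. An empty file yields the full default configuration.
#' @return Validated config list (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  config <- config %||% list()
  if (!is.list(config)) stop_config("<root>", "must be a mapping")
  cfg <- merge_config(default_config(), config)
  check_range(cfg$seed, "seed", 0)
  sim <- cfg$simulate
  check_range(sim$fps, "simulate.fps", 0, strict = TRUE)
  check_range(sim$duration_s, "simulate.duration_s", 0, strict = TRUE)
  check_range(sim$baseline, "simulate.baseline", 0, strict = TRUE)
  check_range(sim$noise_sd, "simulate.noise_sd", 0)
  check_range(sim$amplitude_pct, "simulate.amplitude_pct", 0, strict = TRUE)
  check_range(sim$tau_s, "simulate.tau_s", 0, strict = TRUE)
  check_range(sim$roi_size_px, "simulate.roi_size_px", 1)
  if (sim$roi_size_px %% 2 != 1) stop_config("simulate.roi_size_px", "must be odd")
  known <- c("low", "intermediate", "high", "inactive")
  bad <- setdiff(names(sim$n_per_class), known)
  if (length(bad)) stop_config(paste0("simulate.n_per_class.", bad[1]), "unknown class")
  for (nm in names(sim$n_per_class)) {
    check_range(sim$n_per_class[[nm]], paste0("simulate.n_per_class.", nm), 0)
  }
  pr <- cfg$process
  check_range(pr$window_frames, "process.window_frames", 1)
  if (pr$window_frames %% 2 != 1) stop_config("process.window_frames", "must be odd")
  check_range(pr$block_s, "process.block_s", 0, strict = TRUE)
  check_range(pr$f0_percentile, "process.f0_percentile", 0)
  if (pr$f0_percentile > 100) stop_config("process.f0_percentile", "must be <= 100")
  check_range(pr$min_separation_px, "process.min_separation_px", 0)
  check_range(cfg$screen$threshold_pct, "screen.threshold_pct", 0,
              strict = TRUE, allow_null = TRUE)
  check_range(cfg$screen$n_rounds, "screen.n_rounds", 1)
  check_range(cfg$screen$n_labeled_per_class, "screen.n_labeled_per_class", 1)
  inf <- cfg$infer
  check_range(inf$threshold_pct, "infer.threshold_pct", 0, strict = TRUE)
  check_range(inf$tau_s, "infer.tau_s", 0, strict = TRUE)
  check_range(inf$amplitude_pct, "infer.amplitude_pct", 0, strict = TRUE)
  check_range(inf$min_duration_frames, "infer.min_duration_frames", 1)
  check_range(cfg$features$max_isi_s, "features.max_isi_s", 0, strict = TRUE)
  check_range(cfg$cluster$k, "cluster.k", 2)
  check_range(cfg$cluster$n_restarts, "cluster.n_restarts", 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

stage_file <- function(outdir, name) file.path(outdir, name)

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(errorCondition(
      paste0("stage `", stage, "` needs missing input: ", path),
      class = c("caltrace_dependency_error", "error")
    ))
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in the fixed order
#' `simulate -> process -> screen -> infer -> features -> cluster`, writing
#' each stage's artifacts (CSV/JSON) under `outdir` and a `manifest.json`
#' recording the config, seeds, package version and MD5 checksums of every
#' artifact. Reruns with an identical config and seed reproduce identical
#' checksums.
#'
#' @param config A [validate_config()] result, a YAML path, or `NULL`.
#' @param stages Character subset of the six stage names (default: all).
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, stages = c("simulate", "process",
                                                   "screen", "infer",
                                                   "features", "cluster"),
                         outdir = "caltrace-run") {
  all_stages <- c("simulate", "process", "screen", "infer", "features", "cluster")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  names(seeds) <- all_stages
  sim <- config$simulate
  geometry <- acquisition_geometry(fps = sim$fps, frame_shape = c(720, 960),
                                   um_per_px = sim$um_per_px,
                                   roi_size_px = sim$roi_size_px,
                                   duration = sim$duration_s)
  model_sim <- transient_model(amplitude = sim$amplitude_pct, tau = sim$tau_s,
                               threshold = config$infer$threshold_pct)
  artifacts <- character(0)

  if ("simulate" %in% stages) {
    pop <- make_population(sim$n_per_class, seed = seeds[["simulate"]],
                           model = model_sim, geometry = geometry,
                           baseline = sim$baseline, noise_sd = sim$noise_sd)
    ids <- paste0("roi_", seq_along(pop$traces))
    write_traces_csv(pop$traces, stage_file(outdir, "traces_raw.csv"), ids)
    write_spikes_csv(pop$spikes, stage_file(outdir, "spikes_truth.csv"), ids)
    write.csv(data.frame(roi_id = ids, label = pop$labels),
              stage_file(outdir, "labels_truth.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "traces_raw.csv", "spikes_truth.csv",
                   "labels_truth.csv")
  }

  if ("process" %in% stages) {
    raw_path <- require_artifact(stage_file(outdir, "traces_raw.csv"), "process")
    raw <- read_traces_csv(raw_path)
    pr <- config$process
    norm <- lapply(raw, process_trace, window_frames = pr$window_frames,
                   block_s = pr$block_s, f0_probs = pr$f0_percentile / 100)
    write_traces_csv(norm, stage_file(outdir, "traces_dff.csv"), names(raw))
    artifacts <- c(artifacts, "traces_dff.csv")
  }

  if ("screen" %in% stages) {
    dff_path <- require_artifact(stage_file(outdir, "traces_dff.csv"), "screen")
    lab_path <- require_artifact(stage_file(outdir, "labels_truth.csv"), "screen")
    norm <- read_traces_csv(dff_path, normalized = TRUE)
    labels <- read.csv(lab_path)
    res <- screen_population(norm, ifelse(labels$label == "inactive",
                                          "inactive", "active"),
                             threshold = config$screen$threshold_pct,
                             n_rounds = config$screen$n_rounds,
                             n_labeled_per_class = config$screen$n_labeled_per_class,
                             seed = seeds[["screen"]])
    write_screen_model(res$model, stage_file(outdir, "screen_model.json"))
    write.csv(data.frame(roi_id = names(norm), label = res$labels,
                         margin = res$margins),
              stage_file(outdir, "screen_labels.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "screen_model.json", "screen_labels.csv")
  }

  if ("infer" %in% stages) {
    dff_path <- require_artifact(stage_file(outdir, "traces_dff.csv"), "infer")
    scr_path <- require_artifact(stage_file(outdir, "screen_labels.csv"), "infer")
    norm <- read_traces_csv(dff_path, normalized = TRUE)
    scr <- read.csv(scr_path)
    active_ids <- scr$roi_id[scr$label == "active"]
    inf <- config$infer
    model_inf <- transient_model(amplitude = inf$amplitude_pct,
                                 tau = inf$tau_s,
                                 threshold = inf$threshold_pct)
    trains <- lapply(norm[active_ids], function(tr) {
      peel(tr, model_inf,
           min_duration_frames = inf$min_duration_frames)$spikes
    })
    write_spikes_csv(trains, stage_file(outdir, "spikes_inferred.csv"),
                     active_ids)
    artifacts <- c(artifacts, "spikes_inferred.csv")
  }

  if ("features" %in% stages) {
    spk_path <- require_artifact(stage_file(outdir, "spikes_inferred.csv"),
                                 "features")
    scr_path <- require_artifact(stage_file(outdir, "screen_labels.csv"),
                                 "features")
    scr <- read.csv(scr_path)
    active_ids <- scr$roi_id[scr$label == "active"]
    trains <- read_spikes_csv(spk_path, sim$duration_s, active_ids)
    ft <- feature_table(trains, max_isi = config$features$max_isi_s,
                        ids = active_ids)
    write.csv(ft, stage_file(outdir, "features.csv"), row.names = FALSE)
    artifacts <- c(artifacts, "features.csv")
  }

  if ("cluster" %in% stages) {
    ft_path <- require_artifact(stage_file(outdir, "features.csv"), "cluster")
    ft <- read.csv(ft_path)
    pca <- fit_pca(ft)
    assign <- kmeans_cluster(pca$scores, k = config$cluster$k,
                             n_restarts = config$cluster$n_restarts,
                             seed = seeds[["cluster"]])
    report <- classify_groups(assign, ft)
    cls <- report$group_class[as.character(assign$labels)]
    write.csv(data.frame(neuron_id = ft$neuron_id, group = assign$labels,
                         class = cls),
              stage_file(outdir, "assignments.csv"), row.names = FALSE)
    write_report_json(report, pca$model,
                      stage_file(outdir, "report.json"),
                      config = unclass(config))
    artifacts <- c(artifacts, "assignments.csv", "report.json")
  }

  manifest <- list(
    package_version = as.character(packageVersion("caltrace")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(config),
    stage_seeds = as.list(seeds),
    stages_run = stages,
    checksums = as.list(tools::md5sum(file.path(outdir, artifacts)) |>
                          stats::setNames(artifacts))
  )
  jsonlite::write_json(manifest, stage_file(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

#' Screen a population of normalized traces
#'
#' Trains the boosting screen on up to `n_labeled_per_class` labelled traces
#' per class (sampled reproducibly from the provided labels, emulating the
#' manual selection of representative traces) and classifies the whole
#' population.
#'
#' @param traces List of [normalized_trace()].
#' @param labels Ground-truth/manual labels (`"active"`/`"inactive"`) used
#'   for the training subset.
#' @param threshold High-activity threshold, % dF/F0 (`NULL` = per-trace
#'   robust default).
#' @param n_rounds Boosting rounds.
#' @param n_labeled_per_class Training examples per class.
#' @param seed Integer seed for the training-subset draw.
#' @return List: `model`, `labels` (predicted), `margins`, `features`.
#' @export
screen_population <- function(traces, labels, threshold = NULL,
                              n_rounds = 50, n_labeled_per_class = 100,
                              seed = 1) {
  feats <- t(vapply(traces, screen_features, numeric(5), threshold = threshold))
  idx_act <- which(labels == "active")
  idx_ina <- which(labels == "inactive")
  pick <- with_seed(seed, c(
    idx_act[sample.int(length(idx_act), min(n_labeled_per_class, length(idx_act)))],
    idx_ina[sample.int(length(idx_ina), min(n_labeled_per_class, length(idx_ina)))]
  ))
  model <- train_screen(feats[pick, , drop = FALSE], labels[pick],
                        n_rounds = n_rounds, seed = seed)
  pred <- classify_screen(model, feats)
  list(model = model, labels = pred$label, margins = pred$margin,
       features = feats)
}
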