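#' Pipeline configuration
#'
#' One document of keys driving the full chain detections -> trajectories ->
#' networks -> measures -> models -> report.  All operating constants are
#' surfaced with their standard defaults: 102 px head-to-head threshold,
#' walktrap at 4 steps, 0.04 mm per pixel.  Configs round-trip losslessly
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param input_dir directory with `detections_<trial>.csv` files and a
#'   `metadata.csv`; `NULL` means simulate instead.
#' @param simulate list of arguments for [simulate_experiment()] (used when
#'   `input_dir` is `NULL`).
#' @param threshold_px head-to-head interaction threshold, pixels.
#' @param head_offset_px tag-centre to head displacement, pixels.
#' @param node_policy `"participants"` or `"all_tagged"`.
#' @param walktrap_steps random-walk length for clustering.
#' @param density_denominator `"nodes"` or `"group_size"`.
#' @param zero_handling gamma zero rule for betweenness models.
#' @param fit_models fit the mixed-model stack (needs enough trials).
#' @param out_dir output directory.
#' @param seed master seed for any simulation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL,
                            simulate = list(n_trials = 4, duration_s = 420),
                            threshold_px = 102, head_offset_px = 0,
                            node_policy = "participants",
                            walktrap_steps = 4,
                            density_denominator = "nodes",
                            zero_handling = "shift",
                            fit_models = FALSE,
                            out_dir = tempfile("trophnet_run_"),
                            seed = 1L) {
  structure(list(input_dir = input_dir, simulate = simulate,
                 threshold_px = threshold_px,
                 head_offset_px = head_offset_px,
                 node_policy = node_policy,
                 walktrap_steps = walktrap_steps,
                 density_denominator = density_denominator,
                 zero_handling = zero_handling,
                 fit_models = fit_models, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) detection tables, builds trajectories and
#' interaction networks, assembles the global and individual measure tables,
#' optionally fits the mixed-model stack with AIC selection for every
#' response, and writes all artefacts plus a manifest with checksums.
#' Identical config and seed give identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly written to
#'   `out_dir/manifest.json`: file paths with MD5 checksums, the config, and
#'   record counts per stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # ---- stage: inputs ------------------------------------------------------
  if (is.null(config$input_dir)) {
    args <- config$simulate
    args$seed <- config$seed
    expt <- do.call(simulate_experiment, args)
    metadata <- expt$metadata
    detections <- lapply(expt$trials, `[[`, "detections")
    names(detections) <- metadata$trial_id
  } else {
    meta_path <- file.path(config$input_dir, "metadata.csv")
    if (!file.exists(meta_path)) {
      troph_error("missing_file",
                  sprintf("[inputs] metadata.csv not found in %s",
                          config$input_dir))
    }
    metadata <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    detections <- lapply(metadata$trial_id, function(id) {
      p <- file.path(config$input_dir, sprintf("detections_%s.csv", id))
      if (!file.exists(p)) {
        troph_error("missing_file", sprintf("[inputs] %s not found", p))
      }
      read_detections(p, trial_id = id)
    })
    names(detections) <- metadata$trial_id
  }
  if (length(detections) == 0) {
    troph_error("no_trials", "[inputs] no trials to process")
  }

  # ---- stage: trajectories, networks --------------------------------------
  trajectories <- lapply(detections, build_trajectories,
                         head_offset_px = config$head_offset_px)
  networks <- list()
  files <- character(0)
  for (id in names(detections)) {
    edges <- detect_interactions(trajectories[[id]],
                                 threshold_px = config$threshold_px)
    roster <- unique(detections[[id]]$ant_id)
    networks[[id]] <- build_network(edges, roster,
                                    policy = config$node_policy,
                                    trial_id = id)
    ep <- file.path(config$out_dir, sprintf("edges_%s.csv", id))
    write_edge_list(edges, id, ep)
    gp <- file.path(config$out_dir, sprintf("network_%s.graphml", id))
    write_network_graphml(networks[[id]], gp)
    files <- c(files, ep, gp)
  }

  # ---- stage: measures ----------------------------------------------------
  measures <- assemble_measures(networks, trajectories, metadata,
                                walktrap_steps = config$walktrap_steps,
                                density_denominator = config$density_denominator)
  gpath <- file.path(config$out_dir, "measures_global.csv")
  ipath <- file.path(config$out_dir, "measures_individual.csv")
  utils::write.csv(measures$global, gpath, row.names = FALSE)
  utils::write.csv(measures$individual, ipath, row.names = FALSE)
  files <- c(files, gpath, ipath)

  # ---- stage: models ------------------------------------------------------
  report <- NULL
  if (isTRUE(config$fit_models)) {
    report <- fit_measure_models(measures,
                                 zero_handling = config$zero_handling)
    rpath <- file.path(config$out_dir, "model_report.json")
    jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    files <- c(files, rpath)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("trophnet")),
    config = unclass(config),
    n_trials = length(detections),
    n_individual_rows = if (is.null(measures$individual)) 0L
                        else nrow(measures$individual),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Fit the mixed-model stack to a measure table
#'
#' For each response -- density and cluster count at the group level, degree
#' and total distance at the individual level (LMM), betweenness at the
#' individual level (gamma log-link GLMM) -- runs AIC selection over the
#' five candidate structures and reports the selected model's coefficients,
#' Type II Wald table, and R-squared components.
#'
#' @param measures a `trial_measures` object from [assemble_measures()].
#' @param zero_handling gamma zero rule for the betweenness model.
#' @return named list (response -> list of `selected`, `aic_table`,
#'   `coefficients`, `wald`, `r2`).
#' @export
fit_measure_models <- function(measures, zero_handling = "shift") {
  stopifnot(inherits(measures, "trial_measures"))
  targets <- list(
    density = list(data = measures$global, level = "group",
                   family = "gaussian"),
    n_clusters = list(data = measures$global, level = "group",
                      family = "gaussian"),
    degree = list(data = measures$individual, level = "individual",
                  family = "gaussian"),
    total_distance_px = list(data = measures$individual,
                             level = "individual", family = "gaussian"),
    betweenness = list(data = measures$individual, level = "individual",
                       family = "gamma_log")
  )
  out <- list()
  for (resp in names(targets)) {
    tg <- targets[[resp]]
    res <- tryCatch({
      specs <- candidate_specs(resp, level = tg$level, family = tg$family)
      sel <- suppressWarnings(
        if (tg$family == "gamma_log") {
          select_model_aic(specs, tg$data, zero_handling = zero_handling)
        } else {
          select_model_aic(specs, tg$data)
        }
      )
      fit <- sel$best_fit
      list(selected = sel$best_name,
           aic_table = sel$table,
           coefficients = fit$coefficients,
           wald = suppressWarnings(wald_type2_anova(fit)),
           r2 = r2_components(fit),
           converged = fit$converged)
    }, error = function(e) list(error = conditionMessage(e)))
    out[[resp]] <- res
  }
  out
}
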