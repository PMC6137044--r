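# Reproducible end-to-end runs: configuration validation, seeded stage
# execution, artifact manifest with content hashes, and plot-ready table
# export. One global seed is expanded into per-stage child seeds by the
# documented counter scheme in child_seed(), so adding a stage never perturbs
# the random streams of earlier stages.

RUN_CONFIG_KEYS <- c("preset", "seed", "outdir", "n_particles", "n_steps",
                     "n_seeds", "noise_sd", "n_frames", "image_shape",
                     "max_shift_px", "boundary")

STAGE_COUNTERS <- c(simulate = 1L, drift = 2L, track = 3L, cpdfit = 4L,
                    eisodist = 5L, frap = 6L)

#' Build and validate a pipeline run configuration
#'
#' @param preset Packaged preset name: `"aptes_yeast"`, `"cona_yeast"`,
#'   `"frap_guv_ld"` (see [sim_preset()]) or `"drift_demo"` (simulated
#'   drifting-cell movie quantified by FFT correlation).
#' @param seed Global integer seed; expanded per stage via [child_seed()].
#' @param outdir Output directory (created if missing).
#' @param ... Stage-parameter overrides. Recognized keys: `n_particles`,
#'   `n_steps` (SPT presets), `n_seeds`, `noise_sd` (FRAP preset),
#'   `n_frames`, `image_shape`, `max_shift_px`, `boundary` (drift preset).
#'   Unknown keys are rejected.
#' @return A validated `run_config` list.
#' @export
run_config <- function(preset, seed = 1L, outdir = tempfile("sptfrap_run_"),
                       ...) {
  extra <- list(...)
  unknown <- setdiff(names(extra), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!preset %in% c("aptes_yeast", "cona_yeast", "frap_guv_ld", "drift_demo")) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  defaults <- list(n_particles = 2500L, n_steps = 2L, n_seeds = 8L,
                   noise_sd = 0.02, n_frames = 20L, image_shape = c(64L, 64L),
                   max_shift_px = 3L, boundary = "periodic")
  cfg <- utils::modifyList(defaults, extra)
  cfg$preset <- preset
  cfg$seed <- as.integer(seed)
  cfg$outdir <- outdir
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Schema: an object with `preset` (required), `seed`, and any of the
#' stage-override keys accepted by [run_config()]. Unknown keys are rejected
#' with their names.
#'
#' @param path JSON config path.
#' @param outdir Optional output-directory override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL) {
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$preset)) stop("config must name a `preset`", call. = FALSE)
  args <- cfg
  args$preset <- NULL
  if (!is.null(outdir)) args$outdir <- outdir
  do.call(run_config, c(list(preset = cfg$preset), args))
}

#' Execute a configured pipeline run
#'
#' Runs the preset's stages in dependency order, writes every artifact plus a
#' resolved copy of the configuration into `outdir`, and returns a manifest
#' of written files with MD5 content hashes. Identical configuration and seed
#' give an identical manifest.
#'
#' @param config A `run_config` from [run_config()].
#' @return A list with `status` (0 on success), `manifest` (data frame
#'   `file`, `md5`) and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  artifact <- function(name) file.path(config$outdir, name)
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  jsonlite::write_json(unclass(config), artifact("resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  note(artifact("resolved_config.json"))

  if (config$preset %in% c("aptes_yeast", "cona_yeast")) {
    preset <- sim_preset(config$preset)
    sim <- simulate_trajectories(
      preset$params, n_particles = config$n_particles,
      n_steps = config$n_steps, dt_s = preset$dt_s,
      seed = child_seed(config$seed, STAGE_COUNTERS[["simulate"]]))
    write_localizations(sim$trajectories, artifact("trajectories.csv"))
    note(artifact("trajectories.csv"))
    gt <- sim$ground_truth; gt$true_positions <- NULL
    write_ground_truth(gt, artifact("ground_truth.json"))
    note(artifact("ground_truth.json"))
    steps <- step_sizes(sim$trajectories, lag_frames = 1L,
                        frame_interval_s = preset$dt_s)
    fit <- fit_cpd_two_population(
      empirical_cpd(steps), n_boot = 200L,
      boot_seed = child_seed(config$seed, STAGE_COUNTERS[["cpdfit"]]))
    jsonlite::write_json(
      list(alpha = fit$alpha_mobile, d_mobile = fit$d_mobile,
           d_immobile = fit$d_immobile,
           se_alpha = fit$se[["alpha_mobile"]],
           se_d_mobile = fit$se[["d_mobile"]],
           se_d_immobile = fit$se[["d_immobile"]],
           n_steps = fit$n_steps, lag_s = fit$lag_s,
           residual_norm = fit$residual_norm),
      artifact("fit.json"), auto_unbox = TRUE, digits = NA)
    note(artifact("fit.json"))
  } else if (config$preset == "frap_guv_ld") {
    preset <- sim_preset("frap_guv_ld")
    sim <- simulate_frap_trace(
      preset$pre_level, preset$bleach_depth, preset$mobile_fraction,
      preset$t_half_s, n_pre = preset$n_pre, n_post = preset$n_post,
      dt_s = preset$dt_s, noise_sd = config$noise_sd * preset$pre_level,
      seed = child_seed(config$seed, STAGE_COUNTERS[["simulate"]]),
      roi_radius_um = preset$roi_radius_um)
    write_frap_trace(sim$trace, artifact("trace.csv"))
    note(artifact("trace.csv")); note(artifact("trace.csv.json"))
    write_ground_truth(sim$ground_truth, artifact("ground_truth.json"))
    note(artifact("ground_truth.json"))
    fit <- fit_recovery(normalize_trace(sim$trace), gamma = preset$gamma)
    jsonlite::write_json(
      list(mobile_fraction = fit$mobile_fraction, t_half_s = fit$t_half_s,
           d_um2_s = fit$d_um2_s, f0 = fit$f0, f_inf = fit$f_inf,
           residual_norm = fit$residual_norm, n_post = fit$n_post),
      artifact("fit.json"), auto_unbox = TRUE, digits = NA)
    note(artifact("fit.json"))
  } else { # drift_demo
    sseed <- child_seed(config$seed, STAGE_COUNTERS[["simulate"]])
    cfg <- sim_config(seed = sseed, n_frames = config$n_frames,
                      image_shape = config$image_shape, noise_sd = 5)
    shifts <- with_seed(sseed + 1L, matrix(
      sample(-config$max_shift_px:config$max_shift_px,
             2L * (config$n_frames - 1L), replace = TRUE),
      ncol = 2))
    sim <- simulate_drifting_cells(cfg, shifts, boundary = config$boundary)
    write_stack(sim$stack, artifact("stack.tif"))
    note(artifact("stack.tif"))
    write_ground_truth(sim$ground_truth, artifact("ground_truth.json"))
    note(artifact("ground_truth.json"))
    trace <- quantify_movement(sim$stack)
    utils::write.csv(trace$trace, artifact("movement.csv"), row.names = FALSE)
    note(artifact("movement.csv"))
  }

  manifest <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    stringsAsFactors = FALSE)
  list(status = 0L, manifest = manifest, outdir = config$outdir)
}

#' Export plot-ready panel tables from a pipeline run
#'
#' Writes one tidy CSV per panel type found among the run's artifacts:
#' per-frame-pair movement (`table_movement.csv`), CPD points with the fitted
#' curve evaluated from the stored parameters (`table_cpd.csv`), and the
#' normalized FRAP trace with its fit (`table_frap.csv`).
#'
#' @param run A result list from [run_pipeline()], or an output directory.
#' @return Character vector of written table paths.
#' @export
export_figure_tables <- function(run) {
  outdir <- if (is.character(run)) run else run$outdir
  cfg_path <- file.path(outdir, "resolved_config.json")
  if (!file.exists(cfg_path)) {
    stop("no resolved_config.json in ", outdir,
         ": run run_pipeline() first", call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(cfg_path)
  written <- character(0)
  if (cfg$preset == "drift_demo") {
    src <- file.path(outdir, "movement.csv")
    if (!file.exists(src)) stop("missing movement.csv: run the drift stage",
                                call. = FALSE)
    mv <- utils::read.csv(src)
    out <- file.path(outdir, "table_movement.csv")
    utils::write.csv(mv, out, row.names = FALSE)
    written <- c(written, out)
  } else if (cfg$preset %in% c("aptes_yeast", "cona_yeast")) {
    fit_path <- file.path(outdir, "fit.json")
    trajs_path <- file.path(outdir, "trajectories.csv")
    if (!file.exists(fit_path) || !file.exists(trajs_path)) {
      stop("missing fit.json/trajectories.csv: run the cpdfit stage",
           call. = FALSE)
    }
    fit <- jsonlite::fromJSON(fit_path)
    preset <- sim_preset(cfg$preset)
    trajs <- read_localizations(trajs_path)
    cpd <- empirical_cpd(step_sizes(trajs, 1L, preset$dt_s))
    cpd$p_fit <- cpd_model(cpd$r2_um2, fit$lag_s, fit$alpha, fit$d_mobile,
                           fit$d_immobile)
    out <- file.path(outdir, "table_cpd.csv")
    utils::write.csv(cpd, out, row.names = FALSE)
    written <- c(written, out)
  } else {
    trace_path <- file.path(outdir, "trace.csv")
    fit_path <- file.path(outdir, "fit.json")
    if (!file.exists(trace_path) || !file.exists(fit_path)) {
      stop("missing trace.csv/fit.json: run the frap stage", call. = FALSE)
    }
    trace <- normalize_trace(read_frap_trace(trace_path))
    fit <- jsonlite::fromJSON(fit_path)
    tab <- data.frame(time_s = trace$time_s, intensity = trace$intensity)
    tab$fit <- ifelse(
      tab$time_s < 0, 1,
      fit$f0 + (fit$f_inf - fit$f0) *
        (1 - exp(-log(2) * pmax(tab$time_s, 0) / fit$t_half_s)))
    out <- file.path(outdir, "table_frap.csv")
    utils::write.csv(tab, out, row.names = FALSE)
    written <- c(written, out)
  }
  written
}
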