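#' Read and write end trajectories
#'
#' Trace CSVs carry physical units only: columns `time_s` and `position_nm`
#' (header required, comma-separated, UTF-8). Calibration travels in an
#' optional JSON sidecar (`<path>.json`) with fields `pixel_size` and
#' `frame_interval`.
#'
#' @param path CSV file path.
#' @return An [end_trajectory()].
#' @export
read_trace <- function(path) {
  df <- read_checked(path, c("time_s", "position_nm"))
  cal <- read_sidecar(path)
  end_trajectory(df$time_s, df$position_nm,
                 pixel_size = cal$pixel_size %||% 160,
                 frame_interval = cal$frame_interval %||% 5)
}

#' @rdname read_trace
#' @param trajectory an [end_trajectory()].
#' @export
write_trace <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "end_trajectory"))
  utils::write.csv(data.frame(time_s = trajectory$times,
                              position_nm = trajectory$positions),
                   path, row.names = FALSE)
  write_sidecar(path, list(pixel_size = trajectory$pixel_size,
                           frame_interval = trajectory$frame_interval))
  invisible(path)
}

#' Read and write single-molecule event tables
#'
#' Event CSVs have columns `position_um`, `t_on`, `t_off` and optionally
#' `censored` (logical), `labeled` (logical), `condition` (character).
#'
#' @param path CSV file path.
#' @return data.frame of class `binding_events`.
#' @export
read_events <- function(path) {
  df <- read_checked(path, c("position_um", "t_on", "t_off"))
  if (!"censored" %in% names(df)) df$censored <- FALSE
  if (any(df$t_off <= df$t_on))
    stop("read_events: every event needs t_off > t_on (column t_off)")
  class(df) <- c("binding_events", "data.frame")
  df
}

#' @rdname read_events
#' @param events a `binding_events` data.frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Read and write per-condition nucleation counts
#'
#' Counts CSVs have columns `x_uM`, `seeds_total`, `seeds_nucleated`;
#' `fraction` and `error` are recomputed on read.
#'
#' @param path CSV file path.
#' @param error_rule passed to [fraction_error()].
#' @return data.frame ready for [fit_sigmoid()].
#' @export
read_counts <- function(path, error_rule = "sqrt") {
  df <- read_checked(path, c("x_uM", "seeds_total", "seeds_nucleated"))
  if (any(df$seeds_nucleated > df$seeds_total))
    stop("read_counts: seeds_nucleated exceeds seeds_total (column seeds_nucleated)")
  df$fraction <- df$seeds_nucleated / df$seeds_total
  df$error <- mapply(fraction_error, df$seeds_nucleated, df$seeds_total,
                     MoreArgs = list(rule = error_rule))
  df
}

#' @rdname read_counts
#' @param counts the counts data.frame.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts[, c("x_uM", "seeds_total", "seeds_nucleated")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read and write kymographs as multi-page TIFF
#'
#' One TIFF page per channel, float intensities rescaled to `[0, 1]` on
#' write; channel names, per-channel scale factors, and calibration are
#' stored in a JSON sidecar (`<path>.json`) and restored on read.
#'
#' @param kymo a [kymograph()].
#' @param path TIFF file path.
#' @return `read_kymograph()` returns a [kymograph()].
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  scales <- vapply(kymo$channels, function(m) max(m, 1e-12), numeric(1L))
  pages <- mapply(function(m, s) m / s, kymo$channels, scales,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(channels = names(kymo$channels),
                           scales = as.list(scales),
                           pixel_size = kymo$pixel_size,
                           frame_interval = kymo$frame_interval))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- read_sidecar(path)
  if (is.null(meta$channels) || length(meta$channels) != length(pages))
    stop("read_kymograph: sidecar metadata missing or inconsistent")
  channels <- mapply(function(m, s) m * s, pages,
                     as.numeric(unlist(meta$scales)), SIMPLIFY = FALSE)
  names(channels) <- unlist(meta$channels)
  kymograph(channels, pixel_size = meta$pixel_size,
            frame_interval = meta$frame_interval)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema mismatch in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

read_sidecar <- function(path) {
  side <- paste0(path, ".json")
  if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a YAML run configuration
#'
#' Loads stage parameters, file paths, seed and output directory from YAML,
#' filling documented defaults for anything omitted.
#'
#' @param path YAML file, or a list to validate.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(stages = c("simgen", "dynamics", "nucleation", "singlemol"),
                   rng_seed = 1L, out_dir = "mtkymo_out",
                   sim = list(), duration = 600, n_trajectories = 50,
                   min_event_displacement = 480,
                   window = 120, shrink_threshold = -2.5,
                   nucleation = list(C = 5.9, s = 6, seeds_per_condition = 50,
                                     concentrations = seq(3, 10)),
                   binding = list(mt_length = 20, duration = 600))
  cfg <- utils::modifyList(defaults, cfg)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline on synthetic data
#'
#' Executes the requested stages end-to-end — trajectory simulation plus
#' dynamics extraction, nucleation generation plus sigmoid fit, binding
#' simulation plus dwell/association statistics — writing each stage's
#' outputs (CSV/JSON) and a machine-readable provenance record (config
#' hash, seed, package and R versions) into the output directory. With a
#' fixed seed the run is deterministic: identical configs produce identical
#' output files.
#'
#' @param config a `run_config` from [read_run_config()], a YAML path, or a
#'   list.
#' @return Invisibly, a named list of stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  known <- c("simgen", "dynamics", "nucleation", "singlemol")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("run_pipeline: unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(sim_config, utils::modifyList(cfg$sim,
                                               list(rng_seed = cfg$rng_seed)))
  results <- list()
  if (any(c("simgen", "dynamics") %in% cfg$stages)) {
    trajs <- simulate_dynamic_instability(sim, duration = cfg$duration,
                                          n = cfg$n_trajectories)
    for (i in seq_along(trajs))
      write_trace(trajs[[i]],
                  file.path(cfg$out_dir, sprintf("trace_%03d.csv", i)))
    results$trajectories <- length(trajs)
    if ("dynamics" %in% cfg$stages) {
      ann <- lapply(trajs, segment_phases,
                    min_event_displacement = cfg$min_event_displacement)
      dyn <- compute_dynamics(ann, pixel_size = sim$pixel_size)
      jsonlite::write_json(
        list(growth_rate = dyn$growth_rate, shrink_rate = dyn$shrink_rate,
             catastrophe_freq = dyn$catastrophe_freq,
             rescue_per_length = dyn$rescue_per_length,
             dynamicity = dyn$dynamicity, totals = dyn$totals),
        file.path(cfg$out_dir, "dynamics_summary.json"),
        auto_unbox = TRUE, digits = NA)
      results$dynamics <- dyn
    }
  }
  if ("nucleation" %in% cfg$stages) {
    nuc <- cfg$nucleation
    counts <- generate_nucleation_counts(nuc$C, nuc$s, nuc$concentrations,
                                         nuc$seeds_per_condition,
                                         rng_seed = cfg$rng_seed)
    write_counts(counts, file.path(cfg$out_dir, "nucleation_counts.csv"))
    fit <- fit_sigmoid(counts)
    jsonlite::write_json(list(C = fit$C, C_ci = fit$C_ci,
                              s = fit$s, s_ci = fit$s_ci,
                              residual_sd = fit$residual_sd),
                         file.path(cfg$out_dir, "nucleation_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    results$nucleation <- fit
  }
  if ("singlemol" %in% cfg$stages) {
    ev <- simulate_binding(sim, mt_length = cfg$binding$mt_length,
                           duration = cfg$binding$duration)
    write_events(ev, file.path(cfg$out_dir, "events.csv"))
    dw <- dwell_times(ev)
    ar <- association_rate(nrow(ev), cfg$binding$duration,
                           cfg$binding$mt_length, sim$conc)
    jsonlite::write_json(list(dwell_mean_s = dw$mean, dwell_se_s = dw$se,
                              n_events = dw$n,
                              association_rate = ar[["rate"]],
                              association_rate_se = ar[["se"]]),
                         file.path(cfg$out_dir, "singlemol_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    results$singlemol <- list(dwell = dw, association = ar)
  }
  cfg_path <- file.path(cfg$out_dir, "run_config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               rng_seed = cfg$rng_seed,
               package_version = as.character(utils::packageVersion("mtkymo")),
               r_version = R.version.string,
               timestamp = NULL)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
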