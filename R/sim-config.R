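#' Simulation configuration
#'
#' Bundles every generative parameter used by the stochastic simulators and
#' the kymograph renderer. Defaults correspond to the dynamic-microtubule
#' regime quantified in this package's validation suite: a plus end growing
#' at 7.6 nm/s with 100 nm/s shrinkage, catastrophe at 0.004 s^-1 and rescue
#' at 0.02 s^-1, imaged at 160 nm/pixel every 5 s; lattice binding at an
#' association rate of 1e-3 events um^-1 nM^-1 s^-1 and a mean residence of
#' 12 s (k_off = 1/12 s^-1).
#'
#' @param v_g growth speed (nm/s), > 0.
#' @param v_s shrinkage speed magnitude (nm/s), > 0.
#' @param f_c catastrophe rate (s^-1), >= 0.
#' @param f_r rescue rate (s^-1), >= 0.
#' @param k_on association rate (events um^-1 nM^-1 s^-1), >= 0.
#' @param k_off dissociation rate (s^-1), > 0.
#' @param conc probe concentration (nM), >= 0.
#' @param coop_on,coop_off dimensionless neighbor-cooperativity multipliers
#'   (>= 0). `coop_on` scales the association rate with the local occupied
#'   fraction within +/-2 lattice sites; `coop_off` divides the dissociation
#'   rate by `1 + coop_off * n_occupied_nearest_neighbors`. Zero for both
#'   recovers independent binding.
#' @param label_frac fraction of molecules carrying a fluorophore, in `[0,1]`.
#' @param pixel_size image calibration (nm per pixel), > 0.
#' @param frame_interval time between frames (s), > 0.
#' @param noise_sd additive Gaussian image noise (a.u.), >= 0.
#' @param psf_sigma Gaussian point-spread sigma (pixels), >= 0.
#' @param rng_seed integer seed; every simulator call derives its random
#'   stream from this value only (no global RNG state is consumed).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(v_g = 7.6, v_s = 100, f_c = 0.004, f_r = 0.02,
                       k_on = 1e-3, k_off = 1 / 12, conc = 5,
                       coop_on = 0, coop_off = 0, label_frac = 1,
                       pixel_size = 160, frame_interval = 5,
                       noise_sd = 0, psf_sigma = 1, rng_seed = 1L) {
  cfg <- list(v_g = v_g, v_s = v_s, f_c = f_c, f_r = f_r,
              k_on = k_on, k_off = k_off, conc = conc,
              coop_on = coop_on, coop_off = coop_off,
              label_frac = label_frac,
              pixel_size = pixel_size, frame_interval = frame_interval,
              noise_sd = noise_sd, psf_sigma = psf_sigma,
              rng_seed = as.integer(rng_seed))
  vals <- unlist(cfg)
  if (any(!is.finite(vals)))
    stop("sim_config: all parameters must be finite, got non-finite: ",
         paste(names(cfg)[!is.finite(vals)], collapse = ", "))
  chk <- function(ok, msg) if (!ok) stop("sim_config: ", msg, call. = FALSE)
  chk(v_g > 0, "v_g must be > 0")
  chk(v_s > 0, "v_s must be > 0")
  chk(f_c >= 0, "f_c must be >= 0")
  chk(f_r >= 0, "f_r must be >= 0")
  chk(k_on >= 0, "k_on must be >= 0")
  chk(k_off > 0, "k_off must be > 0")
  chk(conc >= 0, "conc must be >= 0")
  chk(coop_on >= 0, "coop_on must be >= 0 (negative cooperativity multipliers are rejected)")
  chk(coop_off >= 0, "coop_off must be >= 0 (negative cooperativity multipliers are rejected)")
  chk(label_frac >= 0 && label_frac <= 1, "label_frac must be in [0, 1]")
  chk(pixel_size > 0, "pixel_size must be > 0")
  chk(frame_interval > 0, "frame_interval must be > 0")
  chk(noise_sd >= 0, "noise_sd must be >= 0")
  chk(psf_sigma >= 0, "psf_sigma must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  dynamics: v_g=%.3g nm/s, v_s=%.3g nm/s, f_c=%.3g /s, f_r=%.3g /s\n",
              x$v_g, x$v_s, x$f_c, x$f_r))
  cat(sprintf("  binding:  k_on=%.3g /um/nM/s, k_off=%.3g /s, conc=%.3g nM, coop=(%.3g, %.3g), labeled=%.0f%%\n",
              x$k_on, x$k_off, x$conc, x$coop_on, x$coop_off, 100 * x$label_frac))
  cat(sprintf("  optics:   %g nm/px, %g s/frame, noise_sd=%g, psf_sigma=%g px, seed=%d\n",
              x$pixel_size, x$frame_interval, x$noise_sd, x$psf_sigma, x$rng_seed))
  invisible(x)
}

#' Microtubule end trajectory
#'
#' A sampled end-position-versus-time trace with pixel/frame calibration and,
#' for simulated data, the noiseless ground-truth phase intervals.
#'
#' @param times sample times (s), strictly increasing.
#' @param positions end positions (nm) relative to the seed boundary.
#' @param truth_phases optional data.frame with columns `t_start`, `t_end`,
#'   `phase` (`"growth"` or `"shrink"`) tiling the observation interval.
#' @param pixel_size,frame_interval calibration (nm per pixel, s per frame).
#'
#' @return Object of class `end_trajectory`.
#' @export
end_trajectory <- function(times, positions, truth_phases = NULL,
                           pixel_size = 160, frame_interval = 5) {
  times <- as.numeric(times); positions <- as.numeric(positions)
  if (length(times) != length(positions))
    stop("end_trajectory: times and positions must have equal length")
  if (any(diff(times) <= 0))
    stop("end_trajectory: times must be strictly increasing")
  if (!is.null(truth_phases)) {
    stopifnot(is.data.frame(truth_phases),
              all(c("t_start", "t_end", "phase") %in% names(truth_phases)))
    if (nrow(truth_phases) > 1L &&
        any(abs(truth_phases$t_start[-1L] -
                truth_phases$t_end[-nrow(truth_phases)]) > 1e-9))
      stop("end_trajectory: truth_phases must tile the interval without gaps or overlap")
  }
  structure(list(times = times, positions = positions,
                 truth_phases = truth_phases,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "end_trajectory")
}

#' @export
print.end_trajectory <- function(x, ...) {
  cat(sprintf("<end_trajectory> %d samples over %.1f s, final position %.0f nm%s\n",
              length(x$times), diff(range(x$times)), x$positions[length(x$positions)],
              if (is.null(x$truth_phases)) "" else
                sprintf(", %d truth phases", nrow(x$truth_phases))))
  invisible(x)
}

#' Two-channel kymograph
#'
#' Space-time intensity arrays (rows = frames, columns = pixels along the
#' microtubule), one matrix per named channel, sharing one calibration.
#'
#' @param channels named list of numeric matrices of identical dimension;
#'   names are channel roles such as `"lattice"`, `"probe"`, `"seed"`.
#' @param pixel_size,frame_interval calibration.
#' @return Object of class `kymograph`.
#' @export
kymograph <- function(channels, pixel_size = 160, frame_interval = 5) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("kymograph: all channels must share one shape")
  if (any(vapply(channels, function(m) any(m < 0), logical(1L))))
    stop("kymograph: intensities must be >= 0")
  structure(list(channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<kymograph> %d frames x %d px (%g nm/px, %g s/frame), channels: %s\n",
              d[1L], d[2L], x$pixel_size, x$frame_interval,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}
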