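#' Simulate two-state dynamic-instability end trajectories
#'
#' Generates piecewise-linear end trajectories from the classic two-state
#' model of dynamic instability: a growth phase advancing at `v_g` switches
#' to shrinkage (at `v_s`) after an exponential waiting time with rate `f_c`
#' (catastrophe); shrinkage switches back to growth with rate `f_r` (rescue).
#' A shrinking end reaching the seed boundary (position 0) is truncated
#' there and re-enters growth; such forced transitions are not rescues.
#'
#' Positions are sampled on the frame grid `seq(0, duration, frame_interval)`
#' by linear interpolation of the exact vertex path; optional Gaussian
#' tracking noise is added to the sampled positions only. The ground-truth
#' phase intervals are always recorded noiselessly in `truth_phases`.
#'
#' @param config a [sim_config()].
#' @param duration observation time (s), > 0.
#' @param n number of trajectories, >= 1.
#' @param pos_noise_sd Gaussian position noise on sampled positions (nm).
#' @param seed_boundary if `TRUE` (default) position is absorbed/reflected at
#'   0 (the seed); if `FALSE` shrinkage may run to negative positions.
#'
#' @return List of [end_trajectory()] objects.
#' @export
simulate_dynamic_instability <- function(config, duration, n = 1L,
                                         pos_noise_sd = 0,
                                         seed_boundary = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (n < 1L) stop("n must be >= 1")
  if (pos_noise_sd < 0) stop("pos_noise_sd must be >= 0")
  withr::with_seed(config$rng_seed,
    lapply(seq_len(n), function(i)
      di_one(config, duration, pos_noise_sd, seed_boundary)))
}

rexp_or_inf <- function(rate) if (rate <= 0) Inf else stats::rexp(1L, rate)

di_one <- function(cfg, duration, pos_noise_sd, seed_boundary) {
  t <- 0; pos <- 0; phase <- "growth"
  vt <- 0; vp <- 0
  ps <- pe <- xs <- xe <- numeric(0); lab <- character(0)
  while (t < duration - 1e-12) {
    if (phase == "growth") {
      w <- rexp_or_inf(cfg$f_c)
      t_end <- min(t + w, duration)
      pos_end <- pos + cfg$v_g * (t_end - t)
      nxt <- "shrink"
    } else {
      w <- rexp_or_inf(cfg$f_r)
      t_seed <- if (seed_boundary) pos / cfg$v_s else Inf
      t_end <- min(t + min(w, t_seed), duration)
      pos_end <- pos - cfg$v_s * (t_end - t)
      if (seed_boundary && t_seed <= w && t + t_seed <= duration) pos_end <- 0
      nxt <- "growth"
    }
    ps <- c(ps, t); pe <- c(pe, t_end); lab <- c(lab, phase)
    xs <- c(xs, pos); xe <- c(xe, pos_end)
    vt <- c(vt, t_end); vp <- c(vp, pos_end)
    t <- t_end; pos <- pos_end; phase <- nxt
  }
  times <- seq(0, duration, by = cfg$frame_interval)
  positions <- stats::approx(vt, vp, xout = times, rule = 2)$y
  if (pos_noise_sd > 0) {
    positions <- positions + stats::rnorm(length(positions), 0, pos_noise_sd)
    if (seed_boundary) positions <- pmax(positions, 0)
  }
  end_trajectory(times, positions,
                 truth_phases = data.frame(t_start = ps, t_end = pe,
                                           phase = lab,
                                           pos_start = xs, pos_end = xe,
                                           stringsAsFactors = FALSE),
                 pixel_size = cfg$pixel_size,
                 frame_interval = cfg$frame_interval)
}

#' Simulate single-molecule lattice binding with optional cooperativity
#'
#' Continuous-time (Gillespie) simulation of probe molecules on a 1-D lattice
#' of 8 nm sites along a microtubule. Each empty site gains occupants at rate
#' `k_on * conc * site_length * (1 + coop_on * rho_local)`, where `rho_local`
#' is the occupied fraction within +/-2 sites; each bound molecule leaves at
#' rate `k_off / (1 + coop_off * n_occupied_nearest_neighbors)`. With both
#' cooperativity multipliers at zero, residences are i.i.d. exponential with
#' mean `1/k_off` (independent binding). Molecules still bound when the
#' observation ends are emitted with `censored = TRUE` and `t_off` at the
#' observation boundary.
#'
#' @param config a [sim_config()]; uses `k_on`, `k_off`, `conc`, `coop_on`,
#'   `coop_off`, `label_frac`, `rng_seed`.
#' @param mt_length microtubule length (um), > 0.
#' @param duration observation time (s), > 0.
#' @param site_nm lattice site length (nm); default 8 (one tubulin dimer).
#'
#' @return data.frame of class `binding_events` with columns `position_um`,
#'   `t_on`, `t_off`, `censored`, `labeled`.
#' @export
simulate_binding <- function(config, mt_length, duration, site_nm = 8) {
  stopifnot(inherits(config, "sim_config"))
  if (mt_length <= 0) stop("mt_length must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  n_sites <- max(1L, as.integer(round(mt_length * 1000 / site_nm)))
  site_um <- site_nm / 1000
  withr::with_seed(config$rng_seed,
                   gillespie_binding(config, n_sites, site_um, duration))
}

gillespie_binding <- function(cfg, n_sites, site_um, duration) {
  base_on <- cfg$k_on * cfg$conc * site_um
  occ <- logical(n_sites)
  t_on_site <- numeric(n_sites)
  idx <- seq_len(n_sites)
  lo <- pmax(idx - 2L, 1L); hi <- pmin(idx + 2L, n_sites)
  nbr_n <- hi - lo  # neighborhood size excluding the site itself
  cap <- 1024L; m <- 0L
  ev_pos <- ev_on <- ev_off <- numeric(cap)
  grow <- function() {
    cap <<- cap * 2L
    length(ev_pos) <<- cap; length(ev_on) <<- cap; length(ev_off) <<- cap
  }
  t <- 0
  repeat {
    occn <- as.numeric(occ)
    cs <- cumsum(c(0, occn))
    rho <- (cs[hi + 1L] - cs[lo] - occn) / pmax(nbr_n, 1L)
    r_on <- base_on * (1 + cfg$coop_on * rho)
    r_on[occ] <- 0
    nn <- c(0, occn[-n_sites]) + c(occn[-1L], 0)
    r_off <- cfg$k_off / (1 + cfg$coop_off * nn)
    r_off[!occ] <- 0
    total <- sum(r_on) + sum(r_off)
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t >= duration) break
    j <- sample.int(2L * n_sites, 1L, prob = c(r_on, r_off))
    if (j <= n_sites) {
      occ[j] <- TRUE; t_on_site[j] <- t
    } else {
      i <- j - n_sites
      occ[i] <- FALSE
      m <- m + 1L; if (m > cap) grow()
      ev_pos[m] <- (i - 0.5) * site_um
      ev_on[m] <- t_on_site[i]; ev_off[m] <- t
    }
  }
  m_complete <- m
  for (i in which(occ)) {   # still bound at movie end: censored
    m <- m + 1L; if (m > cap) grow()
    ev_pos[m] <- (i - 0.5) * site_um
    ev_on[m] <- t_on_site[i]; ev_off[m] <- duration
  }
  cens <- c(rep(FALSE, m_complete), rep(TRUE, m - m_complete))
  labeled <- if (m > 0L) stats::runif(m) < cfg$label_frac else logical(0)
  out <- data.frame(position_um = ev_pos[seq_len(m)],
                    t_on = ev_on[seq_len(m)], t_off = ev_off[seq_len(m)],
                    censored = cens, labeled = labeled)
  out <- out[order(out$t_on), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_events", "data.frame")
  out
}

#' Site-occupancy matrix from binding events
#'
#' Reconstructs the lattice occupancy at each requested time from an event
#' table: a site is occupied at time `t` by an event with `t_on <= t < t_off`.
#'
#' @param events a `binding_events` data.frame (see [simulate_binding()]).
#' @param mt_length microtubule length (um).
#' @param times times at which to evaluate occupancy (s).
#' @param site_nm lattice site length (nm).
#' @param labeled_only if `TRUE`, only fluorescently labeled molecules count.
#' @return 0/1 matrix `length(times) x n_sites` with attribute `times`.
#' @export
occupancy_matrix <- function(events, mt_length, times, site_nm = 8,
                             labeled_only = FALSE) {
  n_sites <- max(1L, as.integer(round(mt_length * 1000 / site_nm)))
  occ <- matrix(0, nrow = length(times), ncol = n_sites)
  ev <- if (labeled_only) events[events$labeled, , drop = FALSE] else events
  if (nrow(ev) > 0L) {
    site <- pmin(pmax(as.integer(ceiling(ev$position_um * 1000 / site_nm)), 1L),
                 n_sites)
    for (k in seq_len(nrow(ev))) {
      f <- which(times >= ev$t_on[k] & times < ev$t_off[k])
      if (length(f)) occ[f, site[k]] <- 1
    }
  }
  attr(occ, "times") <- times
  occ
}

# Gaussian blur along each row (the spatial axis), edge-renormalized so a
# constant row stays constant; sigma in pixels.
blur_rows <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- ncol(mat)
  convrow <- function(row) {
    padded <- c(rep(0, half), row, rep(0, half))
    vapply(seq_len(n), function(j) sum(padded[j:(j + 2L * half)] * k),
           numeric(1L))
  }
  wnorm <- convrow(rep(1, n))
  out <- t(apply(mat, 1L, convrow))
  sweep(out, 2L, wnorm, "/")
}

#' Render a two-channel kymograph from a trajectory and lattice occupancy
#'
#' Builds the `lattice` channel as the indicator of polymer extent (pixels
#' between the seed boundary and the instantaneous end position) and the
#' `probe` channel as the labeled site-occupancy binned to pixels, both
#' convolved row-wise with a Gaussian point-spread function, scaled, and
#' corrupted with additive Gaussian noise (clamped at zero). Calibration is
#' propagated from the trajectory.
#'
#' @param trajectory an [end_trajectory()].
#' @param occupancy optional occupancy matrix from [occupancy_matrix()] whose
#'   `times` attribute must equal `trajectory$times`; `NULL` renders a probe
#'   channel of zeros.
#' @param config a [sim_config()]; uses `psf_sigma`, `noise_sd`, `rng_seed`.
#' @param width_px image width in pixels; default fits the trajectory plus
#'   `margin_px`.
#' @param margin_px solution-side margin beyond the maximal end position.
#' @param lattice_scale,probe_scale intensity of, respectively, a fully
#'   polymerized pixel and a fully (labeled-)occupied pixel, in a.u.
#' @return A [kymograph()] with channels `lattice` and `probe`.
#' @export
render_kymograph <- function(trajectory, occupancy = NULL, config,
                             width_px = NULL, margin_px = 10L,
                             lattice_scale = 100, probe_scale = 100) {
  stopifnot(inherits(trajectory, "end_trajectory"),
            inherits(config, "sim_config"))
  times <- trajectory$times
  if (!is.null(occupancy)) {
    ot <- attr(occupancy, "times")
    if (is.null(ot) || length(ot) != length(times) ||
        any(abs(ot - times) > 1e-9))
      stop("render_kymograph: occupancy and trajectory cover different time spans")
  }
  ps <- trajectory$pixel_size
  n_frames <- length(times)
  if (is.null(width_px))
    width_px <- as.integer(ceiling(max(trajectory$positions, 0) / ps)) + margin_px
  centers <- (seq_len(width_px) - 0.5) * ps
  lattice <- outer(trajectory$positions, centers, function(p, c) as.numeric(c <= p))
  probe <- matrix(0, n_frames, width_px)
  if (!is.null(occupancy)) {
    n_sites <- ncol(occupancy)
    site_px <- pmin(pmax(as.integer(ceiling(((seq_len(n_sites) - 0.5) * 8) / ps)),
                         1L), width_px)
    for (j in seq_len(width_px)) {
      cols <- which(site_px == j)
      if (length(cols))
        probe[, j] <- rowMeans(occupancy[, cols, drop = FALSE])
    }
  }
  lattice <- blur_rows(lattice, config$psf_sigma) * lattice_scale
  probe <- blur_rows(probe, config$psf_sigma) * probe_scale
  if (config$noise_sd > 0) {
    withr::with_seed(config$rng_seed, {
      lattice <- lattice + stats::rnorm(length(lattice), 0, config$noise_sd)
      probe <- probe + stats::rnorm(length(probe), 0, config$noise_sd)
    })
    lattice <- pmax(lattice, 0); probe <- pmax(probe, 0)
  }
  kymograph(list(lattice = lattice, probe = probe),
            pixel_size = ps, frame_interval = trajectory$frame_interval)
}

#' Generate binomial templated-nucleation counts from a sigmoid truth
#'
#' For each tubulin concentration `x`, the number of seeds nucleating within
#' the observation window is drawn as
#' `Binomial(seeds_per_condition, x^s / (C^s + x^s))`, the Hill-type sigmoid
#' used for the concentration dependence of templated nucleation.
#'
#' @param C half-maximal concentration (uM), > 0.
#' @param s steepness (dimensionless), > 0.
#' @param concentrations tubulin concentrations (uM), >= 0.
#' @param seeds_per_condition seeds observed per condition.
#' @param rng_seed integer seed.
#' @param noiseless if `TRUE`, return expected fractions instead of draws
#'   (counts are rounded expected counts).
#' @return data.frame with columns `x_uM`, `seeds_total`, `seeds_nucleated`,
#'   `fraction`, `error` (error per [fraction_error()]).
#' @export
generate_nucleation_counts <- function(C, s, concentrations,
                                       seeds_per_condition = 50L,
                                       rng_seed = 1L, noiseless = FALSE) {
  if (C <= 0 || s <= 0) stop("C and s must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  p <- ifelse(concentrations == 0, 0,
              concentrations^s / (C^s + concentrations^s))
  n <- as.integer(seeds_per_condition)
  N <- if (noiseless) round(p * n) else
    withr::with_seed(rng_seed, stats::rbinom(length(p), n, p))
  frac <- if (noiseless) p else N / n
  data.frame(x_uM = concentrations, seeds_total = n, seeds_nucleated = N,
             fraction = frac,
             error = vapply(N, fraction_error, numeric(1L), total = n))
}

#' Simulate severing-protection intensity timecourses
#'
#' Emulates a field of stabilized microtubules imaged during a severing
#' reaction: every microtubule starts at unit lattice intensity; severing
#' events arrive as a Poisson process and each removes a fixed fraction of
#' the remaining polymer (stepwise intensity loss). Probe-coated
#' microtubules are severed at `coated_rate` (0 = full protection),
#' uncoated controls at `sever_rate`. Per-frame measurement noise yields a
#' per-microtubule standard error.
#'
#' @param n_fields number of fields of view.
#' @param n_control,n_coated microtubules per population per field.
#' @param duration movie length (s).
#' @param frame_interval s between frames (default 15 as in timed severing
#'   assays).
#' @param sever_rate control severing-event rate (s^-1 per microtubule).
#' @param coated_rate coated severing-event rate (s^-1 per microtubule).
#' @param step_frac fraction of remaining intensity lost per severing event.
#' @param meas_noise per-frame Gaussian measurement noise (fraction of
#'   initial intensity).
#' @param rng_seed integer seed.
#' @return data.frame with columns `mt_id`, `field`, `coated`, `time_s`,
#'   `intensity`, `se` suitable for [severing_timecourse()].
#' @export
simulate_severing <- function(n_fields = 3L, n_control = 10L, n_coated = 10L,
                              duration = 600, frame_interval = 15,
                              sever_rate = 0.015, coated_rate = 0,
                              step_frac = 0.25, meas_noise = 0.02,
                              rng_seed = 1L) {
  stopifnot(n_fields >= 1L, n_control >= 1L, n_coated >= 1L,
            duration > 0, frame_interval > 0, sever_rate >= 0,
            coated_rate >= 0, step_frac > 0, step_frac < 1)
  times <- seq(0, duration, by = frame_interval)
  withr::with_seed(rng_seed, {
    rows <- list(); id <- 0L
    for (f in seq_len(n_fields)) {
      for (coated in c(FALSE, TRUE)) {
        rate <- if (coated) coated_rate else sever_rate
        n_mt <- if (coated) n_coated else n_control
        for (k in seq_len(n_mt)) {
          id <- id + 1L
          n_ev <- stats::rpois(1L, rate * duration)
          ev_t <- sort(stats::runif(n_ev, 0, duration))
          truth <- (1 - step_frac)^findInterval(times, ev_t)
          obs <- truth + stats::rnorm(length(times), 0, meas_noise)
          rows[[id]] <- data.frame(
            mt_id = id, field = f, coated = coated, time_s = times,
            intensity = obs, se = meas_noise)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
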