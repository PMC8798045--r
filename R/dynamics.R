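#' Phase annotation of an end trajectory
#'
#' Ordered vertices marking growth/shrink phase boundaries, as one would
#' mark them on a kymograph. Between consecutive vertices the end is in one
#' phase; growth segments must have non-negative displacement and shrink
#' segments non-positive.
#'
#' @param vertices data.frame with columns `time` (s, strictly increasing)
#'   and `position` (nm).
#' @param phases character vector of length `nrow(vertices) - 1`, each
#'   `"growth"` or `"shrink"`.
#' @param n_marks number of marked points (defaults to the vertex count);
#'   enters the dynamicity error as N.
#' @return Object of class `phase_annotation`.
#' @export
phase_annotation <- function(vertices, phases, n_marks = nrow(vertices)) {
  stopifnot(is.data.frame(vertices),
            all(c("time", "position") %in% names(vertices)))
  if (nrow(vertices) < 2L) stop("phase_annotation: need >= 2 vertices")
  if (any(diff(vertices$time) <= 0))
    stop("phase_annotation: vertex times must be strictly increasing")
  if (length(phases) != nrow(vertices) - 1L)
    stop("phase_annotation: need one phase label per segment")
  if (!all(phases %in% c("growth", "shrink")))
    stop("phase_annotation: phases must be 'growth' or 'shrink'")
  dp <- diff(vertices$position)
  if (any(dp[phases == "growth"] < 0))
    stop("phase_annotation: growth segments must have non-negative displacement")
  if (any(dp[phases == "shrink"] > 0))
    stop("phase_annotation: shrink segments must have non-positive displacement")
  structure(list(vertices = vertices, phases = phases,
                 observation_time = diff(range(vertices$time)),
                 n_marks = n_marks),
            class = "phase_annotation")
}

#' @export
print.phase_annotation <- function(x, ...) {
  cat(sprintf("<phase_annotation> %d phases (%d growth, %d shrink) over %.1f s\n",
              length(x$phases), sum(x$phases == "growth"),
              sum(x$phases == "shrink"), x$observation_time))
  invisible(x)
}

#' Segment an end trajectory into growth and shrink phases
#'
#' Automatic substitute for manual kymograph marking: a hysteresis
#' (zigzag) changepoint detector tracks the running extremum of the
#' position trace and calls a phase transition whenever the trace reverses
#' by more than `min_event_displacement` from that extremum. Vertices are
#' placed at the extremal samples, so on a noiseless sawtooth the corners
#' are recovered exactly, and reversals smaller than the threshold are
#' absorbed into the surrounding phase.
#'
#' @param trajectory an [end_trajectory()] with >= 3 samples.
#' @param min_event_displacement smallest reversal called as an event (nm);
#'   default 480 nm (3 pixels at 160 nm/px).
#' @param use_truth if `TRUE` and the trajectory carries `truth_phases`,
#'   build the annotation from the ground truth instead of detecting.
#' @return A [phase_annotation()].
#' @export
segment_phases <- function(trajectory, min_event_displacement = 480,
                           use_truth = FALSE) {
  stopifnot(inherits(trajectory, "end_trajectory"))
  tt <- trajectory$times; pp <- trajectory$positions
  if (length(tt) < 3L) stop("segment_phases: need >= 3 samples")
  if (use_truth && !is.null(trajectory$truth_phases)) {
    tp <- trajectory$truth_phases
    vt <- c(tp$t_start, tp$t_end[nrow(tp)])
    vp <- if (all(c("pos_start", "pos_end") %in% names(tp)))
      c(tp$pos_start, tp$pos_end[nrow(tp)])
    else stats::approx(tt, pp, xout = vt, rule = 2)$y
    return(phase_annotation(data.frame(time = vt, position = vp), tp$phase))
  }
  n <- length(pp)
  state <- "growth"          # provisional; a leading drop flips it
  ext_i <- 1L; ext_v <- pp[1L]
  vert_i <- 1L; labels <- character(0)
  for (k in 2L:n) {
    if (state == "growth") {
      if (pp[k] >= ext_v) { ext_i <- k; ext_v <- pp[k] }
      else if (ext_v - pp[k] >= min_event_displacement) {
        vert_i <- c(vert_i, ext_i); labels <- c(labels, "growth")
        state <- "shrink"; ext_i <- k; ext_v <- pp[k]
      }
    } else {
      if (pp[k] <= ext_v) { ext_i <- k; ext_v <- pp[k] }
      else if (pp[k] - ext_v >= min_event_displacement) {
        vert_i <- c(vert_i, ext_i); labels <- c(labels, "shrink")
        state <- "growth"; ext_i <- k; ext_v <- pp[k]
      }
    }
  }
  vert_i <- c(vert_i, n); labels <- c(labels, state)
  # drop zero-length segments (e.g. when the trace starts by shrinking the
  # provisional growth segment collapses onto the first sample)
  dup <- which(diff(vert_i) == 0L)
  if (length(dup)) { vert_i <- vert_i[-dup]; labels <- labels[-dup] }
  v <- refine_vertices(tt, pp, vert_i)
  phase_annotation(data.frame(time = v$time, position = v$position), labels)
}

# Replace each interior vertex (placed at an extremal sample) by the
# intersection of the OLS lines fitted to the two adjacent phases, which
# removes the frame-quantization bias on phase slopes. The extremal sample
# itself is excluded from both fits because it straddles the transition.
refine_vertices <- function(tt, pp, vert_i) {
  vt <- tt[vert_i]; vp <- pp[vert_i]
  n_seg <- length(vert_i) - 1L
  if (n_seg < 2L) return(list(time = vt, position = vp))
  fit_line <- function(a, b, drop_first, drop_last) {
    idx <- vert_i[a]:vert_i[b]
    if (drop_first && length(idx) > 2L) idx <- idx[-1L]
    if (drop_last && length(idx) > 2L) idx <- idx[-length(idx)]
    if (length(idx) < 2L) return(NULL)
    cf <- stats::lm.fit(cbind(1, tt[idx]), pp[idx])$coefficients
    c(intercept = unname(cf[1L]), slope = unname(cf[2L]))
  }
  for (k in 2L:n_seg) {        # interior vertices only
    left <- fit_line(k - 1L, k, drop_first = k - 1L > 1L, drop_last = TRUE)
    right <- fit_line(k, k + 1L, drop_first = TRUE, drop_last = k + 1L <= n_seg)
    if (is.null(left) || is.null(right)) next
    dslope <- left["slope"] - right["slope"]
    if (abs(dslope) < 1e-12) next
    t_x <- (right["intercept"] - left["intercept"]) / dslope
    # accept only if the intersection stays between the neighboring samples
    if (t_x > tt[vert_i[k] - 1L] && t_x < tt[vert_i[k] + 1L] &&
        t_x > vt[k - 1L] && t_x < vt[k + 1L]) {
      vt[k] <- t_x
      vp[k] <- left["intercept"] + left["slope"] * t_x
    }
  }
  list(time = vt, position = unname(vp))
}

#' Dynamic-instability parameters with their error models
#'
#' Pools one or more phase annotations and computes, with the stated error
#' models:
#' \itemize{
#'   \item growth rate (nm/s): phase slopes pooled weighted by phase
#'     duration, SE as the weighted SE across phases;
#'   \item shrinkage rate (nm/s, positive): phase slopes pooled weighted by
#'     shrinkage length, weighted SE;
#'   \item catastrophe frequency (s^-1): number of catastrophes divided by
#'     total time in growth, with counting error `sqrt(n)/growth_time`;
#'   \item rescue per shrinkage length (um^-1): rescues divided by total
#'     shrinkage length, counting error `sqrt(n)/shrink_length`;
#'   \item dynamicity (nm/s): total length grown plus total length shrunk
#'     divided by total observation time, with error
#'     `pixel_size * N / T` where N is the number of marked points.
#' }
#' A growth phase that ends with the observation is not a catastrophe, and a
#' shrink phase terminating at the seed (transition position within
#' `seed_zone` of zero) is not a rescue.
#'
#' @param annotations a [phase_annotation()] or list of them.
#' @param pixel_size nm per pixel entering the dynamicity error (default 160).
#' @param seed_zone distance from the seed boundary (nm) within which a
#'   shrink-to-growth transition is attributed to the seed, not to rescue.
#'   The default 0 (exact seed contact) suits noiseless annotations; for
#'   vertices marked on noisy kymographs a tolerance of about one pixel is
#'   appropriate.
#' @return Object of class `dynamics_summary`: a list with elements
#'   `growth_rate`, `shrink_rate`, `catastrophe_freq`, `rescue_per_length`,
#'   `dynamicity` (each `c(value, se)`), and `totals`.
#' @export
compute_dynamics <- function(annotations, pixel_size = 160, seed_zone = 0) {
  if (inherits(annotations, "phase_annotation")) annotations <- list(annotations)
  if (length(annotations) == 0L) stop("compute_dynamics: empty annotation set")
  stopifnot(all(vapply(annotations, inherits, logical(1L), "phase_annotation")))
  g_dt <- g_dp <- s_dt <- s_dp <- numeric(0)
  n_cat <- 0L; n_res <- 0L
  obs_time <- 0; n_marks <- 0L
  for (a in annotations) {
    v <- a$vertices; ph <- a$phases
    dt <- diff(v$time); dp <- diff(v$position)
    g <- ph == "growth"
    g_dt <- c(g_dt, dt[g]);  g_dp <- c(g_dp, dp[g])
    s_dt <- c(s_dt, dt[!g]); s_dp <- c(s_dp, -dp[!g])
    if (length(ph) > 1L) {
      trans_from <- ph[-length(ph)]; trans_to <- ph[-1L]
      trans_pos <- v$position[2:(length(ph))]
      n_cat <- n_cat + sum(trans_from == "growth" & trans_to == "shrink")
      n_res <- n_res + sum(trans_from == "shrink" & trans_to == "growth" &
                             trans_pos > seed_zone)
    }
    obs_time <- obs_time + a$observation_time
    n_marks <- n_marks + a$n_marks
  }
  growth_time <- sum(g_dt); growth_len <- sum(g_dp)
  shrink_time <- sum(s_dt); shrink_len <- sum(s_dp)
  if (growth_time <= 0 && n_cat > 0)
    stop("compute_dynamics: catastrophes observed with zero growth time")
  growth_rate <- pooled_rate(g_dp / g_dt, g_dt)
  shrink_rate <- pooled_rate(s_dp / s_dt, s_dp)
  cat_freq <- if (growth_time > 0)
    c(n_cat / growth_time, sqrt(n_cat) / growth_time) else c(NA_real_, NA_real_)
  res_per_um <- if (shrink_len > 0)
    c(n_res / (shrink_len / 1000), sqrt(n_res) / (shrink_len / 1000))
  else c(NA_real_, NA_real_)
  dynamicity <- c((growth_len + shrink_len) / obs_time,
                  pixel_size * n_marks / obs_time)
  structure(list(growth_rate = growth_rate, shrink_rate = shrink_rate,
                 catastrophe_freq = cat_freq, rescue_per_length = res_per_um,
                 dynamicity = dynamicity,
                 totals = list(n_catastrophes = n_cat, n_rescues = n_res,
                               growth_time_s = growth_time,
                               growth_length_nm = growth_len,
                               shrink_time_s = shrink_time,
                               shrink_length_nm = shrink_len,
                               observation_time_s = obs_time,
                               n_marks = n_marks)),
            class = "dynamics_summary")
}

# weighted mean of per-phase slopes with weighted SE across phases
pooled_rate <- function(slopes, w) {
  ok <- is.finite(slopes) & w > 0
  slopes <- slopes[ok]; w <- w[ok]
  if (length(slopes) == 0L) return(c(NA_real_, NA_real_))
  m <- sum(w * slopes) / sum(w)
  if (length(slopes) == 1L) return(c(m, NA_real_))
  # weighted variance (frequency weights), SE of the weighted mean
  v <- sum(w * (slopes - m)^2) / sum(w)
  n_eff <- sum(w)^2 / sum(w^2)
  c(m, sqrt(v / max(n_eff - 1, 1)))
}

#' @export
print.dynamics_summary <- function(x, ...) {
  f <- function(v, unit) sprintf("%.4g +/- %.2g %s", v[1L], v[2L], unit)
  cat("<dynamics_summary>\n")
  cat("  growth rate:       ", f(x$growth_rate, "nm/s"), "\n")
  cat("  shrinkage rate:    ", f(x$shrink_rate, "nm/s"), "\n")
  cat("  catastrophe freq:  ", f(x$catastrophe_freq, "/s"),
      sprintf(" (n=%d)", x$totals$n_catastrophes), "\n")
  cat("  rescue/length:     ", f(x$rescue_per_length, "/um"),
      sprintf(" (n=%d)", x$totals$n_rescues), "\n")
  cat("  dynamicity:        ", f(x$dynamicity, "nm/s"), "\n")
  invisible(x)
}

#' Inverse-variance weighted mean of replicate estimates
#'
#' Combines per-replicate values with standard errors using weights
#' `1/SE^2`; the combined standard error is `1/sqrt(sum(weights))`.
#'
#' @param values replicate estimates.
#' @param se standard errors, all > 0.
#' @return Named numeric `c(mean, se)`.
#' @export
weighted_mean_se <- function(values, se) {
  if (length(values) != length(se) || length(values) < 1L)
    stop("weighted_mean_se: need equal-length, non-empty values and se")
  if (any(!is.finite(se)) || any(se <= 0))
    stop("weighted_mean_se: all SE must be finite and > 0")
  w <- 1 / se^2
  c(mean = sum(w * values) / sum(w), se = 1 / sqrt(sum(w)))
}
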