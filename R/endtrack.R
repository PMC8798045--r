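#' Sliding-window end velocities
#'
#' Fits an ordinary least-squares line to the end position within
#' consecutive, non-overlapping windows (default 2 min) anchored at the
#' trajectory's first sample, and applies the leading-segment elimination
#' rule: windows with negative slope at the beginning of a trajectory are
#' marked `eliminated` until the first positive-slope window, so that every
#' trajectory starts with a positive-velocity segment; subsequent
#' negative-velocity windows are kept. A trailing window shorter than
#' `min_tail` is dropped, and windows with fewer than two samples are
#' absent.
#'
#' @param trajectory an [end_trajectory()] spanning at least one window.
#' @param window window length (s), default 120.
#' @param min_tail shortest trailing partial window retained (s), default 60.
#' @return data.frame of class `velocity_segments` with columns `t_start`,
#'   `t_end`, `velocity` (nm/s), `n_points`, `class` (`"growth"` until
#'   classified, or `"eliminated"`), `intensity` (NA until attached).
#' @export
fit_segment_velocities <- function(trajectory, window = 120, min_tail = 60) {
  stopifnot(inherits(trajectory, "end_trajectory"))
  tt <- trajectory$times; pp <- trajectory$positions
  span <- tt[length(tt)] - tt[1L]
  if (span < window) stop("fit_segment_velocities: trajectory shorter than one window")
  starts <- seq(tt[1L], tt[length(tt)], by = window)
  starts <- starts[starts < tt[length(tt)]]
  out <- list()
  for (s in starts) {
    e <- min(s + window, tt[length(tt)])
    if (e - s < window && e - s < min_tail) next
    in_w <- tt >= s & tt < s + window
    if (s + window >= tt[length(tt)]) in_w <- tt >= s  # include final sample
    if (sum(in_w) < 2L) next
    fit <- stats::lm.fit(cbind(1, tt[in_w]), pp[in_w])
    out[[length(out) + 1L]] <-
      data.frame(t_start = s, t_end = e, velocity = unname(fit$coefficients[2L]),
                 n_points = sum(in_w))
  }
  seg <- do.call(rbind, out)
  # leading-elimination rule: drop negative-velocity windows before the
  # first positive one
  first_pos <- which(seg$velocity > 0)[1L]
  seg$class <- "growth"
  if (is.na(first_pos)) seg$class[] <- "eliminated"
  else if (first_pos > 1L) seg$class[seq_len(first_pos - 1L)] <- "eliminated"
  seg$intensity <- NA_real_
  class(seg) <- c("velocity_segments", "data.frame")
  seg
}

#' Classify velocity segments as growth or shrinking
#'
#' Segments with velocity strictly smaller than `shrink_threshold`
#' (default -2.5 nm/s) are classified as `shrinking` and excluded from
#' growth statistics; a segment at exactly the threshold is retained.
#' Eliminated segments keep their label.
#'
#' @param segments output of [fit_segment_velocities()].
#' @param shrink_threshold classification threshold (nm/s).
#' @return The segment table with updated `class`.
#' @export
classify_segments <- function(segments, shrink_threshold = -2.5) {
  stopifnot(is.data.frame(segments), "velocity" %in% names(segments))
  shr <- segments$class != "eliminated" & segments$velocity < shrink_threshold
  segments$class[shr] <- "shrinking"
  segments
}

#' End-region probe intensity with local background subtraction
#'
#' For every frame, the probe intensity at the microtubule end is measured
#' as the mean over a `lattice_len`-pixel window on the lattice ending at
#' the tracked end position, minus the mean over a `bg_len`-pixel solution
#' background window whose near edge is `gap` pixels beyond the end
#' (solution side, away from the seed). Frames whose background window has
#' fewer than `bg_len` pixels inside the image are eliminated. Sub-pixel
#' end positions are rounded to the nearest pixel.
#'
#' @param kymo a [kymograph()] with a `probe` channel.
#' @param trajectory an [end_trajectory()] on the same frame grid.
#' @param lattice_len,gap,bg_len window geometry in pixels (defaults 5/3/5).
#' @return data.frame with columns `frame`, `time_s`, `end_px`, `intensity`,
#'   `kept`; eliminated frames have `kept = FALSE` and `intensity = NA`.
#' @export
end_intensity <- function(kymo, trajectory, lattice_len = 5L, gap = 3L,
                          bg_len = 5L) {
  stopifnot(inherits(kymo, "kymograph"), inherits(trajectory, "end_trajectory"))
  if (!"probe" %in% names(kymo$channels))
    stop("end_intensity: kymograph lacks a 'probe' channel")
  probe <- kymo$channels$probe
  n_frames <- nrow(probe); n_px <- ncol(probe)
  if (length(trajectory$times) != n_frames)
    stop("end_intensity: trajectory and kymograph frame counts differ")
  end_px <- pmax(1L, as.integer(round(trajectory$positions / kymo$pixel_size + 0.5)))
  if (all(end_px > n_px))
    warning("end_intensity: tracked end outside the image for all frames")
  intensity <- rep(NA_real_, n_frames); kept <- logical(n_frames)
  for (f in seq_len(n_frames)) {
    e <- end_px[f]
    if (e > n_px) next
    bg_idx <- (e + gap + 1L):(e + gap + bg_len)
    bg_idx <- bg_idx[bg_idx >= 1L & bg_idx <= n_px]
    if (length(bg_idx) < bg_len) next   # < bg_len pixels available: eliminate
    lat_idx <- max(1L, e - lattice_len + 1L):e
    intensity[f] <- mean(probe[f, lat_idx]) - mean(probe[f, bg_idx])
    kept[f] <- TRUE
  }
  data.frame(frame = seq_len(n_frames), time_s = trajectory$times,
             end_px = end_px, intensity = intensity, kept = kept)
}

#' Attach per-segment mean probe intensity to velocity segments
#'
#' Averages the per-frame background-subtracted end intensity (from
#' [end_intensity()]) over the frames of each velocity segment.
#'
#' @param segments output of [fit_segment_velocities()].
#' @param intensity_series output of [end_intensity()].
#' @return The segment table with `intensity` filled in (NA where a segment
#'   contains no kept frames).
#' @export
attach_segment_intensity <- function(segments, intensity_series) {
  stopifnot(is.data.frame(segments), is.data.frame(intensity_series))
  for (i in seq_len(nrow(segments))) {
    sel <- intensity_series$kept &
      intensity_series$time_s >= segments$t_start[i] &
      intensity_series$time_s < segments$t_end[i]
    segments$intensity[i] <- if (any(sel))
      mean(intensity_series$intensity[sel]) else NA_real_
  }
  segments
}

#' Per-bin medians of segment velocity or intensity
#'
#' Groups non-excluded segments by time (window-aligned midpoints) or by
#' velocity and reports the median of the requested quantity per bin; empty
#' bins are omitted.
#'
#' @param segments classified segment table; `eliminated` and `shrinking`
#'   segments are excluded.
#' @param by `"time"` or `"velocity"`.
#' @param value column to take the median of (`"velocity"` or `"intensity"`).
#' @param breaks bin breaks for `by = "velocity"`; for `by = "time"` the
#'   windows themselves are the bins.
#' @return data.frame with `bin_center`, `n`, `median`.
#' @export
bin_medians <- function(segments, by = c("time", "velocity"),
                        value = "velocity", breaks = NULL) {
  by <- match.arg(by)
  keep <- !(segments$class %in% c("eliminated", "shrinking"))
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg) == 0L) stop("bin_medians: no non-excluded segments")
  vals <- seg[[value]]
  if (by == "time") {
    key <- (seg$t_start + seg$t_end) / 2
    groups <- split(vals, key)
    centers <- as.numeric(names(groups))
  } else {
    if (is.null(breaks))
      breaks <- pretty(seg$velocity, n = 10)
    idx <- findInterval(seg$velocity, breaks, rightmost.closed = TRUE)
    ok <- idx >= 1L & idx < length(breaks)
    groups <- split(vals[ok], idx[ok])
    centers <- (breaks[as.integer(names(groups))] +
                  breaks[as.integer(names(groups)) + 1L]) / 2
  }
  res <- data.frame(bin_center = centers,
                    n = vapply(groups, function(g) sum(!is.na(g)), integer(1L)),
                    median = vapply(groups, stats::median, numeric(1L),
                                    na.rm = TRUE))
  res <- res[res$n > 0L, , drop = FALSE]
  rownames(res) <- NULL
  res
}
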