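#' Masked per-frame field intensity
#'
#' Sums the probe intensity over the microtubule-occupied area only:
#' a mask is built by Otsu-thresholding the time-averaged lattice channel
#' and dilating it by one pixel, then the probe channel is summed inside
#' the mask for every frame, excluding solution background.
#'
#' @param channels named list with `lattice` and `probe`, each either a
#'   matrix (frames x pixels, kymograph-like) or a 3-D array
#'   (frames x y x x).
#' @param dilate_px mask dilation in pixels (default 1).
#' @return List with `intensity` (per-frame sums), `mask` (logical),
#'   `mask_px` (pixel count).
#' @export
masked_field_intensity <- function(channels, dilate_px = 1L) {
  stopifnot(is.list(channels), all(c("lattice", "probe") %in% names(channels)))
  lat <- channels$lattice; probe <- channels$probe
  as3d <- function(a) if (length(dim(a)) == 2L)
    array(a, dim = c(nrow(a), 1L, ncol(a))) else a
  lat <- as3d(lat); probe <- as3d(probe)
  stopifnot(all(dim(lat) == dim(probe)))
  avg <- apply(lat, c(2L, 3L), mean)
  rng <- range(avg)
  if (diff(rng) == 0) stop("masked_field_intensity: flat lattice channel, empty mask")
  norm <- (avg - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  if (dilate_px > 0L) {
    brush <- EBImage::makeBrush(2L * dilate_px + 1L, shape = "box")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  }
  if (!any(mask)) stop("masked_field_intensity: empty mask")
  n_frames <- dim(probe)[1L]
  intensity <- vapply(seq_len(n_frames), function(f) {
    frame <- probe[f, , , drop = TRUE]
    sum(frame[mask])
  }, numeric(1L))
  list(intensity = intensity, mask = mask, mask_px = sum(mask))
}

#' Compare probe intensity between seed and pre-existing lattice regions
#'
#' Welch's unequal-variance t-test across microtubules on per-microtubule
#' mean probe intensities measured on the stabilized-seed region versus the
#' pre-existing (GDP) lattice region.
#'
#' @param seed_means,gdp_means per-microtubule region means (a.u.), one
#'   value per microtubule, both non-empty.
#' @return List with `seed` and `gdp` summaries (`mean`, `sd`, `n`) and
#'   `test` (the Welch `htest`).
#' @export
region_compare <- function(seed_means, gdp_means) {
  if (length(seed_means) < 2L || length(gdp_means) < 2L)
    stop("region_compare: need >= 2 microtubules per region")
  ht <- stats::t.test(seed_means, gdp_means, var.equal = FALSE)
  list(seed = list(mean = mean(seed_means), sd = stats::sd(seed_means),
                   n = length(seed_means)),
       gdp = list(mean = mean(gdp_means), sd = stats::sd(gdp_means),
                  n = length(gdp_means)),
       test = ht)
}

#' Probe-intensity profile across a stretch initiation site
#'
#' Once a probe stretch has reached `trigger_length_um`, measures a
#' `linescan_px`-pixel probe linescan centered on the initiation pixel and
#' divides it by the center value, so the profile reads 1.0 at the
#' initiation site. Offsets are reported positive toward the direction of
#' microtubule growth.
#'
#' @param kymo a [kymograph()] with a `probe` channel.
#' @param initiation_px pixel index of stretch initiation.
#' @param frame frame at which to measure; `NULL` finds the first frame in
#'   which the contiguous above-threshold run containing `initiation_px`
#'   reaches `trigger_length_um`.
#' @param trigger_length_um minimum stretch length before measuring (um).
#' @param threshold intensity threshold defining the stretch; default half
#'   the probe channel maximum.
#' @param linescan_px profile length in pixels (default 20).
#' @param growth_direction `"right"` or `"left"`: direction of growth along
#'   the pixel axis.
#' @return data.frame with `offset_px`, `offset_um`, `rel_intensity`, and
#'   attribute `frame`.
#' @export
stretch_profile <- function(kymo, initiation_px, frame = NULL,
                            trigger_length_um = 2, threshold = NULL,
                            linescan_px = 20L,
                            growth_direction = c("right", "left")) {
  growth_direction <- match.arg(growth_direction)
  stopifnot(inherits(kymo, "kymograph"), "probe" %in% names(kymo$channels))
  probe <- kymo$channels$probe
  n_px <- ncol(probe)
  half <- linescan_px %/% 2L
  if (initiation_px - half < 1L || initiation_px + half > n_px)
    stop("stretch_profile: initiation closer than ", half,
         " px to the image edge")
  if (is.null(frame)) {
    if (is.null(threshold)) threshold <- max(probe) / 2
    min_px <- ceiling(trigger_length_um * 1000 / kymo$pixel_size)
    for (f in seq_len(nrow(probe))) {
      above <- probe[f, ] >= threshold
      if (!above[initiation_px]) next
      r <- rle(above)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      j <- which(starts <= initiation_px & ends >= initiation_px &
                   r$values)
      if (length(j) && r$lengths[j] >= min_px) { frame <- f; break }
    }
    if (is.null(frame))
      stop("stretch_profile: stretch never reached ", trigger_length_um,
           " um within the movie")
  }
  offs <- seq.int(-(half - 1L), half)
  idx <- if (growth_direction == "right") initiation_px + offs
         else initiation_px - offs
  center <- probe[frame, initiation_px]
  if (center == 0) stop("stretch_profile: zero intensity at the center point")
  out <- data.frame(offset_px = offs,
                    offset_um = offs * kymo$pixel_size / 1000,
                    rel_intensity = probe[frame, idx] / center)
  attr(out, "frame") <- frame
  out
}

#' Per-channel linescans at requested times
#'
#' Samples every channel of a kymograph along the spatial axis at the frame
#' nearest to each requested time; requested times outside the movie are
#' skipped with a message. With `normalize = TRUE` each channel of each
#' linescan is min-max scaled to `[0, 1]`.
#'
#' @param kymo a [kymograph()].
#' @param times times (s) at which linescans are taken.
#' @param normalize logical.
#' @return Named list (one element per time, `"t<seconds>"`) of data.frames
#'   with `position_um` and one column per channel.
#' @export
damage_linescans <- function(kymo, times, normalize = FALSE) {
  stopifnot(inherits(kymo, "kymograph"))
  n_frames <- nrow(kymo$channels[[1L]])
  t_frames <- (seq_len(n_frames) - 1L) * kymo$frame_interval
  pos <- (seq_len(ncol(kymo$channels[[1L]])) - 0.5) * kymo$pixel_size / 1000
  out <- list()
  for (tm in times) {
    if (tm < min(t_frames) || tm > max(t_frames)) {
      message("damage_linescans: time ", tm, " s outside the movie; skipped")
      next
    }
    f <- which.min(abs(t_frames - tm))
    df <- data.frame(position_um = pos)
    for (ch in names(kymo$channels)) {
      v <- kymo$channels[[ch]][f, ]
      if (normalize) {
        rng <- range(v)
        v <- if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v * 0
      }
      df[[ch]] <- v
    }
    out[[paste0("t", tm)]] <- df
  }
  out
}

#' Severing-protection timecourse statistic
#'
#' Implements the coated-versus-control severing comparison: intensities
#' are first normalized per microtubule to the mean over the baseline
#' window; per field of view, the threshold time is the first frame at
#' which the mean normalized control (non-coated) intensity falls below
#' `threshold` for two consecutive frames; coated microtubules are then
#' sampled at that same time. Population values are combined as
#' inverse-SE^2 weighted means after removing outliers by the
#' 3-scaled-MAD rule.
#'
#' @param records long data.frame with columns `mt_id`, `field`, `coated`
#'   (logical), `time_s`, `intensity`, `se` (per-frame SE per microtubule).
#' @param threshold normalized-intensity threshold (default 0.2).
#' @param baseline `c(t0, t1)` baseline window in s (default 0-60 s).
#' @param mad_thresh MAD multiplier for outlier rejection.
#' @return List with `per_field` (data.frame `field`, `threshold_time_s`),
#'   `coated` and `control` population summaries (`mean`, `se`, `n`,
#'   `n_outliers`), and `ratio` (coated/control weighted means).
#' @export
severing_timecourse <- function(records, threshold = 0.2,
                                baseline = c(0, 60), mad_thresh = 3) {
  stopifnot(is.data.frame(records),
            all(c("mt_id", "field", "coated", "time_s", "intensity", "se")
                %in% names(records)))
  # per-microtubule baseline normalization
  norm <- do.call(rbind, lapply(split(records, records$mt_id), function(r) {
    base <- r$intensity[r$time_s >= baseline[1L] & r$time_s <= baseline[2L]]
    if (length(base) == 0L)
      stop("severing_timecourse: no baseline frames for microtubule ",
           r$mt_id[1L])
    b <- mean(base)
    r$intensity <- r$intensity / b
    r$se <- r$se / abs(b)
    r
  }))
  per_field <- list(); coated_vals <- coated_se <- numeric(0)
  ctrl_vals <- ctrl_se <- numeric(0)
  for (f in unique(norm$field)) {
    fld <- norm[norm$field == f, , drop = FALSE]
    ctrl <- fld[!fld$coated, , drop = FALSE]
    coat <- fld[fld$coated, , drop = FALSE]
    if (nrow(ctrl) == 0L || nrow(coat) == 0L)
      stop("severing_timecourse: field ", f,
           " needs >= 1 control and >= 1 coated microtubule")
    tms <- sort(unique(ctrl$time_s))
    curve <- vapply(tms, function(tm)
      mean(ctrl$intensity[ctrl$time_s == tm]), numeric(1L))
    below <- curve < threshold
    idx <- which(below[-length(below)] & below[-1L])[1L]
    if (is.na(idx)) {
      message("severing_timecourse: control never crossed the threshold in field ",
              f, "; field excluded")
      next
    }
    t_thr <- tms[idx]
    per_field[[length(per_field) + 1L]] <-
      data.frame(field = f, threshold_time_s = t_thr)
    sample_at <- function(mt) {
      k <- which.min(abs(mt$time_s - t_thr))
      c(mt$intensity[k], mt$se[k])
    }
    for (id in unique(coat$mt_id)) {
      v <- sample_at(coat[coat$mt_id == id, , drop = FALSE])
      coated_vals <- c(coated_vals, v[1L]); coated_se <- c(coated_se, v[2L])
    }
    for (id in unique(ctrl$mt_id)) {
      v <- sample_at(ctrl[ctrl$mt_id == id, , drop = FALSE])
      ctrl_vals <- c(ctrl_vals, v[1L]); ctrl_se <- c(ctrl_se, v[2L])
    }
  }
  if (length(per_field) == 0L)
    stop("severing_timecourse: no field produced a threshold time")
  pop <- function(vals, ses) {
    out <- !mad_keep(vals, mad_thresh)
    wm <- weighted_mean_se(vals[!out], ses[!out])
    list(mean = unname(wm["mean"]), se = unname(wm["se"]),
         n = sum(!out), n_outliers = sum(out))
  }
  coated <- pop(coated_vals, coated_se)
  control <- pop(ctrl_vals, ctrl_se)
  list(per_field = do.call(rbind, per_field),
       coated = coated, control = control,
       ratio = coated$mean / control$mean)
}

# TRUE for values retained by the |x - median| <= thresh * scaled-MAD rule
mad_keep <- function(x, thresh = 3) {
  med <- stats::median(x)
  abs(x - med) <= thresh * stats::mad(x)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a 2-D image by grayscale morphological
#' opening with a disc structuring element of the given radius and
#' subtracts it; structures narrower than the ball (e.g. a one-pixel-wide
#' microtubule ridge) survive at full height while broad plateaus are
#' removed. Output is clamped at zero.
#'
#' @param image numeric 2-D matrix.
#' @param radius ball radius in pixels, > 0 (default 5).
#' @return Background-subtracted matrix of the same dimension.
#' @export
rolling_ball_background <- function(image, radius = 5L) {
  if (radius <= 0) stop("rolling_ball_background: radius must be > 0")
  stopifnot(is.matrix(image))
  mx <- max(image)
  if (mx <= 0) return(image * 0)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  bg <- EBImage::imageData(EBImage::opening(EBImage::Image(image / mx), brush)) * mx
  pmax(image - bg, 0)
}
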