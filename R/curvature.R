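#' Curvature along a traced filament polyline
#'
#' Estimates the unsigned curvature at every trace point from the
#' circumscribed circle through three consecutive points of the smoothed
#' polyline (Menger curvature, `kappa = 4*Area/(|ab||bc||ca|) = 1/R`).
#' Coordinates are first smoothed with a centered moving average of
#' `smoothing` points (1 = no smoothing; use 1 for noiseless geometric
#' traces, the default 5 suppresses pixel-scale tracing noise at the cost
#' of a small inward bias on tightly curved arcs). A collinear triple gives
#' `kappa = 0`; endpoints copy the nearest interior value.
#'
#' @param coords data.frame with columns `x_um`, `y_um` (>= 3 points,
#'   roughly uniform spacing, no consecutive duplicates).
#' @param smoothing moving-average window (points, odd recommended).
#' @return data.frame of class `curvature_samples` with `arclength_um`,
#'   `curvature_per_um`, `x_um`, `y_um`.
#' @export
polyline_curvature <- function(coords, smoothing = 5L) {
  stopifnot(is.data.frame(coords), all(c("x_um", "y_um") %in% names(coords)))
  n <- nrow(coords)
  if (n < 3L) stop("polyline_curvature: need >= 3 points")
  if (any(diff(coords$x_um) == 0 & diff(coords$y_um) == 0))
    stop("polyline_curvature: duplicated consecutive points")
  sm <- function(v) {
    if (smoothing <= 1L) return(v)
    half <- floor(smoothing / 2)
    vapply(seq_len(n), function(i) {
      idx <- max(1L, i - half):min(n, i + half)
      mean(v[idx])
    }, numeric(1L))
  }
  x <- sm(coords$x_um); y <- sm(coords$y_um)
  kappa <- rep(NA_real_, n)
  for (i in 2L:(n - 1L)) {
    ax <- x[i - 1L]; ay <- y[i - 1L]
    bx <- x[i]; by <- y[i]
    cx <- x[i + 1L]; cy <- y[i + 1L]
    cross2 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
    ab <- sqrt((bx - ax)^2 + (by - ay)^2)
    bc <- sqrt((cx - bx)^2 + (cy - by)^2)
    ca <- sqrt((cx - ax)^2 + (cy - ay)^2)
    kappa[i] <- if (ab * bc * ca == 0) 0 else abs(2 * cross2) / (ab * bc * ca)
  }
  kappa[1L] <- kappa[2L]; kappa[n] <- kappa[n - 1L]
  arc <- c(0, cumsum(sqrt(diff(coords$x_um)^2 + diff(coords$y_um)^2)))
  out <- data.frame(arclength_um = arc, curvature_per_um = kappa,
                    x_um = coords$x_um, y_um = coords$y_um)
  class(out) <- c("curvature_samples", "data.frame")
  out
}

#' Sample image intensity along a trace
#'
#' Nearest-pixel lookup of a 2-D image (e.g. the probe channel of a
#' projection) at trace coordinates given in um.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param coords data.frame with `x_um`, `y_um`.
#' @param pixel_size nm per pixel.
#' @return Numeric vector of intensities (NA outside the image).
#' @export
sample_trace_intensity <- function(image, coords, pixel_size = 160) {
  px <- pmax(1L, as.integer(round(coords$x_um * 1000 / pixel_size + 0.5)))
  py <- pmax(1L, as.integer(round(coords$y_um * 1000 / pixel_size + 0.5)))
  ok <- px <= ncol(image) & py <= nrow(image)
  out <- rep(NA_real_, nrow(coords))
  out[ok] <- image[cbind(py[ok], px[ok])]
  out
}

#' Bin curvature samples and reject intensity outliers per bin
#'
#' Groups samples into curvature bins of `bin_width` (default 0.1 um^-1;
#' bin k covers `(k*w, (k+1)*w]` with samples on a boundary going to the
#' lower bin and zero curvature into the first bin) and flags intensity
#' outliers within each bin as points more than `mad_thresh` scaled median
#' absolute deviations from the bin median (the default 3-scaled-MAD rule
#' of common `isoutlier`-style routines). Bin means and SDs are computed on
#' the retained samples.
#'
#' @param samples data.frame with `curvature_per_um` and `intensity`.
#' @param bin_width bin width (um^-1).
#' @param outlier_method `"mad"` or `"none"`.
#' @param mad_thresh MAD multiplier (default 3).
#' @return List with `bins` (data.frame `bin_center`, `n`, `n_outliers`,
#'   `mean`, `sd`) and `samples` (input plus `bin_center`, `outlier`).
#' @export
bin_and_filter <- function(samples, bin_width = 0.1,
                           outlier_method = c("mad", "none"),
                           mad_thresh = 3) {
  outlier_method <- match.arg(outlier_method)
  stopifnot(is.data.frame(samples),
            all(c("curvature_per_um", "intensity") %in% names(samples)))
  if (nrow(samples) == 0L) stop("bin_and_filter: need >= 1 sample")
  k <- samples$curvature_per_um
  if (any(k < 0)) stop("bin_and_filter: curvature magnitudes must be >= 0")
  idx <- pmax(ceiling(k / bin_width), 1L)   # boundary -> lower bin; 0 -> bin 1
  samples$bin_center <- (idx - 0.5) * bin_width
  samples$outlier <- FALSE
  if (outlier_method == "mad") {
    for (b in unique(idx)) {
      sel <- idx == b
      v <- samples$intensity[sel]
      med <- stats::median(v)
      smad <- stats::mad(v)  # scaled MAD (constant 1.4826)
      samples$outlier[sel] <- abs(v - med) > mad_thresh * smad
    }
  }
  bins <- do.call(rbind, lapply(sort(unique(idx)), function(b) {
    sel <- idx == b
    keepv <- samples$intensity[sel & !samples$outlier]
    if (length(keepv) == 0L) return(NULL)
    data.frame(bin_center = (b - 0.5) * bin_width,
               n = length(keepv), n_outliers = sum(samples$outlier[sel]),
               mean = mean(keepv),
               sd = if (length(keepv) > 1L) stats::sd(keepv) else NA_real_)
  }))
  list(bins = bins, samples = samples)
}

#' Linear regression of binned intensity on curvature
#'
#' Ordinary least squares of bin-mean intensity on bin-center curvature:
#' the slope (a.u. x um) with its 95% confidence interval and the
#' two-sided p-value for slope = 0. The fit uses the bin means only, so it
#' is invariant to per-bin sample counts.
#'
#' @param binned data.frame with `bin_center` and `mean` (>= 3 bins), e.g.
#'   the `bins` element of [bin_and_filter()].
#' @return List with `slope`, `slope_ci`, `p_value`, `intercept`, `model`.
#' @export
fit_intensity_vs_curvature <- function(binned) {
  stopifnot(is.data.frame(binned),
            all(c("bin_center", "mean") %in% names(binned)))
  if (nrow(binned) < 3L) stop("fit_intensity_vs_curvature: need >= 3 bins")
  fit <- stats::lm(mean ~ bin_center, data = binned)
  co <- summary(fit)$coefficients
  ci <- suppressWarnings(stats::confint(fit))["bin_center", ]
  p <- co["bin_center", "Pr(>|t|)"]
  se <- co["bin_center", "Std. Error"]
  if (is.nan(p) && se == 0) p <- 0   # exact line: zero residual variance
  list(slope = unname(co["bin_center", "Estimate"]),
       slope_ci = unname(ci),
       p_value = unname(p),
       intercept = unname(co["(Intercept)", "Estimate"]),
       model = fit)
}
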