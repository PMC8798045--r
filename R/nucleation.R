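#' Count templated nucleation per condition
#'
#' A seed counts as nucleated if any of its microtubule extensions exceeds
#' `min_length` (strictly; default 480 nm, i.e. >3 pixels at 160 nm/px)
#' within the observation window (default 900 s). Input is a long table of
#' per-seed extension measurements, e.g. from maximum-projection images or
#' per-frame length series.
#'
#' @param extensions data.frame with columns `x_uM` (condition), `seed_id`,
#'   `length_nm`, and optionally `time_s` (absent = within window).
#' @param min_length nucleation length criterion (nm), strict `>`.
#' @param window observation window (s).
#' @return data.frame with per-condition `x_uM`, `seeds_total`,
#'   `seeds_nucleated`, `fraction`, `error`.
#' @export
count_nucleated <- function(extensions, min_length = 480, window = 900) {
  stopifnot(is.data.frame(extensions),
            all(c("x_uM", "seed_id", "length_nm") %in% names(extensions)))
  if (nrow(extensions) == 0L) stop("count_nucleated: zero seeds")
  in_window <- if ("time_s" %in% names(extensions))
    extensions$time_s <= window else rep(TRUE, nrow(extensions))
  hit <- extensions$length_nm > min_length & in_window
  per_seed <- stats::aggregate(hit, by = list(x_uM = extensions$x_uM,
                                              seed_id = extensions$seed_id),
                               FUN = any)
  agg <- stats::aggregate(per_seed$x,
                          by = list(x_uM = per_seed$x_uM),
                          FUN = function(v) c(total = length(v), nuc = sum(v)))
  out <- data.frame(x_uM = agg$x_uM,
                    seeds_total = agg$x[, "total"],
                    seeds_nucleated = agg$x[, "nuc"])
  out$fraction <- out$seeds_nucleated / out$seeds_total
  out$error <- mapply(fraction_error, out$seeds_nucleated, out$seeds_total)
  out[order(out$x_uM), , drop = FALSE]
}

#' Error on a nucleated fraction
#'
#' Counting error on the fraction of nucleated seeds: `sqrt(N)/total` for
#' `N > 0` and `1/total` when no seed nucleated. The published rule reads
#' literally "N/total"; because that conflicts with its own zero-count
#' special case, the square-root counting error is the default and the
#' literal reading is available via `rule = "literal"`.
#'
#' @param N number of nucleated seeds, `0 <= N <= total`.
#' @param total number of seeds observed, > 0.
#' @param rule `"sqrt"` (default) or `"literal"`.
#' @return The error estimate (scalar).
#' @export
fraction_error <- function(N, total, rule = c("sqrt", "literal")) {
  rule <- match.arg(rule)
  if (total <= 0) stop("fraction_error: total must be > 0")
  if (N < 0 || N > total) stop("fraction_error: need 0 <= N <= total")
  if (N == 0) return(1 / total)
  switch(rule, sqrt = sqrt(N) / total, literal = N / total)
}

#' Fit the sigmoidal concentration dependence of templated nucleation
#'
#' Nonlinear least squares of the Hill-type sigmoid
#' `y(x) = x^s / (C^s + x^s)` to nucleated fractions versus tubulin
#' concentration, where `C` is the half-maximal concentration (uM) and `s`
#' the steepness. Fitting uses bounded Levenberg-Marquardt with a
#' deterministic initialization (`C0` = concentration whose fraction is
#' nearest 0.5, `s0 = 4`) and bounds `C in (0, 10*max(x))`, `s in (0, 50)`.
#' 95% confidence intervals come from the linearized covariance at the
#' optimum. The fit is unweighted by default; `weighted = TRUE` uses
#' `1/error^2` weights from the dataset's error column.
#'
#' @param dataset data.frame with columns `x_uM` and `fraction` (and
#'   `error` if `weighted`); needs >= 3 distinct concentrations.
#' @param weighted logical.
#' @return Object of class `sigmoid_fit`: list with `C`, `C_ci`, `s`,
#'   `s_ci`, `residual_sd`, `fitted`, `model`.
#' @export
fit_sigmoid <- function(dataset, weighted = FALSE) {
  stopifnot(is.data.frame(dataset),
            all(c("x_uM", "fraction") %in% names(dataset)))
  x <- dataset$x_uM; y <- dataset$fraction
  if (length(unique(x)) < 3L)
    stop("fit_sigmoid: need >= 3 distinct concentrations")
  if (length(unique(y)) == 1L)
    stop("fit_sigmoid: fractions are all equal; sigmoid is unidentifiable")
  if (all(y == 0)) stop("fit_sigmoid: all fractions zero")
  C0 <- x[which.min(abs(y - 0.5))]
  if (C0 <= 0) C0 <- max(min(x[x > 0]), 1e-3)
  start <- list(C = C0, s = 4)
  w <- if (weighted) {
    if (!"error" %in% names(dataset)) stop("fit_sigmoid: weighted fit needs an error column")
    1 / dataset$error^2
  } else rep(1, length(x))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ x^s / (C^s + x^s),
                      data = data.frame(x = x, y = y),
                      start = start, weights = w,
                      lower = c(C = 1e-9, s = 1e-9),
                      upper = c(C = 10 * max(x), s = 50),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit_sigmoid: did not converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- summary(fit)$coefficients
  dfree <- length(x) - 2L
  tq <- stats::qt(0.975, dfree)
  res <- structure(list(
    C = co["C", "Estimate"],
    C_ci = co["C", "Estimate"] + c(-1, 1) * tq * co["C", "Std. Error"],
    s = co["s", "Estimate"],
    s_ci = co["s", "Estimate"] + c(-1, 1) * tq * co["s", "Std. Error"],
    residual_sd = summary(fit)$sigma,
    fitted = stats::fitted(fit),
    model = fit), class = "sigmoid_fit")
  res
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> y = x^s/(C^s + x^s)\n  C = %.4g uM (95%% CI %.4g-%.4g)\n  s = %.4g (95%% CI %.4g-%.4g)\n  residual sd = %.3g\n",
              x$C, x$C_ci[1L], x$C_ci[2L], x$s, x$s_ci[1L], x$s_ci[2L],
              x$residual_sd))
  invisible(x)
}

#' Evaluate the nucleation sigmoid
#'
#' @param x tubulin concentration (uM).
#' @param C half-maximal concentration (uM).
#' @param s steepness.
#' @return `x^s / (C^s + x^s)`, with `y(0) = 0`.
#' @export
sigmoid_fraction <- function(x, C, s) {
  ifelse(x == 0, 0, x^s / (C^s + x^s))
}
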