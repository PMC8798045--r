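test_that("masked field intensity counts only on-mask probe signal", {
  lat <- matrix(0, 5, 40); lat[, 10:20] <- 100
  probe_off <- matrix(0, 5, 40); probe_off[, 30:35] <- 50
  res <- masked_field_intensity(list(lattice = lat, probe = probe_off),
                                dilate_px = 0L)
  expect_true(all(res$intensity == 0))
  probe_on <- matrix(0, 5, 40); probe_on[, 10:20] <- 3
  res2 <- masked_field_intensity(list(lattice = lat, probe = probe_on),
                                 dilate_px = 0L)
  expect_true(all(res2$intensity == 3 * res2$mask_px))
  expect_error(masked_field_intensity(list(lattice = lat * 0,
                                           probe = probe_on)), "mask")
})

test_that("a linearly loading probe is measured to track true occupancy", {
  cfg <- sim_config(f_c = 0, v_g = 0.1, psf_sigma = 0, noise_sd = 0,
                    rng_seed = 3L)
  # static stabilized microtubule: constant extent, occupancy ramps linearly
  tt <- seq(0, 300, 5)
  tr <- end_trajectory(tt, rep(4000, length(tt)))
  occ <- outer(pmin(tt / 250, 1), rep(1, 500))
  attr(occ, "times") <- tt
  ky <- render_kymograph(tr, occ, cfg)
  res <- masked_field_intensity(ky$channels)
  truth <- pmin(tt / 250, 1)
  measured <- res$intensity / max(res$intensity)
  expect_true(all(diff(res$intensity) >= -1e-9))       # monotone then flat
  expect_lt(max(abs(measured - truth / max(truth))), 0.05)
})

test_that("region comparison is Welch's t-test across microtubules", {
  set.seed(5)
  a <- rnorm(17, 10, 1)
  same <- region_compare(a, a)
  expect_equal(same$test$p.value, 1)
  apart <- region_compare(a, a + 10 * sd(a))
  expect_lt(apart$test$p.value, 0.001)
  expect_match(apart$test$method, "Welch")
})

test_that("null region differences give uniform p-values at n=17", {
  ps <- vapply(1:60, function(seed) {
    set.seed(seed)
    region_compare(rnorm(17, 5, 1), rnorm(17, 5, 1))$test$p.value
  }, numeric(1L))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("stretch profiles are center-normalized and oriented", {
  n_px <- 40L
  probe <- matrix(0.1, 30, n_px)
  center <- 20L
  for (f in 1:30) {
    half_w <- min(f, 12L)
    probe[f, (center - half_w):(center + half_w)] <- 2
  }
  ky <- kymograph(list(probe = probe), pixel_size = 160, frame_interval = 5)
  pr <- stretch_profile(ky, center)
  expect_equal(pr$rel_intensity[pr$offset_px == 0], 1)
  sym <- pr[abs(pr$offset_px) <= 9, ]
  expect_equal(sym$rel_intensity[order(sym$offset_px)],
               rev(sym$rel_intensity[order(-sym$offset_px)]))
  expect_error(stretch_profile(ky, 5L), "edge")
  # one-sided expansion toward growth reads higher on the toward side
  probe2 <- matrix(0.1, 30, n_px)
  for (f in 1:30) probe2[f, center:(center + min(f, 15L))] <- 2
  ky2 <- kymograph(list(probe = probe2), 160, 5)
  pr2 <- stretch_profile(ky2, center)
  expect_gt(mean(pr2$rel_intensity[pr2$offset_px > 0]),
            mean(pr2$rel_intensity[pr2$offset_px < 0]))
})

test_that("damage linescans colocalize probe maxima with lattice dips", {
  n_px <- 50L
  lat <- matrix(100, 10, n_px); lat[, 25] <- 50       # 50% damage dip
  probe <- matrix(1, 10, n_px); probe[, 25] <- 10     # probe enrichment
  ky <- kymograph(list(lattice = lat, probe = probe), 160, 60)
  ls <- damage_linescans(ky, times = c(0, 300))
  expect_length(ls, 2L)
  scan <- ls[["t300"]]
  expect_equal(which.min(scan$lattice), which.max(scan$probe))
  flat <- damage_linescans(kymograph(list(probe = matrix(4, 10, n_px)), 160, 60),
                           times = 0)
  expect_equal(unique(flat[["t0"]]$probe), 4)
  norm <- damage_linescans(ky, times = 0, normalize = TRUE)[["t0"]]
  expect_true(all(norm$lattice >= 0 & norm$lattice <= 1))
  expect_message(damage_linescans(ky, times = 1e5), "skipped")
})

test_that("the severing statistic samples coated intensity at the control threshold time", {
  times <- seq(0, 600, 15)
  mk <- function(id, coated, intensity) {
    data.frame(mt_id = id, field = 1L, coated = coated, time_s = times,
               intensity = intensity, se = 0.05)
  }
  decay <- exp(-times / 250)          # falls below 0.2 at t ~ 402 s
  rec <- rbind(mk(1, FALSE, decay), mk(2, FALSE, decay),
               mk(3, TRUE, rep(1, length(times))),
               mk(4, TRUE, rep(1, length(times))))
  out <- severing_timecourse(rec)
  # independent oracle: normalize by the baseline mean, then find the first
  # of two consecutive sub-threshold frames
  nd <- decay / mean(decay[times <= 60])
  below <- nd < 0.2
  expect_equal(out$per_field$threshold_time_s,
               times[which(below[-length(below)] & below[-1L])[1L]])
  expect_equal(out$coated$mean, 1)
  expect_gt(out$ratio, 4)
  # control never crossing the threshold leaves no usable field
  rec2 <- rbind(mk(1, FALSE, rep(1, length(times))),
                mk(2, TRUE, rep(1, length(times))))
  expect_error(suppressMessages(severing_timecourse(rec2)), "threshold")
})

test_that("equal SEs reduce the weighted mean to the arithmetic mean", {
  times <- seq(0, 600, 15)
  vals <- c(0.9, 1.0, 1.1, 1.2)
  # unit baseline, then a constant plateau at vals[i] (so the normalized
  # intensity sampled at the threshold time is exactly vals[i])
  rec <- do.call(rbind, lapply(seq_along(vals), function(i)
    data.frame(mt_id = i + 10, field = 1L, coated = TRUE, time_s = times,
               intensity = ifelse(times <= 60, 1, vals[i]), se = 0.05)))
  ctrl <- do.call(rbind, lapply(1:2, function(i)
    data.frame(mt_id = i, field = 1L, coated = FALSE, time_s = times,
               intensity = exp(-times / 200), se = 0.05)))
  out <- severing_timecourse(rbind(rec, ctrl))
  expect_equal(out$coated$mean, mean(vals))
  expect_equal(out$coated$n_outliers, 0L)
})

test_that("rolling-ball subtraction preserves ridges and removes plateaus", {
  flat <- matrix(10, 25, 25)
  expect_true(all(rolling_ball_background(flat) == 0))
  ridge <- matrix(2, 25, 25); ridge[13, ] <- 2 + 7   # 1-px-wide ridge
  out <- rolling_ball_background(ridge, radius = 5)
  expect_equal(out[13, 13], 7)
  expect_equal(out[5, 13], 0)
  plateau <- matrix(0, 31, 31); plateau[8:24, 8:24] <- 5  # wider than 2*radius
  out2 <- rolling_ball_background(plateau, radius = 5)
  expect_equal(max(abs(out2[12:20, 12:20])), 0)
  expect_error(rolling_ball_background(flat, radius = 0), "radius")
})
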