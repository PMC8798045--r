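test_that("sawtooth corners are recovered exactly", {
  tr <- sawtooth_trajectory()
  ann <- segment_phases(tr)
  expect_equal(ann$phases[1:6],
               rep(c("growth", "shrink"), 3))
  expect_equal(ann$vertices$time[2:7],
               c(300, 330, 630, 660, 960, 990), tolerance = 1e-9)
  expect_equal(ann$vertices$position[c(2, 4, 6)], rep(3000, 3),
               tolerance = 1e-9)
})

test_that("a constant-velocity trace yields one growth phase and no events", {
  tt <- seq(0, 300, 5)
  ann <- segment_phases(end_trajectory(tt, 8 * tt))
  expect_equal(length(ann$phases), 1L)
  expect_equal(ann$phases, "growth")
  dyn <- compute_dynamics(ann)
  expect_equal(dyn$totals$n_catastrophes, 0L)
  expect_equal(dyn$growth_rate[[1L]], 8)
})

test_that("dynamics formulas reproduce direct arithmetic", {
  # growth 10 um in 500 s, catastrophe, shrink 5 um in 50 s, observed 550 s
  ann <- phase_annotation(
    data.frame(time = c(0, 500, 550), position = c(0, 10000, 5000)),
    phases = c("growth", "shrink"))
  dyn <- compute_dynamics(ann)
  expect_equal(dyn$catastrophe_freq[[1L]], 1 / 500)
  expect_equal(dyn$totals$n_rescues, 0L)          # shrink not followed by growth
  expect_equal(dyn$dynamicity[[1L]], 15000 / 550)
  expect_equal(dyn$growth_rate[[1L]], 20)
  expect_equal(dyn$shrink_rate[[1L]], 100)
  # same trace, a rescue at 5000 nm (well away from the seed)
  ann2 <- phase_annotation(
    data.frame(time = c(0, 500, 550, 560),
               position = c(0, 10000, 5000, 5080)),
    phases = c("growth", "shrink", "growth"))
  dyn2 <- compute_dynamics(ann2)
  expect_equal(dyn2$totals$n_rescues, 1L)
  expect_equal(dyn2$rescue_per_length[[1L]], 1 / 5)   # per um shrunk
  # marked-point error model for dynamicity: pixel * N / T
  ann3 <- phase_annotation(
    data.frame(time = c(0, 500, 550), position = c(0, 10000, 5000)),
    phases = c("growth", "shrink"), n_marks = 3L)
  expect_equal(compute_dynamics(ann3)$dynamicity[[2L]], 160 * 3 / 550)
})

test_that("a shrink phase ending at the seed is not a rescue", {
  ann <- phase_annotation(
    data.frame(time = c(0, 500, 550, 700),
               position = c(0, 5000, 0, 1140)),
    phases = c("growth", "shrink", "growth"))
  expect_equal(compute_dynamics(ann)$totals$n_rescues, 0L)
})

test_that("dynamicity of a pure-growth annotation equals its growth rate", {
  ann <- phase_annotation(data.frame(time = c(0, 100, 250),
                                     position = c(0, 700, 1750)),
                          phases = c("growth", "growth"))
  dyn <- compute_dynamics(ann)
  expect_equal(dyn$dynamicity[[1L]], dyn$growth_rate[[1L]])
})

test_that("catastrophe frequency is invariant to splitting a growth phase", {
  whole <- phase_annotation(
    data.frame(time = c(0, 400, 430), position = c(0, 4000, 1000)),
    phases = c("growth", "shrink"))
  part1 <- phase_annotation(
    data.frame(time = c(0, 200), position = c(0, 2000)), phases = "growth")
  part2 <- phase_annotation(
    data.frame(time = c(200, 400, 430), position = c(2000, 4000, 1000)),
    phases = c("growth", "shrink"))
  expect_equal(compute_dynamics(list(part1, part2))$catastrophe_freq,
               compute_dynamics(whole)$catastrophe_freq)
})

test_that("degenerate inputs are rejected", {
  expect_error(compute_dynamics(list()), "empty")
  expect_error(phase_annotation(data.frame(time = c(0, 10), position = c(0, -5)),
                                phases = "growth"), "non-negative")
  expect_error(segment_phases(end_trajectory(c(0, 5), c(0, 10))), ">= 3")
})

test_that("truth-phase annotations recover the generating parameters", {
  cfg <- di_config(seed = 101L)
  trajs <- simulate_dynamic_instability(cfg, duration = 600, n = 200)
  dyn <- compute_dynamics(lapply(trajs, segment_phases, use_truth = TRUE))
  expect_lt(abs(dyn$growth_rate[[1L]] - 7.6), 1e-6)
  expect_lt(abs(dyn$shrink_rate[[1L]] - 100), 1e-6)
  expect_lt(abs(dyn$catastrophe_freq[[1L]] - 0.004),
            2 * dyn$catastrophe_freq[[2L]])
  expect_lt(abs(dyn$rescue_per_length[[1L]] - 0.2),
            2 * dyn$rescue_per_length[[2L]])
})

test_that("detection under noise matches noiseless detection of the same paths", {
  cfg <- di_config(seed = 55L)
  clean <- simulate_dynamic_instability(cfg, duration = 600, n = 60)
  set.seed(56)
  noisy <- lapply(clean, function(tr)
    end_trajectory(tr$times,
                   pmax(tr$positions + rnorm(length(tr$times), 0, 40), 0),
                   pixel_size = tr$pixel_size,
                   frame_interval = tr$frame_interval))
  matched <- 0L; total <- 0L
  for (i in seq_along(clean)) {
    ref <- transition_times(segment_phases(clean[[i]]))
    det <- transition_times(segment_phases(noisy[[i]]))
    total <- total + length(ref)
    if (length(ref) && length(det))
      matched <- matched + sum(vapply(ref, function(t0)
        min(abs(det - t0)) <= 2 * cfg$frame_interval, logical(1L)))
  }
  expect_gt(total, 50L)
  expect_gte(matched / total, 0.9)
})

test_that("inverse-variance weighting follows the closed form", {
  expect_equal(weighted_mean_se(c(10, 20), c(1, 1)),
               c(mean = 15, se = 1 / sqrt(2)))
  wm <- weighted_mean_se(c(10, 20), c(1, 2))
  expect_equal(wm[["mean"]], 12)
  expect_equal(wm[["se"]], 1 / sqrt(1.25), tolerance = 1e-12)
  expect_equal(weighted_mean_se(7.3, 0.4), c(mean = 7.3, se = 0.4))
  expect_error(weighted_mean_se(c(1, 2), c(1, 0)), "SE")
})
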