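test_that("config invariants are enforced", {
  expect_error(sim_config(v_s = 0), "v_s")
  expect_error(sim_config(v_g = -1), "v_g")
  expect_error(sim_config(k_off = 0), "k_off")
  expect_error(sim_config(coop_on = -0.5), "coop_on")
  expect_error(sim_config(v_g = NaN), "finite")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("zero catastrophe rate yields a single deterministic growth phase", {
  cfg <- sim_config(v_g = 10, f_c = 0, rng_seed = 3L)
  tr <- simulate_dynamic_instability(cfg, duration = 100, n = 1)[[1L]]
  expect_equal(tr$positions[length(tr$positions)], 1000)
  expect_equal(nrow(tr$truth_phases), 1L)
  expect_equal(tr$truth_phases$phase, "growth")
})

test_that("growth-phase waiting times are exponential with mean 1/f_c", {
  # long observation so that right-censoring of the last phase is negligible
  cfg <- sim_config(v_g = 10, f_c = 0.005, f_r = 0, rng_seed = 11L)
  trajs <- simulate_dynamic_instability(cfg, duration = 3e4, n = 30)
  dur <- unlist(lapply(trajs, function(tr) {
    tp <- tr$truth_phases
    g <- tp$phase == "growth" & tp$t_end < 3e4
    (tp$t_end - tp$t_start)[g]
  }))
  expect_gt(length(dur), 100L)
  se <- sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - 1 / 0.005), 2 * se)
})

test_that("trajectories respect the seed boundary and tile the observation", {
  cfg <- di_config(seed = 5L)
  trajs <- simulate_dynamic_instability(cfg, duration = 600, n = 20)
  for (tr in trajs) {
    expect_true(all(tr$positions >= 0))
    tp <- tr$truth_phases
    expect_equal(tp$t_start[1L], 0)
    expect_equal(tp$t_end[nrow(tp)], 600)
    if (nrow(tp) > 1L)
      expect_equal(tp$t_start[-1L], tp$t_end[-nrow(tp)])
  }
})

test_that("long-run growth-time fraction matches 1/f_c over (1/f_c + 1/f_r)", {
  cfg <- sim_config(f_c = 0.01, f_r = 0.05, rng_seed = 21L)
  trajs <- simulate_dynamic_instability(cfg, duration = 5000, n = 40,
                                        seed_boundary = FALSE)
  frac <- vapply(trajs, function(tr) {
    tp <- tr$truth_phases
    sum((tp$t_end - tp$t_start)[tp$phase == "growth"]) / 5000
  }, numeric(1L))
  expected <- (1 / 0.01) / (1 / 0.01 + 1 / 0.05)
  expect_lt(abs(mean(frac) - expected), 3 * sd(frac) / sqrt(length(frac)))
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- di_config(seed = 9L)
  a <- simulate_dynamic_instability(cfg, duration = 300, n = 3, pos_noise_sd = 25)
  b <- simulate_dynamic_instability(cfg, duration = 300, n = 3, pos_noise_sd = 25)
  expect_identical(a, b)
  bc <- control_binding_config(seed = 9L)
  expect_identical(simulate_binding(bc, 10, 100), simulate_binding(bc, 10, 100))
  expect_identical(generate_nucleation_counts(5.9, 6, 3:10, 100, rng_seed = 2L),
                   generate_nucleation_counts(5.9, 6, 3:10, 100, rng_seed = 2L))
})

test_that("independent binding gives exponential dwells with mean 1/k_off", {
  cfg <- sim_config(k_on = 1e-3, k_off = 1 / 12, conc = 200, rng_seed = 13L)
  ev <- simulate_binding(cfg, mt_length = 20, duration = 400)
  d <- dwell_times(ev)   # censored excluded
  expect_gt(d$n, 1000L)
  expect_lt(abs(d$mean - 12), 2 * d$se)
  ks <- suppressWarnings(stats::ks.test(d$durations, "pexp", rate = 1 / 12))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero association rate produces zero events and censoring is flagged", {
  cfg0 <- sim_config(k_on = 0, rng_seed = 1L)
  expect_equal(nrow(simulate_binding(cfg0, 10, 100)), 0L)
  cfg <- control_binding_config(seed = 4L)
  ev <- simulate_binding(cfg, mt_length = 20, duration = 60)
  expect_true(any(ev$censored))
  expect_true(all(ev$t_off[ev$censored] == 60))
  expect_true(all(ev$t_off > ev$t_on))
})

test_that("dissociation cooperativity lengthens dwells at high occupancy", {
  base <- sim_config(k_on = 1e-3, conc = 2000, coop_on = 5, coop_off = 0,
                     label_frac = 1, rng_seed = 31L)
  coop <- sim_config(k_on = 1e-3, conc = 2000, coop_on = 5, coop_off = 2,
                     label_frac = 1, rng_seed = 31L)
  d0 <- dwell_times(simulate_binding(base, mt_length = 2, duration = 400))
  d1 <- dwell_times(simulate_binding(coop, mt_length = 2, duration = 400))
  expect_gt(d1$mean, d0$mean)
})

test_that("kymograph rendering is linear in occupancy and noiseless when asked", {
  cfg <- sim_config(f_c = 0, v_g = 20, psf_sigma = 0, noise_sd = 0,
                    rng_seed = 2L)
  tr <- simulate_dynamic_instability(cfg, duration = 200, n = 1)[[1L]]
  full <- matrix(1, nrow = length(tr$times),
                 ncol = round(max(tr$positions) / 8))
  attr(full, "times") <- tr$times
  ky <- render_kymograph(tr, full, cfg)
  on_lat <- ky$channels$lattice[ky$channels$lattice > 0]
  expect_equal(length(unique(on_lat)), 1L)   # single shared intensity
  half <- full; half[, seq_len(ncol(half) / 2)] <- 0.5
  attr(half, "times") <- tr$times
  ky2 <- render_kymograph(tr, half, cfg)
  seg <- seq_len(ncol(half) / 2 * 8 / cfg$pixel_size)
  expect_equal(mean(ky2$channels$probe[, seg]),
               mean(ky$channels$probe[, seg]) / 2)
  bad <- full; attr(bad, "times") <- tr$times + 1
  expect_error(render_kymograph(tr, bad, cfg), "time span")
})

test_that("rendering with a fixed seed is bit-identical on repeat", {
  cfg <- sim_config(f_c = 0, noise_sd = 5, psf_sigma = 1, rng_seed = 8L)
  tr <- simulate_dynamic_instability(cfg, duration = 100, n = 1)[[1L]]
  occ <- matrix(1, length(tr$times), 100)
  attr(occ, "times") <- tr$times
  expect_identical(render_kymograph(tr, occ, cfg),
                   render_kymograph(tr, occ, cfg))
})

test_that("nucleation counts follow the binomial sigmoid truth", {
  expect_equal(sigmoid_fraction(5.9, C = 5.9, s = 6), 0.5)
  expect_equal(sigmoid_fraction(0, C = 5.9, s = 6), 0)
  d0 <- generate_nucleation_counts(5.9, 6, 0, 100, rng_seed = 1L)
  expect_equal(d0$seeds_nucleated, 0L)
  d <- generate_nucleation_counts(5.9, 6, 10, 1e4, rng_seed = 17L)
  p <- sigmoid_fraction(10, 5.9, 6)
  se <- sqrt(p * (1 - p) / 1e4)
  expect_lt(abs(d$fraction - p), 3 * se)
})
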