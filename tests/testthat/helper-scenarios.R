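# Shared scenario builders for the simulation-recovery tests.

# Dynamic-microtubule regime used throughout the recovery checks.
di_config <- function(seed = 1L, ...) {
  sim_config(v_g = 7.6, v_s = 100, f_c = 0.004, f_r = 0.02,
             pixel_size = 160, frame_interval = 5, rng_seed = seed, ...)
}

# Single-molecule control: low-occupancy independent binding, mean dwell
# 1/k_off, sparse labeled molecules on long seeds.
control_binding_config <- function(seed = 1L, k_off = 1 / 12) {
  sim_config(k_on = 1e-3, k_off = k_off, conc = 50, coop_on = 0, coop_off = 0,
             label_frac = 1, rng_seed = seed)
}

# Spiking emulation: a micromolar unlabeled background nucleates sticky
# clusters that spread along the lattice while a labeled subset reports
# single-molecule dwells. The cooperativity factors are fixed study
# conditions (rationale in the methods vignette): strong on-cooperativity
# targets arrivals to cluster edges so the typical (not just mean) dwell
# lengthens as occupancy builds through the first intervals.
spiking_binding_config <- function(seed = 1L) {
  sim_config(k_on = 3e-4, k_off = 1 / 12, conc = 1000,
             coop_on = 30, coop_off = 10, label_frac = 0.25, rng_seed = seed)
}

# Noiseless sawtooth trajectory whose corners align with the frame grid.
sawtooth_trajectory <- function(v_g = 10, v_s = 100, period_g = 300,
                                n_cycles = 3, frame_interval = 5) {
  peak <- v_g * period_g
  period_s <- peak / v_s
  cycle <- period_g + period_s
  tt <- seq(0, n_cycles * cycle, by = frame_interval)
  tc <- tt %% cycle
  pos <- ifelse(tc <= period_g, v_g * tc, peak - v_s * (tc - period_g))
  end_trajectory(tt, pos, frame_interval = frame_interval)
}

# Transition times of a phase annotation (interior vertices).
transition_times <- function(ann) {
  v <- ann$vertices$time
  if (length(v) <= 2L) numeric(0) else v[-c(1L, length(v))]
}
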