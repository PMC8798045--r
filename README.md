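# mtkymo

Quantitative analysis of microtubule dynamics and lattice binding from
TIRF-microscopy kymographs, with a ground-truth stochastic generator for
end-to-end validation.

## The problem

In vitro reconstitution assays grow dynamic microtubules from stabilized
seeds under TIRF microscopy to measure how a microtubule-associated protein
changes microtubule behavior. The raw observables are kymographs — space-time
images with one axis along the filament — and the quantities of interest are:

* **dynamic-instability parameters** from phase-annotated end trajectories:
  growth rate `v_g`, shrinkage rate `v_s`, catastrophe frequency
  `f_cat = n_cat / Σt_growth`, rescue per shrinkage length
  `n_res / Σl_shrink`, and dynamicity
  `(Σl_growth + Σl_shrink) / t_obs`, each with its stated error model
  (counting errors `√n/denominator`; dynamicity error `pixel × N / T`);
* **templated nucleation** versus tubulin concentration, fitted with the
  Hill-type sigmoid `y(x) = x^s / (C^s + x^s)` (`C` = half-maximal
  concentration in µM, `s` = steepness);
* **end velocity and end intensity** in sliding 2-min windows with the
  leading-segment elimination rule and the −2.5 nm/s shrinking threshold,
  plus background-subtracted end-region probe intensity (5/3/5-pixel
  scheme);
* **single-molecule kinetics**: dwell times (mean ± SE, ECDFs), association
  rates `n / (t · L · c)` in events µm⁻¹ nM⁻¹ s⁻¹, and rank-sum
  comparisons between conditions;
* **curvature–intensity regression** (three-point circumcircle curvature,
  0.1 µm⁻¹ bins, 3-scaled-MAD outlier rejection, OLS on bin means);
* **lattice intensity analyses**: masked field intensity, seed-vs-lattice
  region comparison (Welch's t), stretch profiles, damage linescans,
  rolling-ball background subtraction, and the severing-protection
  statistic (per-field 20%-threshold time, inverse-SE² weighted means).

Because the corresponding experiments are imaging-based and not
recomputable from deposited raw data at desk scale, the package ships a
seeded stochastic generator — a two-state dynamic-instability simulator, a
cooperative lattice-binding Gillespie simulator, a kymograph renderer, and
a severing timecourse generator — so every stage is validated by parameter
recovery against known ground truth.

## Worked example

```r
library(mtkymo)

## simulate 200 microtubules at a slow-growth regime and recover the
## dynamic-instability parameters from their phase annotations
cfg <- sim_config(v_g = 7.6, v_s = 100, f_c = 0.004, f_r = 0.02, rng_seed = 42)
trajs <- simulate_dynamic_instability(cfg, duration = 600, n = 200)
compute_dynamics(lapply(trajs, segment_phases, use_truth = TRUE))
#> <dynamics_summary>
#>   growth rate:        7.6 +/- 3.2e-17 nm/s
#>   shrinkage rate:     100 +/- 1.6e-14 nm/s
#>   catastrophe freq:   0.003817 +/- 0.00018 /s  (n=440)
#>   rescue/length:      0.1846 +/- 0.02 /um  (n=87)
#>   dynamicity:         11.23 +/- 1.7 nm/s

## templated nucleation: binomial counts from a sigmoid truth, refit
counts <- generate_nucleation_counts(C = 5.9, s = 6, concentrations = 3:10,
                                     seeds_per_condition = 60, rng_seed = 42)
fit_sigmoid(counts)
#> <sigmoid_fit> y = x^s/(C^s + x^s)
#>   C = 6.017 uM (95% CI 5.796-6.238)
#>   s = 5.853 (95% CI 4.728-6.979)
#>   residual sd = 0.036

## single-molecule dwell times and association rate on a 30 um seed
ev <- simulate_binding(sim_config(k_on = 1e-3, k_off = 1/12, conc = 20,
                                  rng_seed = 42),
                       mt_length = 30, duration = 330)
d <- dwell_times(ev, interval = c(0, 300))
sprintf("dwell %.1f +/- %.1f s (n = %d)", d$mean, d$se, d$n)
#> "dwell 10.7 +/- 0.8 s (n = 155)"
association_rate(nrow(ev), 330, 30, 20)[["rate"]]
#> 0.000843
```

The recovered catastrophe frequency (0.0038 ± 0.0002 s⁻¹), rescue density
(0.18 ± 0.02 µm⁻¹), half-max (6.0 µM, CI covering 5.9), dwell mean
(10.7 ± 0.8 s for a 12 s truth) and association rate (0.84×10⁻³ for a
1×10⁻³ truth) all sit within ~2 SE of their generating values — the
recovery property the test suite asserts systematically.

Trajectories, events, counts and kymographs read/write through
`read_trace()`/`write_trace()`, `read_events()`, `read_counts()`,
`write_kymograph()` (multi-page TIFF + JSON sidecar), and
`run_pipeline()` executes configured stages end-to-end with a provenance
record (`inst/scripts/mtkymo.R` wraps it for the shell).

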