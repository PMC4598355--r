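# finwalk

Data-driven stochastic modelling of spontaneous zebrafish locomotion.

Zebrafish (*Danio rerio*) swim in a burst-and-coast style: speed is highly
variable, and fast turns cluster at low speed. `finwalk` models an
individual fish as a **persistent turning walker with variable speed** —
a planar agent whose speed *U* and turning speed *Ω* follow coupled
Ornstein–Uhlenbeck (O-U) processes

    dU = θ_u (μ_u − U) dt + σ_u dW
    dΩ = θ_ω (μ_ω + f_W − Ω) dt + f_c(U) dZ

where `f_W(φ_W, d_W) = sgn(φ_W) A exp(B d_W)` biases turning away from
the projected wall collision (distance `d_W`, signed approach angle
`φ_W`) and `f_c(U) = σ₀ (2σ₀/σ_ω)^(−U/μ_u)` shrinks the turning noise as
speed grows, reproducing the observed narrowing of the turning-speed
distribution with speed. Walkers are integrated by Euler–Maruyama at 5 Hz
in a 120-cm square arena with 10-cm rounded corners and inelastic wall
collisions. Wall-following (thigmotaxis) emerges from repulsion alone and
is predicted by the ratio σ_ω/θ_ω.

The package is aimed at researchers in computational ethology and
collective behaviour who need a calibrated, reproducible single-fish
locomotion model — as a building block for social/multi-agent extensions,
for robot-fish interaction studies, or as a realistic null model of
individual movement in a tank.

It provides the full workflow:

* **Kinematics & I/O** — `read_trajectory()`, `write_trajectory()`,
  `kinematics()`: speed, signed turning speed (anticlockwise positive),
  heading from tracked position/velocity CSVs.
* **Bout segmentation** — `segment_swimming()`: speed-threshold bouts
  (1 BL/s), gap joining (2 s), fixed 60-s segments.
* **Calibration** — `fit_ou_mle()` (exact closed-form O-U MLE via the
  AR(1) representation), `average_params()` (segment-count-weighted
  averaging), `fit_wall_response()` (LOESS + exponential two-stage fit of
  A and B), `estimate_sigma0()`.
* **Simulation** — `run_simulation()`, `em_step()`, with the calibrated
  per-fish (`fish_model_params()`) or global (`default_params()`)
  parameter bundles.
* **Validation statistics** — `acf_summary()` (lag-1 autocorrelation,
  correlation time, half-life), `joint_log_density()`,
  `occupancy_density()`.
* **Synthetic fixtures** — `gen_ou_exact()` (exact O-U transition
  sampler), `gen_wall_response()`, `gen_reference_trajectory()`.

A command-line wrapper (`exec/finwalk`) exposes the same steps as
`preprocess`, `calibrate`, `simulate`, `fixtures` and `validate`
subcommands; `run_pipeline()` chains them end to end.

## Worked example

Recover O-U parameters from a synthetic speed series generated at the
packaged global values, then simulate and summarise a wall-following
fish:

```r
library(finwalk)

# exact O-U sample at the global speed parameters, 2e5 steps at 5 Hz
x <- gen_ou_exact(ou_params(14.02, 0.59, 4.21), 2e5, dt = 0.2, seed = 1)
fit_ou_mle(x, dt = 0.2)
#> mu = 14.010, theta = 0.600, sigma = 4.224

# ~17 simulated minutes of the thigmotactic fish F7
sim <- run_simulation(fish_model_params("F7"), sim_config(T = 1000, seed = 7))
kin <- kinematics(sim$trajectory)
s <- acf_summary(kin$u, kin$dt)
c(mean_u = mean(kin$u), r1 = s$r1, tau = s$tau, half_life = s$half_life)
#> mean_u 20.14   r1 0.860   tau 1.33 s   half_life 0.92 s

mean(pmax(abs(sim$trajectory$x), abs(sim$trajectory$y)) > 50)
#> 0.38
```

The MLE lands within 2% of the generating triple. The simulated F7 swims
at about 20 cm/s (its calibrated equilibrium is μ_u = 20.96 cm/s, pulled
down by inelastic wall contacts) with a speed autocorrelation half-life
just under a second, and spends 38% of its time in the outer 10-cm band
of the tank against that band's 31% area share — the emergent
wall-following this parameter set is known for.

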