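---
title: "Modelling spontaneous zebrafish locomotion with coupled Ornstein-Uhlenbeck processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spontaneous zebrafish locomotion with coupled Ornstein-Uhlenbeck processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Small schooling fish such as zebrafish (*Danio rerio*) do not swim at
constant speed: their burst-and-coast locomotion produces large, rapid
speed fluctuations, and the variability of their turning depends strongly
on how fast they are moving. `finwalk` models an individual fish as a
*persistent turning walker with variable speed*: a planar agent whose
speed $U_t$ and turning speed $\Omega_t$ each follow a mean-reverting
Ornstein-Uhlenbeck (O-U) process,

$$
\mathrm{d}U_t = \theta_u(\mu_u - U_t)\,\mathrm{d}t + \sigma_u\,\mathrm{d}W_t,
\qquad
\mathrm{d}\Omega_t = \theta_\omega\bigl(\mu_\omega + f_W - \Omega_t\bigr)\,
  \mathrm{d}t + f_c(U_t)\,\mathrm{d}Z_t .
$$

An O-U process relaxes towards its equilibrium $\mu$ at rate $\theta$
(autocorrelation time $1/\theta$) and has stationary variance
$\sigma^2/2\theta$ — exactly the structure seen in tracked-fish speed and
turning series, which are approximately Gaussian with exponentially
decaying autocorrelation. Two modifications couple the walker to its
environment and to itself:

* **Wall avoidance.** $f_W(\phi_W, d_W) = \mathrm{sgn}(\phi_W)\,A\,
  e^{B d_W}$ shifts the turning equilibrium away from the projected
  collision with the tank boundary, where $d_W$ is the distance to that
  collision along the current heading and $\phi_W$ the signed angle
  between the heading and the boundary normal at the hit point. The bias
  is bounded by $A$ and decays with distance ($B < 0$). A hard boundary
  backs this up: a walker that would cross the wall keeps its previous
  position and loses all speed (a fully inelastic collision); its turning
  speed is not reset. The square arena's corners are rounded by
  quarter-circles of radius $R_c$ so that two perpendicular walls never
  compete at a sharp vertex.
* **Speed-turn coupling.** $f_c(U) = \sigma_0 (2\sigma_0/\sigma_\omega)
  ^{-U/\mu_u}$ replaces the constant turning-noise amplitude. It equals
  the saturation value $\sigma_0$ at $U = 0$ and $\sigma_\omega/2$ at the
  mean speed, so fast turns concentrate at low speed. This reproduces both
  the observed joint speed-turn density (narrowing of the turning
  distribution with speed) and the sharply peaked, heavy-tailed marginal
  distribution of turning speed.

Trajectories are integrated by the Euler-Maruyama scheme at
$\Delta t = 0.2$ s, the tracking acquisition step; the heading advances by
$\Omega_t \Delta t$ (wrapped to $[-\pi, \pi)$) and the position by
$U_t \Delta t$ along the new heading. Turning speed is clipped to
$\pm 15$ rad/s, the largest rate observed in (and near the Nyquist limit
$\pi/\Delta t \approx 15.7$ rad/s of) 5 Hz data.

## Calibration pipeline

1. **Kinematics.** Speed is the norm of the tracked velocity; turning
   speed is the signed angle between consecutive velocity vectors divided
   by $\Delta t$, positive for anticlockwise (left) turns; heading is the
   velocity orientation, held through stationary samples.
2. **Bout segmentation.** Swimming is speed above 1 BL/s (3 cm/s at the
   3-cm body length) on a 3-sample moving average; sub-threshold dips
   shorter than $\tau_s = 2$ s do not interrupt a bout; bouts are cut into
   60-s segments (anchored at the bout start, remainder discarded), which
   carry the original unsmoothed data.
3. **O-U MLE.** On each segment's speed and turning series the O-U
   parameters are estimated by exact maximum likelihood using the AR(1)
   conditional-Gaussian representation: conditional on the first
   observation the likelihood is maximised in closed form by least squares
   of $x_{k+1}$ on $x_k$, and $(\mu, \theta, \sigma)$ follow from the
   fitted coefficient $a = e^{-\theta\Delta t}$ and residual variance. The
   estimates satisfy the score equations exactly; series whose fitted $a$
   falls outside $(0,1)$ are rejected as non-mean-reverting.
4. **Averaging.** Per-fish parameters are unweighted means over that
   fish's segments; the global set weights each fish by its segment count
   $n_i$: $\tilde\mu = \sum_i n_i \mu[F_i] / \sum_i n_i$. The packaged
   per-fish table and its weighted means (e.g. $\tilde\mu_u = 14.02$ cm/s,
   $\tilde\theta_\omega = 2.74$ s$^{-1}$) are available via
   `fish_params()` and `default_params()`.
5. **Wall response.** For every sample the projected collision gives
   $(d_W, \phi_W)$; the wall-corrected turning speed $\omega_c$ is
   $+|\omega|$ when the turn steers away from the collision and
   $-|\omega|$ otherwise. $A$ and $B$ are fitted in two stages: a LOESS
   smooth of $\omega_c$ against $d_W$ (or time-to-collision $t_W$),
   then nonlinear least squares of $A e^{Bz}$ to the smoothed curve on a
   100-point grid, initialised from a log-linear fit to its positive part.
6. **Saturation amplitude.** $\sigma_0 = \max(\omega)\sqrt{2\tilde
   \theta_\omega}/2$ makes the stationary two-sigma band of a turning
   process running at the saturated amplitude cover the observed turning
   range; with $\max(\omega) = 10$ rad/s and $\tilde\theta_\omega = 2.81$
   s$^{-1}$ this gives $\sigma_0 \approx 12$.

## Parameter conventions and known discrepancies in the source tables

Two inconsistencies in the published parameter set are deliberately
surfaced rather than hidden:

* The printed global list swaps $\tilde\theta_u$ and $\tilde\sigma_u$
  (4.21 vs 0.59) relative to the per-fish table rows. The package uses the
  table-row semantics ($\theta_u = 0.59$ s$^{-1}$, $\sigma_u = 4.21$
  cm s$^{-1}$ s$^{-1/2}$): only that assignment is consistent with the
  reported speed autocorrelation half-life of about 1.37 s
  ($\theta_u \approx \ln 2 / 1.37 \approx 0.5$).
* $\tilde\theta_\omega$ appears both as 2.74 (weighted table mean) and
  2.81 (the value plugged into the $\sigma_0$ rule). Both are retained:
  the defaults table stores 2.74, the configuration key
  `calibration$sigma0_theta` defaults to 2.81.

The noise units as printed ("cm s$^{-1}$", "rad s$^{-1}$") omit the
Wiener $s^{-1/2}$ factor; the package documents the true units and keeps
the printed numbers.

The simulation amplitude $A = 6.75$ rad/s is three times the fitted
$2.25$ rad/s. The amplification compensates for the scarcity of samples
very close to the boundary in the fitting stage and the simplicity of the
repulsion model; without it walkers under-turn near walls.

## Numerical and design choices

* **Turning-sign convention.** Anticlockwise (left) turns are positive
  throughout, implemented as the sign of the planar cross product
  $v_t \times v_{t+\Delta t}$. Exactly antiparallel consecutive velocities
  (rotation direction genuinely ambiguous, angle $\pi$) take the sign of
  the most recent nonzero turn, defaulting to positive — a deterministic,
  measure-zero tie-break. The forward difference leaves the last sample
  undefined; it is zero-padded and flagged so all kinematic series stay
  aligned.
* **$\phi_W$ sign.** The boundary normal's orientation is fixed by
  requiring the wall bias to be repulsive: $\phi_W > 0$ exactly when the
  inward normal lies anticlockwise of the heading, i.e. when a left turn
  increases the projected collision distance. Head-on approaches
  ($\phi_W = 0$) contribute no bias and take the negative branch of the
  wall-corrected sign rule; both situations are measure-zero.
* **Segmentation boundaries.** A dip of duration exactly $\tau_s$ splits
  ("join" requires strictly shorter); threshold comparison is strictly
  "above"; smoothing is applied once to the whole series, and the 3-sample
  window erodes one sample from each end of a raw dip.
* **Speed floor.** The speed SDE admits negative excursions; the
  simulator floors speed at zero, since speed is a norm. With the
  calibrated parameters the floor binds rarely (the stationary mean is
  3.6 standard deviations above zero).
* **Coupling argument.** $f_c$ is evaluated at the pre-update speed, the
  explicit-Euler reading of the coupled system.
* **LOESS bandwidth and degree.** The wall-response smoother uses span
  0.2 with local degree 2. The fitted exponential has a decay length of
  about 9 cm over a 0-60 cm abscissa; a local-linear smoother at the
  conventional span 0.5 carries a curvature (attenuation) bias of order
  10% on the amplitude that no realistic noise level hides, while
  degree 2 at span 0.2 recovers noiseless input to four decimal places
  and noisy input well within the sampling spread. Both knobs are exposed
  arguments.
* **Exact O-U sampler.** Synthetic O-U fixtures come from the exact
  transition density (no discretisation error), initialised from the
  stationary distribution by default so finite-sample statistics match
  stationary theory; walker-style fixed initialisation is selectable.
* **RNG contract.** One generator, seeded from the configuration, two
  draws per step in fixed order (speed, then turning), making every
  simulation bit-reproducible from its seed.

## What the synthetic benchmarks do and do not show

The tracked-fish recordings behind the published tables are not publicly
deposited, so the test-suite operates on synthetic data whose generating
parameters are the published ones: exact O-U series at the global speed
and turning triples (MLE recovery to within 2-5%), wall-response scatter
at the fitted $(A, B)$ with 1 rad/s Gaussian noise (recovery within the
published spreads $\pm 0.3$ and $\pm 0.04$), and full walker simulations
(containment, clamp, heading range, stationary moments, the
joint-density narrowing, and the thigmotaxis ranking by
$\sigma_\omega/\theta_\omega$). Problem sizes are chosen to keep
Monte-Carlo error well inside those bands: $2\times 10^5$ samples for MLE
recovery, 2,000 points for the wall fit, $10^5$-step free-space runs for
stationary moments, $10^4$-step walled runs for occupancy.

Synthetic benchmarks exercise the estimators under the model's own
assumptions. They do not emulate tracking artefacts (Kalman smoothing of
velocities, missed detections), freezing and thrashing behaviours, or the
heavy non-Gaussian tails of real turning data — the aspect of real fish
the coupling function is designed to approximate, not reproduce exactly.
Passing them shows the pipeline is internally consistent and the
estimators are correct, not that the model captures all features of live
zebrafish.

## Known limitations

* Single fish only; no social interactions or response to moving stimuli.
* The wall model is repulsion-only; wall-following arises (for low
  $\sigma_\omega/\theta_\omega$) as an emergent property, not from an
  attraction term.
* Calibration assumes regularly sampled, Gaussian O-U data; irregular
  sampling and filtering-based inference are out of scope.
* The Euler-Maruyama scheme is first order; at the default
  $\Delta t = 0.2$ s its stationary turning variance differs from the
  continuous process by the factor $2/(2 - \theta_\omega \Delta t)$
  (about 38% in variance for $\theta_\omega = 2.74$), matching the
  discrete sampling of the data it is calibrated to. The test-suite
  verifies the discretisation converges to the exact process as
  $\Delta t \to 0$.
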