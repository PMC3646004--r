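# statewalk

Bayesian behavioural-state inference for animal movement trajectories, and
tools for studying how the **temporal grain** (the interval between
successive position fixes) changes what such models infer.

Telemetry studies routinely fit multi-state random-walk models to GPS
trajectories to label each location with a latent behavioural state —
typically a slow, tortuous "area-restricted" mode (foraging, resting) versus
a fast, directionally persistent "transiting" mode. Because movement rates
and turning angles are computed *between* fixes, both metrics depend
mechanically on the sampling interval: coarser sampling smooths paths,
lowers apparent speed and flattens turning-angle distributions. `statewalk`
lets you quantify that degradation end to end: simulate a ground-truthed
two-regime trajectory, observe it through an emulated GPS collar, thin it to
any interval, refit the model, and compare what the model believes against
what generated the data.

## The model

A trajectory is reduced to movement rates `r_t` (inter-fix distance over
elapsed time) and turning angles `phi_t` (signed change of direction,
quadrant-aware, in `(-pi, pi]`). Each step belongs to one of `N` latent
states (`N` = 1, 2 or 3); given its state `z_t = j`, the step's metrics are
independently

- `r_t ~ Weibull(a_j, b_j)`, with mean `b_j * Gamma(1 + 1/a_j)`;
- `phi_t ~ wrapped Cauchy(mu_j, rho_j)`, where `rho_j` in `[0, 1)` is the
  concentration (0 = uniform turning, 1 = point mass).

States are assigned independently per step with mixing weights `w`
(no switching dynamics). Priors follow the vague choices standard for this
model: `Gamma(0.3, 0.01)` (mean 30, variance 3000) on every `a_j` and
`b_j`, uniform priors on `mu_j` and on `rho_j in (0, 0.99)`, and a
symmetric `Dirichlet(1)` on `w`. Fitting is by Metropolis-within-Gibbs:
exact conjugate updates for labels and weights, adaptive random-walk
Metropolis for the continuous parameters (100,000 iterations after a
2,000-iteration burn-in by default, keeping every 10th sweep). Label
switching is resolved afterwards with the Stephens KL relabeling algorithm,
and summaries are *posterior mean densities* — the average of the sampled
parametric densities, which again integrate to one — with pointwise SD
bands, posterior mean turn vectors `(rho cos mu, rho sin mu)` with RMS
radii, and per-step state probabilities.

## Worked example

Simulate the reference two-regime trajectory (487 points; alternating
straight and area-restricted segments of 20-100 points), convert it to
rates and angles, fit the two-state model and score the classification:

```r
library(statewalk)

traj <- simulate_trajectory(generator_config(seed = 7))
traj
#> Two-regime synthetic trajectory: 487 points, 9 segments
#>   points per regime: area_restricted = 276, straight = 211

steps <- to_step_series(traj$x, traj$y, traj$t, interval = 1)
steps
#> Step series at interval 1 - 486 valid rates, 485 valid angles

chain <- run_chain(steps, n_states = 2,
                   cfg = mcmc_config(n_iter = 20000, burn_in = 2000, seed = 7))
chain <- relabel_stephens(chain)
posterior_summary(chain)
#> Posterior summary, 2 state(s):
#>   state 1: mean rate 0.4654 (sd 0.0307); mean vector (-0.405, -0.009), |v| = 0.406 (sd 0.064)
#>   state 2: mean rate 0.9243 (sd 0.0277); mean vector (0.742, -0.007), |v| = 0.742 (sd 0.033)

probs <- state_probabilities(chain)
truth <- traj$state_true[steps$from[steps$valid_r] + 1]
sprintf("accuracy: %.1f%%", 100 * classification_accuracy(probs, truth))
#> [1] "accuracy: 90.1%"
```

Reading the summary: state 1 (canonically the slower state) moves at about
half the speed of state 2 and its mean turn vector points down the negative
x-axis — turns concentrated near `pi`, the reversal-prone area-restricted
signature — while state 2's vector lies on the positive x-axis (persistent
heading). The accuracy line scores each step's maximum-probability state
against the regime that generated it, maximised over label permutations.

To study degradation, sweep the subsampling factor and watch both turn
vectors shrink towards the origin (turning angles become uniform) and mean
rates fall:

```r
cfg <- experiment_config(generator = generator_config(seed = 1),
                         sweep = c(1, 3, 6, 12),
                         mcmc = mcmc_config(n_iter = 20000, burn_in = 2000))
out <- run_resolution_sweep(cfg)
out$trends[, c("factor", "state", "weib_mean", "mv_norm", "proportion")]
```

`observe_gps()` + `screen_fixes()` provide the collar-style variant
(dropouts, 2D/3D flags, PDOP screening, intervals in seconds), and
`run_equal_n_control()` refits the finest-resolution data at the coarse
sample size to show the degradation is not a small-`n` prior artifact.
`plot_posterior_panels()`, `plot_mean_vectors()` and
`plot_trajectory_states()` reproduce the standard displays (density curves
with grey one/two-SD bands, unit-circle vector diagrams, and
probability-coloured trajectories).

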