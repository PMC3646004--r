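---
title: "Behavioural-state inference and temporal resolution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural-state inference and temporal resolution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, what the synthetic-data generator does and does not emulate,
the numerical choices inside the sampler and summaries, and the design
decisions taken where more than one reasonable option existed.

## The inference model

A trajectory enters the model only through its movement rates
$r_t$ (Euclidean inter-fix distance divided by elapsed time) and turning
angles $\phi_t \in (-\pi, \pi]$ (signed heading change between successive
displacement vectors, counter-clockwise positive). Each step carries a
latent behavioural state $z_t \in \{1, \dots, N\}$, $N \le 3$, and given
$z_t = j$ the step's metrics are conditionally independent:

$$r_t \sim \mathrm{Weibull}(a_j, b_j), \qquad
  \phi_t \sim \mathrm{wrappedCauchy}(\mu_j, \rho_j),$$

with the Weibull in shape/scale form (mean $b_j\,\Gamma(1 + 1/a_j)$, the
quantity we report as a state's mean movement rate) and the wrapped Cauchy
density $\frac{1}{2\pi}\frac{1-\rho^2}{1+\rho^2-2\rho\cos(\phi-\mu)}$,
whose mean resultant vector is $(\rho\cos\mu, \rho\sin\mu)$. States are
assigned independently per step through mixing weights $w$; there is
deliberately **no switching/transition model** — temporal persistence of
behaviour must come from the data, not the prior, which is exactly what
makes the model a clean probe of how much behavioural signal survives
subsampling.

Assumptions worth keeping in mind: steps are conditionally independent
given states (no autocorrelation within a state); rates are strictly
positive with no observation-error model (fix error propagates directly
into $r_t$ and $\phi_t$); and the two metrics are independent within a
state, so rate-angle correlation is expressed only through state
membership.

### Priors

Vague priors throughout: $a_j, b_j \sim \mathrm{Gamma}(0.3,\ 0.01)$
(mean $0.3/0.01 = 30$, variance $0.3/0.01^2 = 3000$), $\mu_j$ uniform on
the circle, $\rho_j \sim U(0, \rho_{\max})$ and
$w \sim \mathrm{Dirichlet}(1, \dots, 1)$. The upper bound
$\rho_{\max} = 0.99$ keeps the angle density bounded; it is a configurable
`prior_spec()` field, and with $\rho$ posteriors below 0.9 in every fit we
have run it is not an active constraint. The symmetric Dirichlet is the
minimal prior that closes the independent-assignment model into a proper
mixture.

## The synthetic-data generator

`simulate_trajectory()` builds a ground-truthed two-regime track: segments
alternate between *straight* (transiting) and *area-restricted* behaviour;
each segment's length in points is uniform on $\{20, \dots, 100\}$, the
final segment truncated so the track totals exactly 487 points (both
bounds and the total are `generator_config()` fields). Within a segment
with turn parameters $(\mu, \kappa)$ and step-innovation SD $\sigma$:

- the heading accumulates von Mises$(\mu, \kappa)$ turns;
- the step length follows the autocorrelated positive random walk
  $d_{i+1} \sim N(d_i, \sigma^2)$, redrawn until positive (rejection
  truncation at zero — the distinct *initial* step lengths per regime only
  matter because later lengths depend on the previous one);
- each segment restarts at the regime's initial step length with a heading
  drawn uniformly on the circle. The restart heading is uniform for *both*
  regimes — for area-restricted segments this is our assumption (a regime
  that reorients freely has no preferred restart direction).

### The default calibration, and why

The package ships its regime calibration as data
(`inst/extdata/regimes-default.yaml`), not as code constants, and
`read_regimes()` refuses configurations with missing entries rather than
guessing. The defaults are the package's own choice of a realistic
two-mode forager:

| regime | $\mu$ | $\kappa$ | $d_0$ | $\sigma$ |
|---|---|---|---|---|
| straight | $0$ | $10$ | $1.0$ | $0.1$ |
| area-restricted | $\pi$ | $1$ | $0.25$ | $0.1$ |

$\kappa = 10$ gives near-persistent travel (circular SD about 18 degrees);
$\kappa = 1$ with mean $\pi$ gives the broad, reversal-biased turning of
area-restricted search; the 4:1 initial-step ratio encodes that animals
move slower while area-restricted; and a common innovation SD of one tenth
of the transit step lets speeds drift smoothly within segments, so the two
regimes' rate distributions overlap in their tails rather than being
trivially separable. Length units are arbitrary (one unit is the nominal
transit step); time units are one step, mapped to 300 s per fix by the
collar emulator. These values were fixed once, before any model fitting,
and are deliberately not tuned against downstream results; classification
accuracy and trend magnitudes quoted anywhere in this package are
properties of *this* calibration.

### What the collar emulator does and does not capture

`observe_gps()` emulates the observation process: one candidate fix per
nominal interval (default 300 s), independent dropouts, isotropic Gaussian
position noise, a 2D/3D flag (a fix computed from only three satellites is
"2D") and a log-normal PDOP draw; `screen_fixes()` then applies the
standard quality rule of discarding 2D fixes whose PDOP exceeds a
threshold (default 5, configurable — with the default mix of
`p_2d = 0.15` and PDOP log-normal(1, 0.5), dropouts plus screening remove
roughly 10% of fixes). Not emulated: habitat- or behaviour-dependent fix
failure, autocorrelated position error, PDOP-dependent error magnitude,
and den/roost gaps — real collar data fail in structured ways that this
independent-thinning model cannot produce. Passing tests therefore show
the *pipeline* behaves correctly under honest missingness, not that it is
robust to every pathology of field data.

## Preprocessing rules

Subsampling selects fixes on the grid `anchor + k * interval`
(anchor = first fix, matching tolerance default 0; a positive tolerance
accommodates jittered real timestamps, first fix per slot wins). Missing
slots are simply absent — no interpolation — so the fixes used at one
interval are not necessarily a subset of those used at another. A rate is
valid only if its two fixes occupy *consecutive* grid slots; an angle only
if its three fixes do; invalid values are excluded from the likelihood
individually, never whole tracks. Steps with a valid rate but no valid
angle contribute their Weibull factor only (the likelihood factorises, and
discarding them would waste data the conversion legitimately produced).
Exact reversals get $\phi = +\pi$; ties in the quadrant-aware arctangent
are otherwise impossible on continuous data.

## The sampler

`run_chain()` is a single-chain Metropolis-within-Gibbs sampler (multiple
chains = multiple seeds):

1. **Labels**: each $z_t$ from its exact conditional
   $P(z_t = j) \propto w_j f_j(r_t, \phi_t)$, normalised in log space.
2. **Weights**: conjugate $w \sim \mathrm{Dirichlet}(1 + n_1, \dots)$.
3. **Per-state parameters**: random-walk Metropolis on $\log a_j$ and
   $\log b_j$ (Jacobian included), a wrapped walk on $\mu_j$, and a walk
   on $\rho_j$ reflected into $(0, \rho_{\max})$ — each a symmetric
   proposal, so detailed balance holds per block. A state currently
   holding no steps samples its prior.

Defaults mirror the study protocol: 100,000 iterations after 2,000
burn-in, thinning 10. During burn-in only, proposal SDs adapt by
Robbins-Monro on the log scale towards an acceptance rate of 0.3 (clamped
to $[10^{-3}, 10]$); adaptation is frozen afterwards so the sampling phase
targets the exact posterior. Initial values: method-of-moments Weibull
fits on a random contiguous-block split of the *sorted* rates (random cut
points, blocks of at least two), so a bimodal rate distribution starts
with distinct state means; $\mu = 0$, $\rho = 0.5$, uniform weights,
uniform random labels.

Numerical choices that matter:

- The Weibull log density is computed directly in log space
  (`ldweibull`): the textbook route through `dweibull(log = TRUE)`
  returns NaN once $(r/b)^a$ overflows, which the vague Gamma prior makes
  reachable whenever a state is briefly empty.
- If every state's density underflows to zero at some step (possible at
  extreme parameter excursions), the label conditional is a 0/0; we break
  the tie with a uniform draw rather than aborting the chain.
- Non-finite proposals or acceptance ratios are rejected, never
  propagated.

## Relabeling and summaries

The mixture posterior is invariant under label permutation, so chains can
swap state identities. `relabel_stephens()` minimises, by coordinate
descent over per-sample permutations (all $N! \le 6$ enumerated), the KL
divergence between each sample's classification-probability matrix
$P^{(m)}_{tj} \propto w_j f_j(r_t, \phi_t)$ and their running average. A
pure batch descent started from identity permutations has a degenerate
fixed point when the chain splits its time evenly between two labellings
(the average is then symmetric), so an online first pass aligns each
sample to the running average of its predecessors before batch refinement;
the KL objective is non-increasing from there and convergence is typically
immediate. Relabeling permutes parameters, weights and labels together,
leaving every sample's likelihood bit-for-bit unchanged. Afterwards states
are put in the presentation order *state 1 = smaller posterior mean rate*
(the slow, area-restricted mode first).

Posterior summaries follow the averaged-density convention: the reported
density for a state is $\bar f(x) = M^{-1}\sum_m f(x;\theta_j^{(m)})$ — a
mean of densities, hence itself a density — with pointwise SD bands; the
mean movement rate is the average of $b\,\Gamma(1+1/a)$ across samples
with its SD; the mean turn vector averages $(\rho\cos\mu, \rho\sin\mu)$,
and its quoted SD is the *planar RMS* deviation of the sample vectors from
their mean (a single circle radius; the alternative, per-component SDs,
conveys little more on a plot and is not what the standard displays draw).
Per-step state probabilities are sample frequencies of the labels — the
output is never discretised, though `classification_accuracy()` will
discretise by maximum probability (ties to the lower state index) and
score against known regimes, maximised over label permutations.

One honest instability: $\Gamma(1 + 1/a)$ explodes as $a \to 0$, so if a
weakly supported state is empty for even a handful of kept samples (its
parameters then being prior draws), the *mean* of $b\,\Gamma(1+1/a)$ can
be astronomically large while the posterior bulk is perfectly sensible.
We report the summary as defined rather than switching to a robust
location estimate; users fitting coarse, small-$n$ series should check
`state_probabilities()` and the acceptance rates before trusting a
posterior mean rate.

## The degradation experiments

`run_resolution_sweep()` chains the whole pipeline per sweep point —
subsample, convert, fit, relabel, summarise — recording per state the
posterior mean rate, mean vector and its norm, state proportion, valid
data counts, and accuracy when truth is available; errors at one point are
reported and skipped, not fatal. The synthetic sweep uses factors 1-12 on
the clean 487-point trajectory; the collar-style sweep uses intervals
300-3600 s in 300-s steps on an 818-point trajectory observed through the
collar emulator — one collar's worth of data, chosen to match the
empirical volumes such deployments produce, which also keeps both states
populated at the coarsest grain.

`run_equal_n_control()` separates the two things coarsening does
(lengthen the interval, shrink the sample) by refitting the finest series
on a random *contiguous* window with as many steps as the coarsest series.
A uniformly random subset would be wrong twice over: it destroys the grid
adjacency that turning angles require (in a probe, 8 of 81 angles
survived), and it breaks within-segment continuity. The verdict compares
turning-angle concentration averaged across states, because a short window
need not contain the two regimes in the track-wide proportions, making
per-state comparison ill-posed.

## Test problem sizes

The test suite runs every Monte-Carlo check at sizes chosen to keep the
whole suite in a coffee break while leaving comfortable statistical
margins: distribution laws at $10^5$-$10^6$ draws with 3-SE bounds;
label-conditional enumeration at $10^5$ sweeps of a 4-point dataset
(total-variation tolerance 0.01); the quadrature cross-check of the
single-state posterior on 5 points against a $400^2$ log-grid, with
MCMC batch-means SEs; parameter recovery on a 500-step known mixture;
pipeline and trend checks at 8,000-20,000 MCMC iterations, with the full
100,000-iteration protocol exercised by `scripts/acceptance.R`.

## Known limitations

- No switching dynamics: state sequences are exchangeable a priori, so
  runs of behaviour shorter than a few steps are hard to recover at any
  resolution.
- No observation-error state space: position noise biases rates upward at
  fine intervals (noise is a larger fraction of short steps).
- The generator's calibration is synthetic: chosen to be ecologically
  plausible, not fitted to any animal, so quantitative results (e.g.
  classification accuracy) characterise the calibration as much as the
  method.
- Single-chain inference inherits the usual caveat: multimodality
  (notably the one-populated-state mode at coarse grains) is explored, not
  escaped, within one run; compare seeds when in doubt.
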