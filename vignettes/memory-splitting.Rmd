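---
title: "Splitting probabilities for random walks with memory: models, solver, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting probabilities for random walks with memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memfp)
```

## The problem

A particle starts at $x_0$ between two perfectly absorbing targets at $0$
and $L$.  The splitting probability $\pi_2$ is the chance it reaches the
target at $L$ before the one at $0$.  For any memoryless symmetric walk the
answer is the gambler's-ruin line $\pi_2 = x_0/L$.  For particles in
polymer fluids, for monomers of macromolecules, or for tagged particles in
crowded channels the motion has memory, and the Markovian line can be badly
wrong in either direction.

`memfp` treats the wide class of 1D processes that are Gaussian,
continuous, unbiased, non-smooth, and have stationary increments.  Such a
process is completely characterised by its mean squared displacement
$\psi(t) = \langle [x(t)-x(0)]^2\rangle$, assumed to grow as
$\kappa t^{2H}$ at long times with $0 < H < 1$.  Four MSD families ship
with the package:

* `msd_powerlaw(kappa, H)` — scale-invariant (fractional Brownian motion);
  subdiffusive for $H<1/2$, superdiffusive for $H>1/2$;
* `msd_bidiffusive(B)` — $\psi(t) = t + B(1-e^{-t})$, white noise plus a
  single-relaxation-time colored noise (a Maxwell-fluid tracer);
* `msd_viscoelastic(amplitude, tau0, alpha)` — the crossover law
  $\psi = A f(t/\tau_0)$,
  $f(y) = [(y-\alpha+1)\gamma(\alpha,y) + y^{\alpha}e^{-y}]/\Gamma(\alpha)$,
  induced by a power-law friction kernel cut off at the memory time
  $\tau_0$: subdiffusion with exponent $\alpha$ below $\tau_0$, diffusion
  above.  The prefactor (a temperature–friction combination) is carried as
  one fitted amplitude and never decomposed;
* `msd_rouse(N)` — first-monomer MSD of a discrete bead–spring chain with
  free ends, from the cosine normal-mode sum; transient subdiffusion with
  local exponent $\approx 1/2$ and centre-of-mass diffusion $2t/N$ beyond
  the Rouse time.

Tabulated MSDs (`msd_tabulated()`) are interpolated monotonically in
log–log space and extended by their declared power-law tail, because the
solver integrates over roughly ten decades of time.

## The self-consistent theory

The key objects are the post-first-passage mean trajectories $\mu_1(t)$,
$\mu_2(t)$: the average position a time $t$ after the first contact with
target 1 or 2, were the motion allowed to continue.  Averaging the position
of the free process over which target is hit first gives the partition
identity
$$x_0 = \lim_{t\to\infty}\left[\pi_1 \mu_1(t) + \pi_2 \mu_2(t)\right],$$
so $\pi_2$ follows from the large-time limit of
$(x_0-\mu_1)/(\mu_2-\mu_1)$ — a limit that exists even when both curves
diverge, as they do for superdiffusive models.  The curves themselves obey
a self-consistent integral equation built from two Gaussian densities: the
free propagator $p(x_i,t)$ centred at $x_0$ and the post-hit density
$q_j(x_i,t)$ centred at $\mu_j(t)$, coupled through the conditional-mean
weight $M(t,\tau) = [\psi(t{+}\tau)+\psi(t)-\psi(\tau)]/[2\psi(t)]$
(`correlation_M()`).  The closure assumes that post-first-passage paths
remain Gaussian with the covariance of the original process; no
alternative closure is implemented.

For Brownian motion $M \equiv 1$, the equation collapses, $\mu_j \equiv
x_j$, and $\pi_2 = x_0/L$ exactly — the built-in analytic control.

### How the solver works, and why not plain relaxation

`solve_splitting()` discretises $\mu_{1,2}$ on a geometric grid of 64 lags
spanning $[10^{-4}, 10^{4}]\,t_c$, where $t_c$ solves $\psi(t_c)=L^2$, and
evaluates the time integral by trapezoidal quadrature in $\log t$ with 32
nodes per decade over $[10^{-8}, 10^{6}]\,t_c$ (the deep lower end matters
for strongly subdiffusive models, whose integrands concentrate at short
times).  Between nodes $\mu$ is interpolated linearly in log-time; below
the first node it ramps to the target value ($\mu_j(0) = x_j$: the
trajectory starts on the target); above the last node it follows a
power-law tail anchored to the last node, whose exponent is refitted
between iterations and frozen within each Newton step so the Jacobian
stays exact.

A subtlety dictates the iteration scheme: the equation admits the exact
spurious solution $\mu_1 = \mu_2 \equiv x_0$ (the unconditional mean, for
which $q_j = p$ identically), connected to the physical solution by a
soft, nearly-null direction of the linearised operator.  Damped fixed-point
relaxation of the linearised system drifts along that direction into the
collapsed solution.  The implementation therefore uses a damped Newton
method on the full nonlinear system — the Jacobian includes the derivative
of the Gaussian weights $q_j$ with respect to $\mu_j$, which is what
separates the two basins — with a residual-norm line search, starting from
the Markovian ansatz.  The outer scalar fixed point
$\pi_2 = g(\pi_2)$ (ratio extrapolation given the solved curves) is
accelerated by a safeguarded secant update; the plain update contracts at
$\approx 0.96$ per round for strongly subdiffusive models.  The ratio limit
is extrapolated from the last grid decade by Aitken's method on the
geometric node sequence, with the relative drift over the last decade
reported as a convergence diagnostic.

Correctness is defined by the residual: converged solutions report a
root-mean-square residual below $10^{-8} L$ on the full discretised
system, and `splitting_residual()` recomputes the residual independently
for any candidate curves, with an algebraic tail estimate of the
quadrature truncation (the individual $p$ and $q$ terms decay only like
$t^{1-3H}$ after the log-substitution; their sum cancels faster at a
solution, so the tail is estimated on the sum).

Defaults worth knowing: tolerance $10^{-8}$ (RMS residual over $L$);
starts within $10^{-6}L$ of a target short-circuit to the deterministic
answer with a warning; `splitting_grid()` exposes all spans.  A solve at
the default grid takes a few seconds; accuracy was checked against grids
refined to 96 nodes and 48 nodes/decade (shifts in $\pi_2$ below
$10^{-3}$) and against step-size-refined Monte Carlo.

```{r brownian}
solve_splitting(msd_powerlaw(kappa = 2, H = 0.5), x0 = 0.3, L = 1)$pi2
```

### Scaling regime

For scale-invariant models with $x_0 \ll L$,
$\pi_2 \simeq A_H (x_0/L)^{1/H-1}$.  `scaling_prefactor()` fits the
exponent and prefactor over start ratios down to $0.025$ on a widened grid
(lag span from $10^{-6} t_c$, because the near-target time scale
$(x_0/\kappa)^{1/H}$ must stay resolved), and raises an error if the
fitted exponent misses $1/H - 1$ by more than 10% — that failure mode
signals an under-resolved grid, not physics.

### Weak-memory regime

For $\psi_\epsilon = 2Dt + \epsilon\,\psi_1(t)$ the correction to
$\pi_2$ is linear in $\epsilon$ at leading order.  `weak_memory_check()`
verifies the linearity numerically.  Its default geometry uses $L = 5$
with $x_0 = 0.3L$: with targets too close ($L = 1$) a bidiffusive-type
perturbation of order $\epsilon = 0.4$ is a 30% distortion of the MSD in
the relevant window and the check leaves the linear regime.

## Exact simulation

All samplers are exact in distribution at the sampled instants; there is
no Euler bias anywhere.

* `sample_increment_process()` — circulant embedding of the increment
  autocovariance $c_k = \frac12[\psi((k{+}1)\Delta t) - 2\psi(k\Delta t) +
  \psi((k{-}1)\Delta t)]$; each FFT yields two independent paths.  Negative
  embedding eigenvalues beyond $10^{-8}$ of the maximum abort; smaller
  ones (roundoff) are clipped with a warning.
* `sample_bidiffusive()` — Brownian plus stationary-initialised
  Ornstein–Uhlenbeck component with exact discrete updates; an
  independent cross-check of the circulant route.
* `sample_rouse()` — exact normal-mode OU updates for the chain (internal
  modes started in equilibrium, so the monomer has stationary increments),
  with the free-end ghost-bead prescription.

First-passage detection is discrete-time: the first sampled position at or
beyond a boundary, with the crossing instant interpolated linearly.  No
bridge correction is applied — bridge corrections are ill-defined for
non-Markovian paths — so estimates carry a resolution bias controlled by
the ratio of the one-step RMS displacement $\sqrt{\psi(\Delta t)}$ to the
relevant distances.  The study conditions used in the validation suite
keep that ratio near $0.01$–$0.03$ of $L$; halving $\Delta t$ under those
conditions moves $\hat\pi_2$ by less than one standard error.  Sampled
post-hit positions overshoot the boundary by $O(\sqrt{\psi(\Delta t)})$,
which is why simulated post-first-passage means are compared to theory
with an allowance of that size.  Paths that reach neither target within
the horizon are excluded and reported as a censoring fraction (warning
above 1%, error above 20%); horizons in the shipped checks were chosen so
censoring is negligible.

In two dimensions (`simulate_confined_fp_2d()`), absorbing disks of radius
$a$ sit at distance $L$, the motion is confined by specular reflection at
radius $R$ about the first target (the boundary interaction is not
dictated by the theory, which is confinement-free; the insensitivity of
$\hat\pi_2$ between $R$ and $2R$ justifies the choice), and a
crossing-resolution guard rejects steps with RMS displacement above
$a/3$.  For the Rouse chain the reflection translates the whole chain,
preserving internal dynamics.

## Higher dimensions in large volumes

For $d > 1$ the package evaluates the large-volume formula
$\pi_1 = (h_{22}-h_{12})/(h_{22}+h_{11}-h_{21}-h_{12})$ with
$h_{ij} = \int_0^\infty [q_j(r_i,t) - p(r_i,t)]\,dt$: time-integrated
excess occupations of the target positions.  The post-hit density $q_j$
needs a model for where the walker sits after hitting a finite target:

* the **Markovian baseline** re-centres the free Gaussian on the target
  surface with uniform hit direction;
* the **semi-empirical mode** measures, in single-target simulations
  (`single_target_post_hit_2d()`, under the decoupling approximation that
  two-target post-hit statistics equal single-target ones), the signed
  radial mean displacement $m_j(t)$ along the hit direction and the
  hit-angle concentration, fitted as the exponential-cosine (von Mises)
  family $\Pi(\theta)\propto e^{\kappa_\theta\cos(\theta-\theta_0)}$ with
  $\theta_0$ measured from the target-to-start axis (the only
  distinguished direction).

The post-hit mean is parameterised as $c_j + (a + m_j(t))u(\theta)$, the
simplest form with $m_j(0)=0$ placing the trajectory start on the target
surface; outputs record which mode produced them, and the exact
self-consistent determination of $m_j$ and $\kappa_\theta$ is out of
scope.  With this sign convention a recoiling (viscoelastic-type) process
has $m_j(t) > 0$: the fluid pulls the walker back toward previously
occupied positions, i.e. away from the target, which is what the
single-target measurements show.  In $d=1$ with point targets the same
$h$-route, fed with the solved $\mu_j$, reproduces the partition-identity
$\pi_2$ to better than $10^{-2}$ — a nontrivial consistency check between
the two formulations.  Time integration uses a log grid over
$[10^{-6},10^{6}]\,t_c$ with an algebraic-tail extrapolation fitted to the
last decade; non-decaying integrands raise an error rather than a number.

## The tracking pipeline

`estimate_msd()` implements the standard overlapping time-averaged MSD
with a per-lag effective sample size $n_{\text{pairs}}/(2k)$ — a
conservative replacement for exact estimator covariances.
`check_gaussian_increments()` standardises increments at probe lags
(defaulting to the memory time and half of it) and applies a
Kolmogorov–Smirnov test plus excess kurtosis, thinning to
non-overlapping increments so the null is calibrated.  `check_drift()`
uses a block bootstrap with blocks longer than twice the memory time,
because anticorrelated increments make the naive standard error wrong.

`fit_msd_viscoelastic()` fits the crossover law by weighted least squares
in log MSD versus log lag (Levenberg–Marquardt), with a profiled grid
fallback for the $\alpha \to 1$ degeneracy, where $\tau_0$ and the
amplitude cease to be separately identifiable (pure diffusion is the same
line for every $\tau_0$).  A fit whose crossover lies at the edge of the
lag range is flagged unreliable.

**Identifiability of the memory time.**  The amplitude and $\tau_0$ are
almost collinear (correlation $\approx 0.98$ in the Fisher information of
the exact Gaussian likelihood): a Cramér–Rao computation for a single
record of $10^5$ frames at $\alpha = 0.5$ gives a standard deviation of
$\log\tau_0$ of at least $0.11$ at the optimal frame interval — no
estimator can pin $\tau_0$ to 10% from one such record.  The package
therefore treats multi-bead ensembles as the unit of analysis
(`estimate_msd_ensemble()`, averaging curves across independent
trajectories with honest cross-trajectory errors), which is also how
tracking experiments are actually analysed; ten records of $10^5$ frames
bring the recovery scatter to a few percent.

`empirical_splitting()` implements the fictitious-target protocol: from
each admitted starting instant, targets are placed relative to the start
(the start sits at relative coordinate $x_0$, which maximises event counts
and matches the ensemble-average description); the trajectory is followed
to its first crossing; and the next start is admitted no earlier than
`spacing` after the crossing — use at least twice the memory time, the
independence rule.  Error bars are twice the standard deviation of the
mean.  A guard rejects analyses where the one-frame RMS displacement
exceeds $L/10$.  `post_fpt_mean()` turns the recorded post-crossing
segments into conditional mean trajectories — the direct experimental
signature of memory: for a viscoelastic fluid they re-enter the interval,
for water they sit flat on the targets.

`gen_synthetic_bead_trajectory()` generates the synthetic stand-in for
bead-tracking data: exact circulant sampling of the viscoelastic MSD, with
optional additive localisation noise (off by default; when present it adds
a $2\sigma^2$ plateau that the fit can absorb as a constant offset).  The
defaults — amplitude $0.02\,\mu m^2$, $\tau_0 = 3$ s, $\alpha = 0.5$,
frame interval $0.05$ s — mimic a mid-concentration polymer solution with
memory time of a few seconds.  What the generator deliberately does not
emulate: tracking gaps, static/dynamic localisation error correlations,
drift, bead polydispersity, and aging.  Passing the end-to-end checks on
this generator therefore validates the pipeline's statistics, not its
robustness to instrumental artefacts.

## Validation suite and study conditions

The acceptance tests (in `tests/testthat/test-acceptance.R`) close several
independent loops, at sizes chosen to keep the full suite within a
half-hour desktop run:

* Markovian closed form to $10^{-3}$ across the interval; exact
  normalisation and reflection symmetry for four memory models.
* Theory versus exact fGN Monte Carlo at $x_0/L = 0.208$: $2\times10^4$
  paths of $\ge 2\times10^4$ steps per run, agreement within three
  standard errors, and the direction of the memory effect on both routes
  ($H=0.6$ above the Markovian line, $H = 0.4$ and $0.34$ below).  For
  anti-persistent paths the discrete-time detector misses boundary
  crossings between samples; the resulting bias on $\hat\pi_2$ is linear
  in the RMS step resolution $\sqrt{\psi(\Delta t)}/L$ (measured slope
  $\approx 0.35$ across resolutions $0.02$–$0.12$) and decays only like
  $\Delta t^{H}$, so for $H = 0.4$ the estimate is extrapolated to
  $\Delta t \to 0$ from two resolutions a factor 2 apart, with the
  extrapolated estimator's standard error; for $H = 0.6$ (bias
  $\sim 10^{-3}$ at one RMS step $\approx 0.01 L$) the raw estimate is
  compared directly.
* Small-start scaling exponents $1/H - 1$ within 10% for $H = 0.4, 0.6$.
* Sampler exactness (autocovariance and MSD over three decades for all
  four families), the Rouse mode-sum against simulation within 5%, and the
  intermediate-time exponent $1/2$.
* Post-first-passage recoil for the bidiffusive fluid against the solved
  $\mu$ curves (allowance: three standard errors plus 2% of $L$ for the
  overshoot), with a flat memoryless control.
* The two-dimensional baseline against confined Monte Carlo in the
  disk geometry $a=1$, $L=40$, $R=90$ vs $R=200$.
* The full synthetic-experiment loop: generate bead-like ensembles
  ($L = 0.6\,\mu m$, five beads, 3000 s at 100 frames/s), fit the MSD,
  feed the fitted model to the solver, and compare empirical splitting
  probabilities and post-crossing means within their 95% bands plus
  explicitly stated frame-resolution systematics.  The fictitious-target
  estimator misses sub-frame target touches, a bias that decays only like
  $\Delta t^{\alpha/2}$ for subdiffusive motion: about $+0.05$ in
  $\hat\pi_2$ at $x_0 = 0.25L$ and $\le 0.025$ for $x_0 \ge 0.4L$ at
  these conditions.  The quantitative theory comparison therefore runs at
  $x_0/L \in \{0.42, 0.5, 0.58\}$ with a $+0.025$ allowance, while the
  qualitative memory signature (empirical $\hat\pi_2$ below the Markovian
  line; post-crossing recoil into the interval) is asserted closer to the
  target, where it is an order of magnitude larger than the bias.
  Post-crossing mean curves carry two level systematics of the same size:
  the recorded crossing position overshoots the target by up to one RMS
  frame step, and sub-frame touches are preferentially missed for slow
  approaches, so the conditional ensemble is skewed toward fast, clean
  crossings.  Both shift the whole curve without changing its dynamics,
  so the curve level is compared with a two-RMS-step allowance while the
  curve shape (anchored at the first compared lag) is held to its plain
  95% band.

`scripts/acceptance.R` re-runs a condensed version of the same
computations from scratch and writes the headline numbers as JSON.

## Known limitations

Smooth (inertial) processes, biased processes, aging (non-stationary
increments), heavy-tailed waiting times, more than two targets, partially
absorbing targets, and hydrodynamic coupling are all out of scope.  The
$d>1$ theory is a large-volume limit with an approximate post-hit
propagator; exact agreement with a fully self-consistent angular closure
is not claimed.  The Gaussian post-hit closure in 1D is an approximation
validated here only against simulation of the shipped process families.
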