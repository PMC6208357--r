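---
title: "Measuring the sampling bias of splitting Langevin integrators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the sampling bias of splitting Langevin integrators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitkl)
```

## The problem

Langevin dynamics couples Newtonian motion to a heat bath through a
friction rate $\gamma$ and matched random forces, so that its stationary
density is the canonical distribution
$\pi(x, v) \propto e^{-\beta U(x)}\, e^{-\beta K(v)}$ with
$K(v) = v^\top M v / 2$. Simulated with a finite timestep $\Delta t$,
however, the dynamics samples a perturbed steady state
$\rho(x, v) \neq \pi(x, v)$, and the perturbation grows with $\Delta t$ as
a power law. Because most applications only use the positions, the
practically relevant error is in the configuration marginal
$\rho_x(x) = \int \rho\, dv$ — and some integrators push almost all of
their finite-timestep error into the velocity marginal, leaving $\rho_x$
nearly exact ("superconvergence").

`splitkl` quantifies this bias as a Kullback-Leibler divergence,
$D_{\mathrm{KL}}(\rho \,\|\, \pi)$ in phase space and
$D_{\mathrm{KL}}(\rho_x \,\|\, \pi_x)$ in configuration space, for any
integrator written as a symmetric (palindromic) splitting string over

* **R** — position drift: $x \mathrel{+}= v\,\tau$,
* **V** — velocity kick: $v \mathrel{-}= M^{-1}\nabla U(x)\,\tau$,
* **O** — Ornstein-Uhlenbeck partial velocity randomization:
  $v \leftarrow a v + \sqrt{1 - a^2}\,(\beta M)^{-1/2}\xi$ with
  $a = e^{-\gamma\tau}$, $\xi \sim \mathcal N(0, 1)$.

Each occurrence of a letter receives the fraction $1/\#(L)$ of the
timestep, so `"OVRVO"` unrolls to
$(O, \tfrac12)(V, \tfrac12)(R, 1)(V, \tfrac12)(O, \tfrac12)$ and
`"VRORV"` to $(V, \tfrac12)(R, \tfrac12)(O, 1)(R, \tfrac12)(V, \tfrac12)$.
All energies and works are **reduced** (multiplied by $\beta$, hence in
units of $k_BT$); positions, velocities and times are in reduced units
too.

## Shadow work

The central measurable is the *shadow work* of a trajectory — the
work-like quantity that satisfies the Crooks fluctuation theorem for one
or more cycles of the discrete integrator. For symmetric splittings it
has the simple form

$$ w = \Delta h - \Delta q, $$

the total change in reduced Hamiltonian $h = \beta U(x) + \beta K(v)$
minus the reduced heat — the kinetic-energy change summed over the O
substeps only. The deterministic R and V kernels cancel exactly from the
forward/reverse path-probability ratio, and each O kernel contributes its
kinetic-energy change. Accounting therefore needs the potential energy
only at cycle boundaries plus the kinetic energy immediately before and
after every O substep; no extra force evaluations. Non-palindromic
strings are rejected at parse time: their reverse-path kernels do not
cancel this way and would silently mis-account the work.

The suite checks the ledger against an independent energy-bookkeeping
oracle (the explicit four-term expansion for a single `OVRVO` cycle, and
a generic per-substep reconstruction for arbitrary palindromes) to
$10^{-12}$ relative, and checks $\gamma = 0 \Rightarrow w = \Delta h$
bitwise.

## Three estimators of the KL divergence

**Near-equilibrium (cheap, approximate).** Run a length-$2T$ protocol:
draw $(x_0, v_0) \sim \pi$, take $T$ integrator steps accumulating
$w_{\text{first}}$ (the endpoint is then approximately a draw from
$\rho$), then $T$ more accumulating $w_{\text{second}}$. Then

$$ D_{\mathrm{KL}}(\rho \,\|\, \pi) \approx \tfrac12\,
\big( \langle w\rangle_\pi - \langle w\rangle_\rho \big), $$

estimated as `(mean(w_first) - mean(w_second)) / 2`. For the
configuration marginal, the midpoint velocities are replaced by a fresh
Maxwell-Boltzmann draw — turning the $\rho$ draw into a draw from
$\omega(x,v) = \rho_x(x)\,\pi(v|x)$, whose full-space divergence equals
$D_{\mathrm{KL}}(\rho_x \|\pi_x)$; the redraw itself does no work. The
95% CI uses the paired per-protocol differences
$d_i = (w_{\text{first},i} - w_{\text{second},i})/2$, since the two
halves of one protocol are correlated. Negative point estimates are
reported as-is (they are small-divergence noise), never clamped.

**Nested Monte Carlo (expensive, asymptotically exact).** Writing the
divergence as $\langle \ln \langle e^{-w} \rangle_{z;\Lambda}
\rangle_\rho$, the estimator draws $N$ outer starts from (approximately)
$\rho$ or $\omega$, and from each start runs many independent $T$-step
realizations with fresh noise, giving a jagged array of works $w_{ij}$:

$$ \hat D = \frac1N \sum_{i=1}^N \ln \frac{1}{M_i} \sum_{j=1}^{M_i}
e^{-w_{ij}}. $$

Each inner exponential average is adaptively sized: batches of 100
(after a minimum of 50) until the first-order Taylor estimate of the
log-mean's standard deviation, $\mathrm{sd}(e^{-w}) / (\overline{e^{-w}}
\sqrt{M})$, drops below a threshold (default $0.01$), or a budget
(default $5 \times 10^4$) is hit — budget-exhausted rows are kept but
flagged. The finite-sample estimate is biased *low* (by roughly
$\sigma^2_{\text{inner}}/2M$ per row, the usual exponential-average
bias); the bias direction is recorded in the estimate's metadata, not
corrected. Confidence intervals come from a two-level bootstrap:
resample rows, then columns within each resampled row.

**Jensen upper bound (free reprocessing).** By $\langle \ln X \rangle
\le \ln \langle X \rangle$, $\ln \langle e^{-w} \rangle_\rho$ bounds the
divergence from above. On jagged data the sample version averages the
*per-row* exponential means with equal weight before taking the log.
Pooling the raw works would weight rows by their inner counts — and
since the adaptive loop gives hard rows more samples, that weighting is
not innocent: it biases the outer average and can even fall below the
nested estimate, destroying the algebraic ordering. With equal outer
weights, `jensen >= nested` holds on every dataset by concavity, which
the suite checks on randomized jagged arrays. Its CI also uses the
two-level bootstrap; within-row works share a start point, so a pooled
i.i.d. bootstrap would understate the uncertainty.

**Exact reference (1D only).** For one-dimensional systems the
divergence is computed exactly: a long trajectory is histogrammed (100
bins per dimension; edges from the bounding box of a trial run at the
largest timestep of the sweep, shared across conditions so divergences
are comparable), and compared against the equilibrium histogram obtained
by trapezoidal quadrature of $e^{-\beta U}$ (positions) and the exact
normal CDF (velocities), via $\sum_b p_b \ln (p_b / q_b)$.

## The protocol length T

$T$ must be long enough that the midpoint of the protocol is genuinely a
steady-state draw. Velocities decorrelate on the collision time
$1/\gamma$, but for a heavy particle at high friction the *positions*
relax more slowly, on $\gamma m / k$ with $k$ the curvature of the well.
On the package's double-well test system ($\beta = 1$, $\gamma = 10$,
$m = 10$) the thermally averaged curvature $\langle U'' \rangle_\pi
\approx 42$ gives a configurational relaxation time $\approx 2.4$ reduced
time units — twelve collision times — and a protocol spanning only the
collision time visibly under-estimates the divergence. The package
therefore exposes three levels:

* `default_protocol_length()` — $\lceil (2/\gamma)/\Delta t \rceil$, two
  collision times; adequate at low friction or for light particles.
* `suggest_protocol_length()` — spans two full relaxation times
  $2\,(2/\gamma + \gamma m / \langle U''\rangle_\pi)$; what
  `sandwich_validation()` uses.
* `check_protocol_length()` / `auto_protocol_length()` — the empirical
  validation: rerun at $T$ and $2T$ and require concordance within twice
  the combined standard error; the auto variant doubles $T$ until two
  successive doublings concord.

A worked confirmation on the double well: at $\Delta t = 0.5$ the
suggested $T = 11$ steps gives a near-equilibrium phase-space estimate
statistically consistent with the exact histogram value, while $T = 1$
(two collision times) recovers only about half of it.

## Sandwich validation

Because the near-equilibrium estimator is approximate, the package
validates it the same way the reference estimators validate each other:
per condition, the nested estimate (likely under-estimate), the
near-equilibrium estimate, and the Jensen bound (upper bound) are
computed on a shared protocol length, and the condition passes when
`nested <= near-eq <= jensen` within 95% CIs and the exact histogram
value lies inside the nested-to-Jensen bracket. On the double well this
holds for all four splittings `OVRVO`, `ORVRO`, `RVOVR`, `VRORV`, at
$\Delta t \in \{0.3, 0.5\}$, in both phase and configuration modes (the
acceptance suite runs exactly this grid).

## GHMC

Metropolizing the integrator — accept a proposal of one or more cycles
with $\alpha = \min\{1, e^{-w}\}$, negating the momentum on rejection —
yields generalized hybrid Monte Carlo, which samples $\pi$ exactly. The
package uses it two ways: `ghmc_acceptance_rate()` estimates the
acceptance rate from fresh equilibrium starts (isolating the rate from
chain autocorrelation; no momentum flips are involved in the rate
itself), and `run_ghmc_chain()` is a full chain, used as the exact
equilibrium sampler for systems with more than one degree of freedom
(1D systems use inverse-CDF sampling on a fine quadrature grid instead,
exact up to quadrature error). A notable finding reproduced by the test
suite: the ranking of splittings by rejection rate does *not* predict
their ranking by configuration-space bias — `VRORV` has the smallest
configurational error at $\Delta t = 0.6$ by orders of magnitude, yet a
middle-of-the-pack rejection rate, so Metropolization is "overly
conservative" for it.

## Built-in systems and study conditions

* `double_well` — $U(x) = x^6 + 2\cos(5(x+1))$, $\beta = 1$, $m = 10$,
  studied at $\gamma = 10$. Anharmonic, asymmetric, bimodal; the main
  1D testbed. Its empirical stability limit under the four splittings is
  $\Delta t \approx 0.7$, and its phase-space divergence scales close to
  $\Delta t^4$.
* `quartic` — $U(x) = x^4$, $\beta = 1$, $m = 1$; the minimal
  illustration system ($\langle x^2\rangle_\pi = \Gamma(3/4)/\Gamma(1/4)$
  gives a closed-form quadrature check).
* `quartic_nd` — separable $\sum_i x_i^4$ in any dimension, for
  exercising the n-D code paths.
* `lj_cluster` — five Lennard-Jones particles ($\varepsilon = \sigma =
  1$) confined by a harmonic restraint of configurable stiffness `k`; a
  *synthetic stand-in* with the geometry of a small condensed-phase
  cluster. It reproduces the qualitative structure of molecular-mechanics
  results, not any published number.
* custom — any user potential/gradient pair; potentials whose density
  does not decay (e.g. a free particle) must declare a bounded `domain`.

## Numerical choices

* Quadrature: trapezoidal rule, $10^4$ sub-points per bin by default;
  the 1D support is auto-bounded where the reduced potential rises 40
  units above its minimum (tail mass $< 10^{-17}$), overridable by a
  declared domain.
* Instability: a trajectory is unstable when any coordinate is
  non-finite or $|x| > 10^6$; `run_steps()` raises a classed condition
  carrying the step index, sweep drivers convert it to a flagged row, and
  a GHMC proposal that destabilizes counts as rejected.
* Stability scans declare a timestep stable when *all* replicate
  trajectories (default 10) survive a fixed number of steps. The
  reported limit is the largest stable grid point; trajectory length is
  the resolution knob of this operational definition (the acceptance run
  uses $10^5$ steps, where the double-well limit settles at $0.70 \pm
  0.05$ across seeds).
* Histogram KL uses $0 \ln(0/q) = 0$; sample mass where the reference
  has none raises an error naming the bins. Empirical-vs-quadrature
  comparisons renormalize both within the shared bounding box, and the
  sampling floor of a histogram KL ($\approx$ bins / $2 N_{\text{eff}}$)
  must sit well below the smallest divergence of interest — the
  acceptance-scale slope fit uses $10^7$ steps per condition for this
  reason, and the methods report the floor alongside.
* RNG: all stochastic substeps consume R's own RNG stream (one
  standard-normal per degree of freedom per O substep, in substep
  order), so a single `seed` argument makes every trajectory, chain and
  bootstrap bitwise reproducible; seeded helpers restore the caller's
  stream.
* CSV outputs format doubles with 17 significant digits, so tables
  round-trip bit-identically through `write_results_csv()` /
  `read_results_csv()`.

## What the toy systems do and do not show

The 1D systems make the exact histogram reference possible, which is
what lets the estimator sandwich be *verified* rather than assumed; and
they exhibit the phenomena of interest (power-law bias growth,
superconvergence of `VRORV`, rate/bias decoupling) in clean form. They
do not have the dimensionality, disorder, or force-field structure of
molecular-mechanics systems: passing tests here validates the
estimators and the work accounting, not any claim about a particular
molecular system's error at a particular femtosecond timestep. The
`lj_cluster` stand-in extends the machinery to a rugged n-D landscape
but is deliberately not calibrated against any published cluster
results. Holonomic constraints, periodic boundaries, barostats and
non-palindromic splittings are out of scope.

## Problem sizes used by the shipped runs

The test suite and acceptance script size their simulations to finish on
a single CPU while keeping estimator noise below the effects being
tested: stability scans use 10 trajectories of $10^5$ steps per
timestep; the slope fit uses $10^7$-step histograms per timestep; the
sandwich grid uses 200 outer samples with inner threshold $\sigma =
0.02$, $2 \times 10^4$ near-equilibrium protocols, and $10^7$-step
reference histograms; GHMC rates use $2 \times 10^4$ proposals. Each
quantity reported by `scripts/acceptance.R` is recomputed from scratch
at run time under the seed passed on the command line.
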