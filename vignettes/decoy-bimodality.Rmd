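---
title: "Bursty autoregulation with decoy binding sites: model, stationary law, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bursty autoregulation with decoy binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyburst)
```

## The model and its assumptions

`decoyburst` studies a single gene whose protein product activates its own
transcription and additionally binds a pool of $y$ decoy sites on the DNA.
The model rests on four simplifications, each standard in the stochastic
gene expression literature:

1. **Bursty synthesis.** mRNA turnover is fast relative to protein turnover,
   so each transcriptional burst delivers protein essentially
   instantaneously. Burst sizes are exponentially distributed with mean $b$
   molecules — the continuous limit of the geometric burst-size law that a
   single-step promoter inactivation mechanism produces.
2. **Deterministic decay.** Bursts move the copy number by tens of
   molecules; degradation and binding move it one molecule at a time, so
   their intrinsic noise is negligible and decay is treated as a
   deterministic drift.
3. **Quasi-steady-state binding.** Binding and unbinding at decoy sites
   equilibrate much faster than protein turnover. With dissociation constant
   $k_b$, the bound amount is $x_b = y x_f/(x_f + k_b)$ and total protein is
   $$x = x_f + \frac{y x_f}{x_f + k_b},$$
   inverted in closed form by `free_from_total()`. The state space is
   therefore one-dimensional (total protein $x$), with free protein $x_f$
   slaved to it.
4. **Non-cooperative activation.** The burst hazard is
   $a(x) = a_0 + a_1 x_f/(k_p + x_f)$: basal rate $a_0$, regulable increment
   $a_1$, promoter dissociation constant $k_p$. Sequestration of free
   protein by the (1–2 copy) promoter itself is neglected; the decoys,
   present at up to hundreds of copies, are not.

Time is measured in free-protein lifetimes, fixing the free decay rate
constant at 1; the only decay parameter is $\gamma_b$, the decay rate of
*bound* protein relative to free. The total decay flux is
$c(x) = x_f + \gamma_b (x - x_f)$, which collapses to $c = x$ when
$\gamma_b = 1$. Concentration units are molecules per cell.

The resulting dynamics form a piecewise-deterministic Markov process: decay
flow $\dot x = -c(x)$ interrupted by upward jumps of exponential size at
hazard $a(x)$.

## The stationary density

The stationary density $p(x)$ of the jump–drift process satisfies the
first-order balance
$$\frac{d}{dx}\bigl(c(x)\,p(x)\bigr) + \frac{c(x)\,p(x)}{b} = a(x)\,p(x),$$
whence
$$p(x) = \frac{\kappa}{c(x)} \exp\!\Bigl(-\frac{x}{b} +
  \int^x \frac{a(x')}{c(x')}\,dx'\Bigr).$$
(`stationary_ode_residual()` verifies the balance on every grid the package
produces; the indefinite integral's constant is absorbed into $\kappa$.)

Changing the integration variable to $x_f$ (Jacobian
$J = 1 + y k_b/(x_f+k_b)^2$) makes the integrand a rational function of
$x_f$ with simple poles at $0$, $-k_p$, $-k_b$ and $-(k_b + \gamma_b y)$.
Collecting residues gives the closed form
$$p(x) \propto e^{-x/b}\, x_f^{q_1 - 1} (x_f + k_p)^{q_2}
  (x_f + k_b)^{q_3 + 1} (x_f + k_b + \gamma_b y)^{q_4 - 1},$$
with
$$q_1 = \frac{a_0 (k_b + y)}{k_b + \gamma_b y},\qquad
  q_2 = \frac{a_1 (k_p - k_b)}{k_p - k_b - \gamma_b y}
        \Bigl(1 + \frac{y k_b}{(k_p - k_b)^2}\Bigr),$$
$$q_3 = \frac{1}{\gamma_b}\Bigl(\frac{a_1 k_b}{k_p - k_b} - a_0\Bigr),\qquad
  q_4 = \frac{\gamma_b^2 y + k_b}{\gamma_b}
        \Bigl(\frac{a_0}{k_b + \gamma_b y} +
              \frac{a_1}{k_b - k_p + \gamma_b y}\Bigr).$$
Each exponent is exactly the residue of $a/c \cdot J$ at the corresponding
pole; the factor $\gamma_b^2 y + k_b$ in $q_4$ comes from evaluating the
numerator $(x_f + k_b)^2 + y k_b$ at $x_f = -(k_b + \gamma_b y)$. The test
suite cross-validates the closed form against direct adaptive quadrature of
$\int a/c$ over randomized parameter sets (ratio constant in $x$ to relative
$10^{-6}$; in practice agreement is near machine precision).

The closed form assumes the four poles are distinct. The degenerate
combinations $k_p = k_b$, $k_p = k_b + \gamma_b y$ and $\gamma_b y = 0$
(detected with relative tolerance $10^{-9}$) are served by the quadrature
route `unnormalized_density_quadrature()` instead, which also covers the
protected-decay limit $\gamma_b = 0$. The quadrature is performed in the
$x_f$ coordinate — the substitution both removes the coordinate singularity
and leaves a smooth integrand — with the arbitrary reference point at
$x = 1$ absorbed into $\kappa$.

### Behaviour at the origin, and scale-dependence of modality

Near $x = 0$ the density behaves as $x^{q_1 - 1}$: it diverges (integrably)
when $q_1 < 1$, is finite and positive at $q_1 = 1$, and vanishes when
$q_1 > 1$. For $\gamma_b = 1$, $q_1 = a_0$, so one basal burst per lifetime
is the exact threshold. A divergence at zero is a genuine probability
mode — a subpopulation parked at very low copy number — and the package
counts it as one on the linear scale. At exactly $q_1 = 1$ (finite limit)
the origin is *not* counted; this convention makes the boundary of the
bimodal region consistent with the interior-extremum analysis. On the
log10 scale, $\breve p(z) = p(10^z)\, 10^z \ln 10 \sim x^{q_1}$ vanishes as
$z \to -\infty$ for any $a_0 > 0$, so only interior maxima count there.
Bimodality is therefore scale-dependent, and the package always states which
scale a mode count refers to.

### Normalization grid

`stationary_density()` evaluates the (log) unnormalized density on a
log-spaced grid from $x_{lo} = 10^{-4}$ to
$x_{max} = \max(20\,b\,(a_0+a_1),\ 10\,(y + k_b))$ with 4096 points by
default — wide enough to capture both the basal and the fully up-regulated
scale. The integrable singularity is handled analytically: mass on
$(0, x_{lo}]$ is computed from the local power law
$p \approx A x^{q_1 - 1}$ matched at $x_{lo}$, not by gridding. Log-density
evaluation with a max-shift before exponentiation keeps extreme exponents
(e.g. $q_1 \approx 76$ for the protected-decay reference set) from
overflowing; far tails may underflow to zero density, which is harmless
after normalization. Transformed densities (free protein via the Jacobian
$J$, log10 via $x \ln 10$) conserve mass to the trapezoid accuracy of the
grid — $\sim 10^{-5}$ at the default resolution, $10^{-6}$ and below at
$2^{14}$ points.

## Locating extrema and the bimodality boundary

For $\gamma_b = 1$ the extremum condition for $p(x)$ reduces to a root
problem in $x_f$:
$$a_0 + \frac{a_1 x_f}{k_p + x_f} - \frac{x_f}{b}
  - \frac{y x_f}{b (x_f + k_b)} - 1 = 0,$$
and the log10-scale condition is the same expression without the $-1$ (the
$c/x$ term of the log derivative cancels the $dc/dx$ term when $c = x$).
Roots are found by a sign scan over a log-spaced $x_f$ grid
($10^{-4}$–$10^{6}$, 2000 points) followed by bisection to relative
tolerance $\sim 10^{-11}$; crossing direction classifies each root as
maximum or minimum, and kinds necessarily alternate. Tangent (double) roots
produce no sign change and are deliberately not counted as extremum pairs:
at a tangency the density has an inflection, not a pair of modes. For
$\gamma_b \ne 1$ the analytic conditions do not apply and modes are located
directly on the density grid, with a relative prominence floor of
$10^{-12}$ to ignore floating-point ripples.

The number of extrema changes where the extremum function crosses zero
tangentially, i.e. where additionally
$$\frac{a_1 k_p}{(k_p + x_f)^2} - \frac{1}{b}
  - \frac{y k_b}{b (x_f + k_b)^2} = 0.$$
`boundary_curve()` sweeps $x_f$, solves the tangency condition for $k_p$ (a
quadratic with up to two positive roots, labelled `"plus"`/`"minus"`), then
reads $a_0$ off the extremum condition. In the reference cross-sections only
the `"plus"` family is physical ($a_0 > 0$); traced in the $(a_0, k_p)$
plane it folds back on itself, and the two sides of the fold are the two
arcs that enclose the bimodal region when decoys are present. Because the
linear- and log-scale extremum functions differ by the constant 1 and share
the tangency condition, the log-scale boundary is the linear one translated
by exactly 1 leftward in $a_0$ — the package computes both and verifies the
translation rather than assuming it. Without decoys the log-scale extremum
function is monotone past a single rise and admits at most one root: no
amount of parameter tuning makes the log-scale density multimodal at
$y = 0$.

## The deterministic reduction

Dropping fluctuations gives $\dot x = b\,a(x) - c(x)$, with steady states
solving $b a_0 + b a_1 x_f/(k_p + x_f) = x_f + \gamma_b y x_f/(x_f + k_b)$.
`steady_states()` uses the same scan-plus-bisection root finder as the
modality analysis (for comparability) over $x_f \in [10^{-8}, 10^{8}]$, and
classifies stability from the sign of $\dot x$ at $x(1 \pm 10^{-4})$ around
each root — avoiding differentiation of the composite $c(x)$. At
$\gamma_b = 1$ the steady-state balance is $b$ times the log-scale extremum
function, so bistability and log-scale bimodality coincide;
`bistability_equivalence()` computes both classifications on matched scan
grids so the comparison cannot be confounded by different root-search
windows. With $y = 0$ or $\gamma_b = 0$ the balance is monotone past a
single crossing and exactly one steady state exists.

## The stochastic simulator

`simulate_bursts()` samples the process exactly, with no time
discretization:

* **Burst times by thinning.** The hazard is bounded by $M = a_0 + a_1$
  (tight, since $a$ saturates). Candidate gaps are $\mathrm{Exp}(M)$; the
  state is decayed through the gap and the candidate is accepted with
  probability $a(x)/M$. The per-candidate draw order (gap, acceptance
  uniform, size) is fixed, so a seed reproduces a trajectory bit-for-bit.
* **Inter-burst flow in closed form.** For $\gamma_b = 1$ or $y = 0$ the
  flow is exactly $x e^{-t}$. Otherwise the separable ODE is inverted
  analytically: the elapsed time from $x_{f,0}$ down to $x_f$ is a sum of
  three logarithms (partial fractions of $J/c$, with a dedicated branch for
  $\gamma_b = 0$ where the pole at $-k_b$ is double), and the state at a
  given time is recovered by bisection on that expression. A fourth-order
  Runge–Kutta integration serves as the independent oracle for this flow in
  the test suite.
* **Stationary sampling.** `stationary_samples()` records the state at
  uniformly spaced times after a burn-in of 20 lifetimes (relaxation takes
  a few lifetimes; 20 is generous). Time-uniform sampling of an ergodic
  piecewise-deterministic process estimates its stationary law.

`ks_distance()` compares the empirical CDF with the numerically integrated
analytic CDF. The validation scales used by the test suite were chosen to
make the comparison informative: $10^5$ samples spanning $5 \times 10^4$
lifetimes for the bimodal reference circuit. The span matters more than the
sample count — in the bistable regime consecutive samples are correlated
over the residence time in a mode, so the effective sample size is governed
by the number of switching events. At these scales the reference circuits
reproduce the analytic law to KS $< 0.02$ (the no-feedback gamma-law case
to $< 0.01$), while a deliberately mismatched density (burst size doubled)
sits at KS $> 0.05$.

## What the validation does and does not show

All validation is internal to the model: the simulator and the closed form
are independent *implementations of the same idealized process*, so their
agreement checks the mathematics and the code, not the biology. Features of
real single-cell data that the model deliberately omits — molecule-number
discreteness at low copy number, the mRNA stage and its geometric (rather
than exponential) burst sizes, kinetic (non-equilibrated) decoy binding,
extrinsic noise in rates, cell division — are out of scope, and passing
tests say nothing about them. The package's claims are exact-model claims:
the stationary law, its modality phase structure, and the
bistability/bimodality correspondence.

## Known limitations and open choices

* Analytic extremum/tangency conditions exist only for $\gamma_b = 1$;
  other decay ratios are classified numerically from the density grid
  (slower, and resolution-limited for extremely shallow modes).
* Closed-form densities for the degenerate parameter combinations are not
  implemented; the quadrature route stands in for them everywhere. No
  accuracy is lost (the quadrature is adaptive with relative tolerance
  $10^{-10}$), only speed.
* Whether the singular origin peak counts as a mode is a convention; the
  package counts it (and documents the choice) because the divergence
  carries finite probability mass and corresponds to an observable
  basal-expression subpopulation. At the exact threshold $q_1 = 1$ the
  origin is not counted.
* The boundary-curve sweep parameterizes branches by the quadratic root for
  $k_p$, not by position in the $(a_0, k_p)$ plane; users plotting the
  curves should expect the physical family to fold.
* Decoys are a single homogeneous pool; heterogeneous site affinities and
  explicit binding kinetics are non-goals.
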