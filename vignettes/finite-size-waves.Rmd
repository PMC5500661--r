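---
title: "Finite-size noise on traveling neural-field waves: models, numerics, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finite-size noise on traveling neural-field waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finitewave)
```

# The model hierarchy

The voltage-based neural field equation
$$\partial_t u = -u + w * F(u)$$
describes the average membrane potential of a continuum of neuronal
populations. `finitewave` implements the chain of models that connects
this continuum description back to networks of *finite* populations, so
that the intrinsic noise left behind by finite population size can be
quantified — in particular its effect on traveling front solutions
$u(x,t) = \hat u(x - ct)$.

The hierarchy, from microscopic to continuum:

1. **Activity Markov chain** (`jump_rates`, `simulate_ssa`). $P$
   populations of $N$ neurons each; the time-averaged activity of
   population $k$ lives on $\{0, 1/N, \dots, 1\}$ and jumps by $\pm 1/N$
   with rates
   $$q^\pm_k = N\,F'(F^{-1}(x_k))\Big(\sum_j w_{kj}x_j -
   F^{-1}(x_k)\Big)_\pm.$$
   The activity chases the balance $a = F(u)$ between activity and
   synaptic input; the sensitivity factor $F'$ concentrates fluctuations
   where the gain is steep and silences them near the stable fixed
   points. The classical activity-based rates
   ($\tilde q^+ = N F(\sum_j w_{kj}x_j)$, $\tilde q^- = N x_k$,
   variant `"classical"`) share the deterministic limit structure but keep
   firing at balanced high-activity states; `jump_rates` implements both
   so the contrast is testable.
2. **Mean-field limit** (`meanfield_rhs`, `integrate_meanfield`). As
   $N \to \infty$ the chain converges to
   $\dot x_k = F'(F^{-1}(x_k))(-F^{-1}(x_k) + \sum_j w_{kj}x_j)$,
   the voltage-based network equation in activity variables.
3. **Fluctuations** (`simulate_ssa` accumulators,
   `martingale_decompose`). The compensated martingale
   $M_k(t) = x_k(t) - x_k(0) - \int_0^t Q\pi_k\,ds$ has bracket
   $\langle M_k\rangle_t = N^{-1}\int_0^t
   F'(F^{-1}(x_k))\,|{\textstyle\sum_j} w_{kj}x_j - F^{-1}(x_k)|\,ds$;
   $\sqrt N M$ converges to a stochastic integral against independent
   Brownian motions (single-jump transitions leave distinct coordinates
   uncorrelated).
4. **Diffusion network around the wave** (`diffusion_coefficients_m`,
   `sigma_m_apply`, `simulate_diffusion_network`). Linearizing the
   square-root noise amplitude around the traveling wave — possible
   only for a *moving* wave, where the drift at the wave,
   $-\hat b^m(t, \pi^m u^{TW}) \approx c\,\hat u_x > 0$, stays clear of
   the square root's degeneracy — yields dispersion coefficients
   $\alpha^m, \beta^m, \gamma^m$ cut off outside the front region
   $\{\partial_x u^{TW} \ge \delta\}$.
5. **Continuum stochastic field equation** (`noise_model`,
   `integrate_spde`). Populations closer than $2\varepsilon$ overlap, so
   the continuum limit is driven by a Q-Wiener process with a box
   correlation kernel of half-width $\varepsilon$; the averaging map
   $\Phi^m$ (`phi_m_project`) turns one continuum noise realization into
   lattice noise, which is how the lattice and continuum systems are
   *coupled* in the convergence experiment
   (`run_continuum_experiment`).

# Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $\gamma$ | gain slope (1/voltage) | 8 | steep enough for bistability with margin; $F'(a)\approx 1.6$–$1.9$ |
| $\kappa$ | gain threshold (voltage) | 0.5 / 0.55 / 0.6 | 0.5 is the symmetric standing-wave case; larger values make the low state dominant, $c>0$ |
| kernel scale | synaptic footprint (space) | 1 | sets the length unit |
| $N$ | neurons per population | experiment-specific | noise amplitude $\propto N^{-1/2}$ |
| $m$, $L$ | lattice density, half-length | 4–64, 2–6 | $P = 2mL$ populations at $k/m$ |
| $\varepsilon$ | noise correlation half-width | 0.25 | populations within $2\varepsilon$ overlap; lattice noise independent iff $m < 1/(4\varepsilon)$ |
| $\delta$ | slope cutoff for the noise | $0.1\max\hat u_x$ | keeps $\sigma\in L^2$; confines noise to the moving front |

The model itself fixes no numeric $(\gamma,\kappa)$; the shipped
fixtures are package choices satisfying every standing assumption
(`validate_assumptions`). At $\gamma = 8$ bistability is lost beyond
$\kappa \approx 0.64$, so `fast_wave` ($\kappa = 0.6$, $c \approx
0.459$) is near the fastest wave the family supports. With the
convention that $\hat u$ increases from $a_1$ to $a_2$, positive speed
requires the *low* state to invade, i.e. $\int_{a_1}^{a_2}(F(s)-s)\,ds <
0$, hence $\kappa > 1/2$ for the logistic family; the wave direction is
not a free choice on top of the monotonicity convention.

# Numerical design

**Wave solver.** No scheme is prescribed by the theory, which only
guarantees existence and uniqueness of the monotone front. We use
collocation with Newton iteration on the joint unknowns $(\hat u_j, c)$:
4th-order central differences with the profile extended by its
asymptotic constants, Dirichlet values $a_1, a_2$ at the ends of
$[-L_w, L_w]$ ($L_w = 20\,\mathrm{scale}$), and the phase condition
$\hat u(0) = a$ closing the system. Initial guess: a logistic ramp and
$c = 0$. Convergence is quadratic (5–7 iterations to residual
$10^{-12}$).

**Convolution quadrature.** Two kernel-specific rules:

* *gaussian*: trapezoid weights with the Euler–Maclaurin $h^2/12$
  endpoint-derivative correction. For an analytic integrand the interior
  trapezoid error is superalgebraically small, so the endpoint terms are
  the whole story; without the correction they excite a sawtooth mesh
  mode of amplitude $\sim 10^{-6}$ in the flat tails of the profile
  (4-point central differences annihilate the alternating mode, so
  nothing damps it).
* *exponential*: exact cell-integrated CDF weights. The $|x|$ kink on
  grid nodes breaks the trapezoid rule's reflection symmetry, which
  showed up as a spurious speed $c \approx -3\cdot 10^{-4}$ for the
  symmetric fixture; cell integration restores exact discrete symmetry
  and pins the standing wave at $|c| < 10^{-15}$.

**Lattice geometry.** Following the half-open cell convention
$I^m_k = [k/m, (k+1)/m)$, populations sit at the *left* endpoints of
their cells. The discrete convolution therefore samples its input half a
cell to the left, and lattice fronts travel at $c + 1/(2m) + O(1/m^2)$.
This is a property of the model family, not a bug: the tests verify the
bias halves when $m$ doubles and that at $m = 64$ the lattice front runs
within 5% of $c$. All weights are closed-form CDF differences, making
the row partition $\sum_l w^m_{kl} + w^{m,+}_k + w^{m,-}_k = 1$ exact to
rounding.

**Noise sampling.** Increments are white noise convolved with the box
kernel. When $2\varepsilon$ is an integer number of grid cells, the
point-sampled box stencil is a discrete autocorrelation, so increments
carry the triangular covariance $dt\,(2\varepsilon - |x-y|)_+ /
(4\varepsilon^2)$ *exactly* at grid lags; otherwise a cell-averaged
stencil is used with an $O(h/\varepsilon)$ covariance bias. Grids are
always chosen with $h \le \varepsilon/4$ and integer $2\varepsilon/h$.

**SSA.** Direct Gillespie with full per-jump rate recomputation in C++
(Rcpp), with the synaptic input vector updated incrementally per jump
($O(P)$ per event). The compensator and bracket integrals are
accumulated exactly between jumps (piecewise-constant integrands). R's
RNG drives the core, so `set.seed` gives bit-for-bit reproducibility.

**Time stepping.** Mean-field and continuum deterministic runs use
`deSolve::lsoda` at tolerances $10^{-8}$–$10^{-10}$; stochastic systems
use fixed-step Euler–Maruyama (the noise near the wave is
additive-dominant, and weak-order checks against halved steps stay
within Monte Carlo error). The un-linearized square-root SDE is
included only as a documented experimental integrator
(`simulate_sqrt_sde`) with the coefficient clipped at zero — the square
root is not Lipschitz at 0 and the equation has no standard existence
theory — and it backs a Taylor-remainder test, nothing else.

# What the experiments show (and at what sizes)

Problem sizes were chosen so the full suite runs in minutes on one CPU
while leaving the statistical assertions comfortable margins:

* **LLN**: $P = 16$ ($m = 4$, $L = 2$), $T = 2$, $N \in \{100, 400,
  1600\}$, 100 replicas; fitted log-log slope $\approx -0.50$, asserted
  within $[-0.65, -0.35]$ (window set by the Monte Carlo error of the
  3-point fit).
* **CLT**: $N = 1600$, 500 replicas, $T = 1$; pooled variance over
  populations within 10% of the bracket integral along the mean-field
  path. Off-diagonal covariances are checked at 3 standard errors for
  three representative pairs (adjacent at the front, adjacent in the
  flank, maximally distant) — testing all 120 pairs at 3 SE would fail
  by chance about a quarter of the time.
* **Noise covariance**: $10^4$ increments; point variance and lag
  covariances within 3–4 standard errors of $dt\,q*q$; quarter-interval
  averages uncorrelated for $m < 1/(4\varepsilon)$.
* **Stochastic field**: deterministic transport of the wave over
  $T = 5$ preserves the shape to $4\cdot10^{-6}$ (sup norm, aligned at
  the measured shift); front-position variance over 100 seeds per level
  scales as $N^{-1}$ across $N \in \{10^2, 10^3, 10^4\}$ at $T = 0.5$.
  The horizon matters: by $T = 1$ the $N = 10^2$ ensemble has left the
  linear-response regime (deviations are no longer small compared with
  the front width, and the dispersion coefficients grow like
  $(c\,\hat u_x F')^{-1/2}$ near the cutoff edge), and its variance
  breaks the $1/N$ law — a real limitation of the linearized model, not
  of the integrator.
* **Lattice-to-continuum**: $m \in \{4, 8, 16\}$ with growing windows
  $L^m \in \{2, 3, 4\}$, 50 replicas, all systems driven by one
  Q-Wiener realization per replica through $\Phi^m$; the mean
  sup-in-time $L^2(-L^m, L^m)$ squared error decreases strictly
  (about $8\cdot10^{-3} \to 6.5\cdot10^{-4}$).

# Degenerate inputs, tie-breaks, tolerances

* Coordinates at $0$ or $1$: both rates are set to $0$ (the one-sided
  limit of the rate formula — $F'$ vanishes faster than $F^{-1}$
  diverges). For $N \ge N_0$ (`interior_threshold`; $N_0 = 56$ at
  $\gamma = 8, \kappa = 0.5$) the interior is invariant and the guard is
  never hit.
* Standing waves ($c \le 10^{-8}$) are rejected by the dispersion
  constructors: at $c = 0$ the leading drift at the wave vanishes and
  the square-root expansion around it breaks down. This is an explicit
  error, not a silent fallback.
* Fixed points are located to $10^{-12}$ by bracketed root refinement
  after a $10^{-4}$-step scan of $[-0.5, 1.5]$; "exact" balance
  statements hold to that accuracy.
* The drift positivity $-\hat b^m(t, \pi^m u^{TW}) > 0$ on the cutoff
  set needs the window half-length $L$ large enough; the constructors
  *report* a violation as an error rather than assuming a safe $L$
  (at the shipped fixtures it holds from $L = 2$ upward).

# A corrected constant

The quarter-interval averaged kernel satisfies
$\sup_k \sup_{x\in I^m_k}\|2m\,Q 1_{J^m_k} - q(x,\cdot)\|^2 \to 0$ as
$m \to \infty$, at rate $1/m$ — that is the hypothesis the
lattice-to-continuum theorem needs, and `remark_kernel_bound_check`
verifies it by direct quadrature. The constant usually quoted with this
estimate, $1/(4\varepsilon^2 m)$, is however optimistic by a factor of
two: the symmetric difference of two $\varepsilon$-boxes offset by $d$
has measure $2d$ (not $d$), and with cells $[k/m, (k+1)/m)$ against
quarter-intervals centered at $k/m$, offsets reach $5/(4m)$ (not
$1/m$). The repaired constant $1/(2\varepsilon^2 m)$ dominates the
measured supremum at every density (e.g. $0.917 \le 1.0$ at
$\varepsilon = 0.25$, $m = 8$, where the optimistic constant would be
$0.5$); both constants are reported.

# Known limitations

* The linear-noise model is trustworthy only while deviations stay
  small relative to the front width; see the $T = 1$, $N = 10^2$
  breakdown above.
* The synthetic study conditions (logistic gain, exponential/gaussian
  kernels, box correlation) exercise the theory's assumptions but not
  real-data features: heterogeneous connectivity, parameter drift, or
  non-sigmoid gains. Passing tests certify the mathematics and the
  numerics at desk scale, not biological fidelity.
* Wave stability spectra and Evans-function machinery are out of scope,
  as is any Heaviside (discontinuous) gain — the theory requires
  $F \in C^3$.
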