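---
title: "Genetic switching regimes: models, landscapes and the sorting experiment"
author: "switchscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic switching regimes: models, landscapes and the sorting experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(switchscape)
```

## The model

`switchscape` analyses a two-state gene expression network with a positive
feedback loop.  A single gene switches between a closed (inactive) and an
open (active) chromatin state; the open gene transcribes mRNA, mRNA is
translated into protein, and the protein feeds back by promoting gene
activation.  Six reactions act on the microstate $(\alpha, m, n)$ — gene
state, mRNA count, protein count:

| # | reaction | propensity |
|---|-----------------------------|--------------------------|
| 1 | open $\to$ closed           | $d_G$                    |
| 2 | closed $\to$ open           | $k_G\,O_P + k_{G0}$      |
| 3 | transcription (open only)   | $k_R\,O_P + k_{R0}$      |
| 4 | translation                 | $k_P\, m$                |
| 5 | mRNA decay                  | $d_R\, m$                |
| 6 | protein decay               | $d_P\, n$                |

with the feedback occupancy $O_P = n^k/(n^k + K^k)$ (Hill exponent $k$,
default 1; `hillK` exposes dimer-type feedback $k=2$ and higher).  Two
conventions worth spelling out:

* **Translation is proportional to the mRNA count**, $k_P m$.  This is
  the form consistent with the reaction table and the deterministic rate
  equations; all modules use it.
* **Units.** All rates are "per model time unit"; no physical duration is
  attached to a time unit, and every reported time is in model time
  units.  Copy numbers are molecule counts (volume $V = 1$), so the
  continuum objects below (Gaussian means, quasi-potential coordinates)
  live on the same axes as the lattice.

The canonical parameter set (`paramsPreset("slow")`) is $k_R = 100$,
$k_{R0} = 0.1$, $k_P = 51.5$, $d_R = 0.7$, $d_P = 1.4$, $d_G = 0.0014$,
$k_G = 0.028$, $k_{G0} = 0.00028$, $K = 3000$.  The dimensionless ratio
$\kappa = d_G / d_P$ compares the gene-state lifetime with the protein
lifetime: $\kappa \ll 0.01$ is the slow (non-adiabatic) regime,
$\kappa \gg 1$ the fast (adiabatic) one.  `kappaFamily(kappa, base)`
traverses $\kappa$ while keeping the ratios $d_G/k_G = 0.05$ and
$d_G/k_{G0} = 5$ locked, which is how every sweep and perturbation in the
package changes the switching rates.  A useful consequence: the
adiabatically reduced drift (below) depends on the gene rates only
through these ratios, so the basin geometry is invariant along a locked
family.

## Exact machinery

**CME.**  The chemical master equation is solved on a truncated lattice
$0 \le m < M$, $0 \le n < N$ with reflecting truncation (outflow across
the boundary suppressed) and both gene layers stacked.  The default
window (`autoGrid`) places the protein cutoff at $1.8\times$ and the
mRNA cutoff at $2.5\times$ the largest deterministic fixed point; every
solution carries the mass on the outermost shells (`boundaryMass`) so
the adequacy of any window is checked a posteriori rather than assumed
(default tolerance $10^{-8}$).

The stationary solver exploits the structure of the lattice rather than
a generic sparse factorisation: grouped by protein level $n$, the
generator is block tridiagonal and the inter-level blocks (protein birth
$k_P m$ and death $d_P n$) are *diagonal*.  Censored-chain (stochastic
complement) elimination then costs one dense $2M \times 2M$ inversion
per level; inverses needed again in the backward sweep are recomputed
from checkpoints every 64 levels, bounding memory at ~100 MB where a
direct sparse LU of the ~1.3 million-state generator would need fill in
the tens of GB.  Probability scales are renormalised per level with log
bookkeeping, so stationary tails far below double-precision range do not
underflow the recursion.  A full solve of the slow preset
($155 \times 4082 \times 2$ states) takes about 40 s on one CPU.  The
same elimination solves the first-passage system $Q\tau = -1$ for mean
switching times with a protein half-plane as absorbing target.  On small
windows (`method = "lu"`, and automatically below 20000 states) the
package instead solves the assembled sparse generator directly; the two
routes agree to machine precision and the direct route is the oracle in
the test suite.

**SSA.**  `simulateSSA` is a direct-method Gillespie sampler (C++ core),
reproducible from a single seed; replicate streams are split
deterministically so growing a batch never changes earlier replicates.
For long mean-switching-time sweeps `estimateMST(method = "tau")`
enables tau-leaping in which the two gene channels and any species below
20 copies stay exact and only the high-copy mRNA/protein channels leap
(relative-change control $\epsilon = 0.03$); the suite checks the leaped
switching-time estimate against the exact sampler.  Replicates that
exhaust their event budget are reported as censored, never silently
averaged.

**Basins.**  Basins are protein half-planes split at the saddle of the
reduced drift (below); the first time the protein count crosses the
split counts as arrival.  Switching runs start at the source basin's
metastable point: the per-layer fixed point (gene closed at the origin,
gene open at the expressed state) when $\kappa < 0.01$, the stable
points of the reduced drift otherwise.  The sorting experiment instead
uses its cytometry threshold $n > 400$.

## Slow regime: two layers and Gaussian mixtures

When the gene flips rarely, the dynamics decomposes into long sojourns
on one gene layer.  On layer $\alpha$ the means obey
$\dot m = \alpha(k_{R0} + k_R\,O_P) - d_R m$, $\dot n = k_P m - d_P n$,
and the covariance follows the linear-noise flow
$\dot\sigma = \sigma J^\top + J\sigma + 2D$.  The stationary picture is
a two-component mixture: each layer contributes a Gaussian at its fixed
point with the covariance solving the Lyapunov equation (solved
algebraically, not by long integration), weighted by the fraction of
time spent on that layer.

The closed-layer weight is the dwell-time balance
$w = \frac{1/k_{G0}}{1/k_{G0} + 1/d_G} = \frac{d_G}{d_G + k_{G0}}$,
since the escape rate from the closed layer is $k_{G0}$ (the protein has
decayed, $O_P \approx 0$) and from the open layer $d_G$.  At the
canonical rates $w = 5/6$: the gene is closed five sixths of the time,
and the exact CME gene marginal confirms it (the test suite asserts
agreement within 10%; it holds to better than 1%).  On the closed layer
every rate vanishes at the origin, so its simple-mixture component
degenerates to a point mass.

The *modified* mixture adds the relaxation information carried by
switching paths: the component of layer $\alpha$ is the time-average of
Gaussians along the moment flow started from the *other* layer's
stationary pair, averaged over one mean dwell time ($T_1 = 1/d_G$ on the
open layer, $T_0 = 1/k_{G0}$ on the closed).  The average is a
trapezoid quadrature on a log-spaced grid (200 nodes by default, first
node at $10^{-3}$ time units) so the fast early relaxation is resolved;
pieces with near-singular covariance deposit their weight on the nearest
lattice cell.  As $\kappa \to 0$ the dwell time dwarfs the relaxation
and the modified mixture collapses to the simple one.

Mixtures are compared with the CME on the integer lattice: densities are
evaluated at lattice points, renormalised per layer, floored at
$10^{-16}$, and scored by the Kullback–Leibler divergence
KL(CME ‖ approximation) — that direction weights errors where the exact
solution actually puts mass; the reverse direction is available via
`direction = "approx_first"` in `compareLandscapes`.  Across
$\kappa \in [10^{-5}, 10^{-2}]$ the modified mixture is at least as
close to the CME as the simple one on the closed layer, the open layer
and globally, and the two coincide in the frozen-gene limit — both
statements are asserted by the acceptance suite at full problem size.

## Fast regime: reduced drift and quasi-potential

For $\kappa \gg 1$ the gene equilibrates instantly and averaging over
its two states leaves a two-species jump process with four channels:
effective mRNA synthesis at rate
$(k_{R0} + k_R O_P)(k_{G0} + k_G O_P)/(d_G + k_{G0} + k_G O_P)$
(transcription rate times stationary open probability), mRNA decay,
translation, protein decay.  Summing jump $\times$ rate reproduces the
mean-field drift identically — an algebraic identity the tests check at
random states.  At the fast preset ($d_G = 140$, $k_G = 2800$,
$k_{G0} = 28$) the drift has two stable points and a saddle, found by
eliminating $m$ along the protein nullcline and polishing sign changes.

Rare transitions between the attractors are governed by the
Freidlin–Wentzell Hamiltonian
$H(x, p) = \sum_j a_j(x)\,(e^{\nu_j \cdot p} - 1)$: $H(x, 0) = 0$,
$\nabla_p H(x,0)$ is the drift, and the quasi-potential
$S(x)$ solves $H(x, \nabla S) = 0$ with
$P^{ss}(x) \propto e^{-V S(x)}$.  The sign convention is the standard
one — the stationary law is exponentially *small* where $S$ is large —
and $S$ is reported in copy-number units ($V = 1$).

`gmamPath` minimises the geometric (Maupertuis) form of the action over
curves: the action of a discretised curve is the sum over segments of
$\sup\{p\cdot\Delta\phi : H(x, p) \le 0\}$, the support function of the
zero sub-level set, evaluated at segment midpoints.  The inner
constrained problem ($\Delta = \mu \nabla_p H$, $H = 0$) is solved by a
damped Newton on $(p, \mu)$ jointly, warm-started across evaluations and
seeded by the closed-form solution of the quadratic (Gaussian)
approximation of $H$; a bracketed bisection on $\log\mu$ is the
fallback.  The outer problem is L-BFGS-B on the interior images with the
analytic envelope gradient ($\partial\ell/\partial\Delta = p^*$,
$\partial\ell/\partial x = -\mu\,\nabla_x H$), re-parameterising to
equal arc length between cycles; curve relaxation happens in
coordinates scaled by the endpoint span, which conditions the strongly
anisotropic mRNA/protein geometry.  Convergence is declared when the
action changes by less than $10^{-4}$ (relative) between cycles.
Deterministic (downhill) paths cost zero action; the 1-D birth–death
model with birth $b$ and death $dn$, whose quasi-potential is
$\int \ln(dn/b)\,dn$ in closed form, is reproduced to $10^{-5}$
relative — well inside the 1% the acceptance suite demands.  Both
optimal switching paths at the fast preset pass through the saddle and
are distinct, the uphill/downhill branches of each transition.

`globalQuasiPotential` assembles a landscape from the two local
quasi-potentials: a fan of minimum-action paths per attractor carries
cumulative actions, interpolated onto a regular grid by inverse-distance
weighting in scaled coordinates (nodes far from every path are masked,
not extrapolated); the on-surface is offset by the difference of the two
saddle barriers — the Freidlin–Wentzell consistency that makes the
assembly continuous at the saddle and encodes the relative stability of
the attractors — the global landscape is the pointwise minimum of the
two surfaces, and the result is anchored at zero minimum (which sits at
the deeper attractor).  The fan-plus-interpolation construction trades
smoothness for cost — it is a visualisation product; quantitative
statements in the package always go through `gmamPath` actions or the
CME directly.

## Switching times and the bistability window

`mstSweep` traverses $\kappa$ with locked ratios and estimates mean
switching times by SSA (or by first-passage solves,
`method = "mfpt"`).  The on-to-off time falls like the gene-closing
waiting time $1/d_G$ in the slow regime, reaches a minimum at
intermediate $\kappa$ (between $10^{-2}$ and $10^{-1}$ at $K = 3000$),
and rises to a $\kappa$-independent plateau in the fast regime.

Bistability is declared when both protein basins hold more than 1% of
the stationary mass.  `findKBoundary` locates the edges of the
fast-regime bistability window by Illinois-damped regula falsi on the
log-occupancy (close to linear in $K$), recomputing the truncation
window and basin split at every $K$; each evaluation is one CME solve,
and the defaults reach a $\pm 5$ resolution in about six solves.  At
the fast preset the recovered boundaries are $K \approx 2752$ and
$K \approx 3220$, and moving $K$ from the lower to the upper boundary
multiplies the off-to-on switching time by $\approx 8$ while dividing
the on-to-off time by $\approx 10^{3}$.

## The sorting experiment and the regime classifier

`sortingExperiment` emulates flow cytometry: 50,000 cells (default) are
sampled *jointly* over gene state, mRNA and protein from the stationary
CME solution, sorted at $n > 400$ into P+ and P− groups, and cultured
independently by exact simulation; each group's P+ fraction is recorded
on a geometric time grid spanning $[0.1\,T, 30\,T]$, where $T$ is the
deterministic reference transition time — the time the closed-layer
relaxation from the expressed state takes to cross the threshold
(closed form for on-to-off; numerically integrated with a root stop for
off-to-on).  The cohort-weighted average of the two groups' fractions
is a martingale pinned at the stationary P+ mass, a consistency check
the suite enforces at binomial precision.

The classifier uses two statistics:

1. **Relaxation.**  If the P+ group has moved more than half of the way
   to equilibrium by the end of the $30\,T$ window, the regime is
   *intermediate*.  The window is a deliberate departure from a shorter
   $3\,T$ horizon: at the switching-time valley the mean switching time
   (~56 time units at $K = 3000$) is an order of magnitude larger than
   $T \approx 3.4$, so at $3\,T$ even the intermediate regime has moved
   only ~20% of the gap and no threshold separates the regimes, while at
   $30\,T$ the separation is wide (intermediate ~90% vs ~5–15% for slow
   and fast).
2. **Perturbation response.**  Otherwise, $\kappa$ is multiplied (default
   4 and 30, ratios locked) and the signed change in the P+ group's
   time-to-half-recovery decides: at least 25% faster recovery means
   *slow* (larger $\kappa$ moves the system down the falling branch of
   the switching-time curve), anything else *fast* (the plateau).  The
   $\times 30$ default carries the slow preset into the valley, which
   makes its response unambiguous; recovery times censored at the
   horizon are scored at the horizon, so "both censored" reads as an
   unchanged (fast-regime) response.  Perturbed cohorts are still drawn
   from the baseline stationary law — the perturbation hits cells at
   their unperturbed steady state — while recovery is measured toward
   the perturbed equilibrium.

On the three canonical presets ($\kappa = 0.001$, the valley
$\kappa = 0.03$, and $\kappa = 50$) the classifier returns slow /
intermediate / fast across seeds; this is asserted by the test suite.

## Numerical choices and degenerate inputs

* Probability floors: $10^{-16}$ for landscapes and divergences (the
  value also used for the mixture comparisons); steady-state mass is
  clamped at 0 and renormalised after each backward level.
* The Hamiltonian caps exponent arguments at 500 and flags the cap; the
  support-function solve guards $\mu > 0$ and falls back from the joint
  Newton to bisection on failure.
* Degenerate sub-models (zero rates) that decouple protein levels are
  routed to the direct sparse solve automatically.
* `findCriticalPoints` flags monostable parameter sets rather than
  failing; basin helpers then fall back to the per-layer fixed points.
* Ties and empty cases: empty reactive ensembles are legal results (no
  switch happened); empty sorted groups report NA fractions; first
  record times coincide with sorting, so group purity at $t = 0^+$ is
  exact by construction.

## What the synthetic conditions do and do not show

All analyses run on parameters in the regime the canonical presets
define; there is no external data.  The model has intrinsic noise only —
no extrinsic rate variability, no cell division or dilution, no
fluorescence calibration or gating spillover, and sorting is error-free.
Passing tests therefore validate the mathematical machinery and the
internal consistency of the three-regime picture, not the measurement
physics of a real cytometry experiment.  Problem sizes in the test suite
are chosen to keep a full run under half an hour on one CPU: full-size
CME solves (~1.3M states) appear where the claim demands them (gene
marginal, mixture hierarchy, bistability boundaries, first-passage
ratios), while property-style checks run on the scaled-down bistable
fixture whose exact solution is available from the direct solver.  The
scaled-down switch has shallow basins (intrinsic fluctuations cross its
basin split without a gene flip), which is precisely why the
regime-classification claims are always tested at full scale.

## Known limitations

* The QSSA reduction behind the fast-regime machinery assumes
  $\kappa \gg 1$; applying `gmamPath` to slow-regime parameters produces
  a well-defined answer for the *reduced* process that does not describe
  the two-layer mechanism that actually governs slow switching.
* The global quasi-potential grid is an interpolation of path fans, not
  a Hamilton–Jacobi solve; masked (NA) nodes appear where no fan path
  passes nearby.
* At unit volume the exact per-state potential $U = -\ln P^{ss}$ and the
  rate function $S$ can rank the basins differently: $U$ carries the
  entropic spread of each basin (the expressed basin spreads comparable
  mass over hundreds of protein counts), while $S$ is the
  large-deviation limit $V^{-1} U$ as $V \to \infty$.  At the fast
  preset the two are *not* monotonically related along the switching
  paths; comparisons between them should be made only at large volume.
* Tau-leaping slightly distorts arrival-time statistics near the basin
  boundary; it is off by default everywhere except the long sweeps, and
  the bias is checked against the exact sampler at the valley.
* The deterministic reference time $T$ underestimates the stochastic
  dwell-excluded transition time (the last-touch convention includes
  diffusive dithering around the metastable level before commitment);
  it is a timescale, not an unbiased estimator.
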