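---
title: "Dynamic resource allocation in the self-replicator model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic resource allocation in the self-replicator model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfrep)
```

## The model

`selfrep` implements a coarse-grained model of a growing microbial cell
reduced to two macroreactions. The metabolic machinery (concentration
$m$) converts external substrate into precursor metabolites ($p$), and
the gene-expression machinery ($r$, essentially ribosomes) converts
precursors into new machinery of both kinds. A single control variable
$\alpha(t) \in [0,1]$, the resource allocation parameter, sets the
fraction of macromolecule synthesis directed to the gene-expression
machinery. With Michaelis–Menten kinetics and the assumption of constant
cytoplasmic density (volume proportional to total macromolecular mass,
$r + m = 1/\beta$), the dimensional system is

$$
\frac{dp}{dt} = e_M\!\left(\tfrac{1}{\beta} - r\right)
  - k_R\,\frac{r\,p}{K_R + p}\,(1 + \beta p),\qquad
\frac{dr}{dt} = k_R\,\frac{r\,p}{K_R + p}\,(\alpha - \beta r),
$$

with growth rate $\mu = \beta k_R\, r p/(K_R+p)$. The substrate term is
folded into the effective nutrient efficiency $e_M$ (units 1/h), taken
constant over the interval of interest: either the substrate
concentration is constant or it saturates the uptake kinetics. The
package's reference parameterization is $e_M = 3.6\,h^{-1}$,
$k_R = 3.6\,h^{-1}$, $K_R = 1\,g\,L^{-1}$, $\beta = 0.003\,L\,g^{-1}$,
an *E. coli*-like set.

Rescaling ($\hat p = \beta p$, $\hat r = \beta r$, $\hat t = k_R t$)
leaves two constants: the environment input $E_M = e_M/k_R$ and
$K = \beta K_R$ (reference values $E_M = 1$, $K = 0.003$):

$$
\frac{d\hat p}{d\hat t} = (1-\hat r)E_M - (1+\hat p)\,\hat\mu,\qquad
\frac{d\hat r}{d\hat t} = \hat\mu\,(\alpha - \hat r),\qquad
\hat\mu = \frac{\hat r\,\hat p}{K + \hat p}.
$$

`rhs_dim()`/`rhs_nondim()` expose both fields, and a round-trip test
verifies their equivalence under the rescaling.

## Steady states and growth laws

For constant $\alpha \in (0,1)$ the system has a trivial unstable fixed
point $(0, 1)$ and a unique nontrivial steady state with
$\hat r^* = \alpha$ and $\hat p^*$ the positive root of a quadratic;
`steady_state_for_alpha()` always takes the "+" branch, the only
nonnegative one, and assesses stability from a central-difference
Jacobian (relative step $10^{-7}$) rather than a transcribed symbolic
Jacobian. Fixed-point residuals are required to be below $10^{-10}$ and
closed-form identities below $10^{-12}$; these tolerances live in one
place, `selfrep_tolerances()`.

Maximizing the steady-state growth rate over $\alpha$ gives the
closed-form optimum implemented in `optimal_allocation_env()`,

$$
\alpha^*_{opt} = \frac{E_M + \sqrt{K E_M}}{E_M + 2\sqrt{K E_M} + 1},
\qquad
\hat\mu^*_{opt} = \frac{E_M}{E_M + 2\sqrt{K E_M} + 1},
$$

which equals exactly $1/2$ at the reference environment. The same locus
expressed as a function of the precursor abundance is the curve
$g(\hat p) = \hat p(K+\hat p)/(\hat p^2 + 2K\hat p + K)$
(`optimal_curve_g()`). The printed form of this expression is ambiguous
in common typesettings; the package fixes it by the requirement
$g(\hat p^*_{opt}(E_M)) = \alpha^*_{opt}(E_M)$ for all $E_M$, which the
test suite verifies to $10^{-10}$ over four decades of $E_M$, and by
consistency with $\hat\mu^*_{opt}(\hat p) =
\hat p^2/(\hat p^2 + 2K\hat p + K)$.

Sweeping $e_M$ at fixed $k_R$ reproduces the first empirical growth law
(quasi-linear ribosomal fraction versus growth rate across media);
sweeping $k_R$ downward at fixed $e_M$ — emulating a translation
inhibitor such as chloramphenicol — reproduces the second
(`predict_growth_law()`, `chloramphenicol_series()`).

## Fitting the growth laws

`fit_growth_laws()` estimates $k_R$, the RNA/protein-to-allocation
conversion factor $\gamma$ (via $\hat r^* = \alpha^*_{opt} =
\gamma\,\mathrm{RNA}/\mathrm{protein}$), per-medium $e_M$, and per-dose
$k_R$ multipliers from a table of (growth rate, RNA/protein ratio)
measurements, with $K$ fixed from literature values. The global search
uses a differential evolution optimizer (rand/1/bin, population
$15\times$ dimension, 500 generations by default, fixed seed) written
in the package, followed by a deterministic quasi-Newton polish; bounds
are $k_R \in [0.1, 20]\,h^{-1}$, $e_M \in [0.01, 50]\,h^{-1}$, dose
multipliers in $(0, 1]$.

The loss was a genuinely open design choice. We evaluated two variants:

* **joint** (default): per-medium $e_M$ are free parameters shared
  across the dose series, and the loss sums squared *relative* residuals
  of both predicted coordinates. Sharing $e_M$ across doses is what
  makes $k_R$ identifiable: the curvature of the dose series at fixed
  medium pins the translation efficiency.
* **ratio_inversion**: $e_M$ is inverted point-by-point from the
  observed growth rate and only ratio residuals are scored. This halves
  the search dimension but silently absorbs all growth-rate noise into
  the per-point inversions; in a 20-replicate study at 5% measurement
  noise it leaves $k_R$ essentially unidentified, which is why it is not
  the default.

$\gamma$ enters linearly and is profiled out in closed form in both
variants.

`generate_synthetic_dataset()` is the package's stand-in for the
classical measurement design: 6 media ($e_M$ from 0.5 to
4.76 $h^{-1}$, spanning poor to rich), 5 inhibitor doses modelled as
$k_R$ multipliers $\{1, 0.8, 0.6, 0.45, 0.3\}$, true $k_R =
2.23\,h^{-1}$ and $\gamma = 0.76$, and multiplicative Gaussian noise
(default 5%) on both observed coordinates. Each synthetic point is an
*exact* optimal steady state of the forward model, so fitting is an
identity-recovery problem: what passing tests show is that the
estimation machinery works, not that the model fits any real organism's
measurements. Real data additionally carry non-Gaussian errors,
correlated replicates, and model misspecification (the real RNA/protein
ratio is only proportionally related to ribosomal allocation on
average), none of which the generator emulates.

## Biomass maximization as an optimal control problem

After a nutrient upshift at $t=0$ ($E_M$ steps from $0.2 E_M$ to
$E_M$, the cell starting at the pre-shift optimal steady state), the
biomass produced over $[0,\tau]$ is
$\log(\mathrm{Vol}(\tau)/\mathrm{Vol}(0)) = \int_0^\tau \hat\mu\,
d\hat t$, and growth-maximal allocation becomes the optimal control
problem $\max_{\alpha(\cdot) \in [0,1]} \int_0^\infty \hat\mu\,d\hat t$
(in the overtaking sense, since the integral diverges). Theory says the
solution is *bang-bang-singular*: arcs of $\alpha = 1$ and $\alpha = 0$
entering, through an infinite chattering sequence of switches, a
singular arc that holds the optimal steady state of the new
environment.

Numerical choices:

* **Truncation and terminal handling.** The infinite horizon is
  truncated to $\hat\tau = 30$ (about 8 hours at the reference
  $k_R$ — several generations past convergence) and the final state is
  pinned to the optimal steady state through a quadratic penalty
  (weight $10^4$). Pinning removes the end-of-horizon artifact of
  dumping precursors just before $\tau$; the residual terminal distance
  is reported and is $\sim 10^{-5}$ in practice. A `"free"` terminal
  mode is available.
* **Transcription.** The control is piecewise constant on $N$ uniform
  intervals ($N = 1000$ by default, $4000$ in the high-resolution
  preset) and the dynamics are discretized by fixed-step RK4; states
  are eliminated by the forward recursion, so the decision variables
  are the $N$ controls with box constraints. `transcribe()` also
  exposes the defect constraints of the discrete dynamics so that
  feasibility can be checked against an independent stiff integrator
  (they agree to $<10^{-8}$).
* **Optimization.** Projected quasi-Newton (L-BFGS-B) with an exact
  discrete-adjoint gradient implemented in C++ — each
  objective/gradient pair costs two $O(N)$ sweeps. The initial guess is
  the on-off closed-loop control, which already has the right arc
  skeleton; deterministic perturbed and constant-allocation restarts
  cover non-convergence.
* **Chattering refinement.** Near the singular entry the objective is
  numerically flat (representations with 3–7 switches differ by less
  than $10^{-6}$ in $J$), so the smooth optimizer blurs the bang
  structure into ramps. `solve_ocp()` therefore finishes with a
  switching-time optimization: the bang skeleton is extracted from the
  sign pattern of $\alpha - 1/2$, switch times are optimized as
  continuous variables (fractional grid intervals handled by control
  averaging), and the singular tail is re-polished. The refined control
  is kept only if its objective matches or exceeds the smooth optimum
  within the solver tolerance — structure is never bought with
  optimality. Chattering is representable only down to the grid step;
  arcs shorter than one interval are not claimed.

On the reference upshift this yields $J = 14.1087$ with the arc
sequence bang($\alpha=1$) → bang(0) → bang(1) → bang(0) → singular
plateau at $\alpha = 0.500$, and doubling $N$ moves $J$ by less than
$10^{-7}$ relative. `estimate_switching_curve()` recovers the switching
curve $\varphi$ by recording the state at every bang-to-bang switch
across solutions from different initial states; the sampled curve
passes through the optimal steady state to $\sim 10^{-3}$ and closing
the loop on it reproduces the optimal payoff to well under 1%.

## Feedback strategies

Three static feedback laws satisfy the requirements of stabilizing the
growth-optimal steady state in every constant environment:

* **nutrient-only**: $\alpha = f(E_M)$, the closed-form optimum itself
  (constant after the upshift). Approximated biochemically by a
  Michaelis–Menten response `f_mm_approx()`.
* **precursor-only**: $\alpha = g(\hat p)$. Approximated by a Hill
  response with coefficient 2, `g_hill_approx()`. The half-saturation
  constants of both approximations are not fixed by theory; the package
  fits them once by least squares over documented domains
  ($E_M \in [0.01, 10]$, $\hat p \in [0, 1]$; both approximations stay
  within 0.05 of the exact laws) and memoizes them per $K$.
* **on-off**: $\alpha = 0$ above the curve $\hat r = g(\hat p)$,
  $\alpha = 1$ below it, $\alpha^*_{opt}$ at the optimal point. The
  discontinuity induces a sliding mode along the curve; rather than
  Filippov regularization, closed-loop integration substitutes the
  continuous surrogate
  $g(\hat p)^n/(g(\hat p)^n + \hat r^n)$ with $n = 100$, evaluated in
  log space as $1/(1 + e^{\,n(\log \hat r - \log g(\hat p))})$ to avoid
  underflow of the 100th powers. The surrogate makes the closed loop
  stiff; `integrate_closed_loop()` uses `deSolve` with relative
  tolerance $10^{-10}$ and absolute $10^{-12}$, reporting on a
  2000-point grid by default. One consequence of the surrogate worth
  knowing: away from $E_M = 1$ its sliding equilibrium sits where the
  logistic equals $\alpha^*_{opt} \ne 1/2$, i.e. offset from the curve
  by a relative $\mathrm{logit}(\alpha^*_{opt})/n$ — about 1% of
  $\hat r$ at the tested environments. Halving the integrator
  tolerances moves final log-volumes by less than $10^{-6}$, and
  extending the horizon by 50% moves final biomass ratios by less than
  $10^{-3}$.

On the reference upshift the package computes final biomass fractions
$\mathrm{Vol}/\mathrm{Vol}_{opt}$ of 0.519 (nutrient-only), 0.941
(precursor-only) and 0.983 (on-off): sensing the precursor pool
dominates sensing the environment alone, and sensing the
precursor–ribosome *imbalance* is nearly optimal. The ratio can
transiently exceed 1 around the optimal control's first switch — the
optimum maximizes the horizon objective, not the running volume — but
never at the final time.

## The ppGpp read-out

In enterobacteria the alarmone ppGpp rises when ribosomes stall on
uncharged tRNA and inhibits ribosomal RNA transcription, making it a
natural candidate implementation of the on-off law. The package's
reduced quasi-steady-state model (`ppgpp_params()`, `ppgpp_qss()`)
lumps all amino acids into the precursor pool and takes tRNA charging
and ppGpp turnover as fast:

* charging capacity is a cooperative function of the precursor level,
  $S(\hat p) = A\,\hat p^2/(\hat p^2 + K_t^2)$; $(A, K_t)$ are
  calibrated once by anchoring $S$ to the optimal curve $g$ at the
  $E_M = 1$ optimal precursor abundance and at $\hat p = 1$
  (this keeps $A < 1$, so the switch always falls inside the
  admissible ribosome range), then frozen;
* translation demand is proportional to $\hat r$; the uncharged-tRNA
  fraction solves a zero-order Goldbeter–Koshland balance between the
  two (saturation constants 0.002), making the stalled-ribosome
  fraction $\sigma$ ultrasensitive to the demand/supply imbalance;
* RelA-driven synthesis proportional to $\sigma$ against first-order
  degradation gives $\mathrm{ppGpp} = \mathrm{basal} +
  \mathrm{gain}\cdot\sigma$ (defaults 10 and 1000 µmol/L, plausible
  for basal and stringent-response concentrations), and transcription
  inhibition maps it to allocation via $\alpha = K_I/(K_I +
  \mathrm{ppGpp})$. $K_I$ is calibrated so that $\alpha =
  \alpha^*_{opt}$ on the curve at the $E_M=1$ optimal point, giving
  $K_I = 510$ µmol/L.

With this calibration the $\alpha = 0.5$ contour of the ppGpp surface
coincides with $\hat r = S(\hat p) \approx g(\hat p)$, and
`compare_surfaces()` (fraction of grid points outside a band of 0.02
around the curve where both surfaces fall on the same side of 0.5)
scores 1.00 against the on-off surface on the default grid. The
composed response is switch-like: its 10–90% transition width in
$\hat r$ is under 5% of $g(\hat p)$. Because the hyperbolic map caps
the far-field values (at $\sigma \to 1$, $\alpha \to
K_I/(K_I + \mathrm{basal} + \mathrm{gain}) \approx 1/3$), the surface
is a compressed version of the on-off surface; it classifies states
identically but does not reach 0. The full kinetic ppGpp model and a
dynamic closed loop under ppGpp control are out of scope — only the
static surfaces are compared.

## Problem sizes and limitations

The test suite runs the upshift scenario at $N = 1000$ control
intervals (the high-resolution arc-structure check at $N = 4000$),
horizon 30, 2000 reporting points, and the parameter-recovery study at
20 replicates with 150 DE generations; the whole suite completes in
about a minute on a single core. Known limitations: no substrate
depletion dynamics, degradation, or maintenance costs (excluded by the
model's assumptions); downshifts work mechanically (`pre_factor > 1`)
but are untested against any reference; the chattering entry is
resolved only to grid resolution; and the regulatory cost of
implementing a feedback strategy is not modelled, so strategy rankings
compare information content, not full physiological cost.
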