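---
title: "Bayesian mechanics of Markov blankets: models, checks and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian mechanics of Markov blankets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmech)
```

## The model

`bayesmech` works with stochastic systems that possess a nonequilibrium
steady state (NESS): a stationary density $p(x)$ maintained by nonzero
probability currents.  The stationary flow of such a system admits a
Helmholtz decomposition

$$\dot x = f(x) + \omega, \qquad
  f(x) = (Q - \Gamma)\,\nabla \Im(x),$$

where $\Im(x) = -\log p(x)$ is the surprisal of the steady-state
density, $\Gamma$ is a diagonal positive diffusion matrix
(the amplitude of the independent random fluctuations $\omega$), and
$Q = -Q^\top$ is an antisymmetric matrix mediating solenoidal flow:
divergence-free circulation on the iso-probability contours of $p$.
The dissipative part $-\Gamma\nabla\Im$ counteracts dispersion by the
fluctuations; the solenoidal part $Q\nabla\Im$ breaks detailed balance
without changing the stationary density.  Both $Q$ and $\Gamma$ are
treated as constant in $x$ — the simplification under which the Gaussian
(Ornstein–Uhlenbeck) theory below is exact and nonlinear systems are
handled through user-supplied surprisal callables.

For a Gaussian steady state with precision $H$ (so
$\Sigma = H^{-1}$), the flow is linear with constant Jacobian
$J = (Q - \Gamma) H$, and the continuous Lyapunov identity

$$J\Sigma + \Sigma J^\top + 2\Gamma = 0$$

holds *identically* for every antisymmetric $Q$ — the algebraic
statement that solenoidal flow leaves the steady state untouched.  The
package's noise convention follows from this identity: random increments
have covariance $2\Gamma\,dt$, the unique scaling under which
$N(\mu, H^{-1})$ is stationary for $J = (Q-\Gamma)H$.  The convention is
fixed once, stated on every constructor, and verified by the sampling
tests.

## Markov blankets from sparse coupling

States are partitioned into external $\eta$, sensory $s$, active $a$ and
internal $\mu$, with blanket $b = (s, a)$, autonomous states
$\alpha = (a, \mu)$ and particular states $\pi = (\mu, b)$.  Two distinct
requirements are in play:

* **condition 1 (flow)** — autonomous states are uncoupled from external
  states: $J_{\mu\eta} = J_{a\eta} = 0$;
* **condition 2 (blanket)** — internal and external states are
  conditionally independent given the blanket, which for a Gaussian
  density is exactly $H_{\mu\eta} = 0$.

Neither implies the other.  `make_fixture()` constructs explicit
witnesses both ways: a system satisfying the flow constraint with
$H_{\mu\eta} \ne 0$ (solving for the solenoidal entries that make the
offending Jacobian blocks cancel), and a system with $H_{\mu\eta} = 0$
whose solenoidal coupling $Q_{\eta\mu} \ne 0$ breaks the flow
constraint.

The admissible *sparse form* supplements the blanket condition with
$H_{\eta a} = H_{s\mu} = 0$ and precludes solenoidal coupling between
autonomous and non-autonomous states:
$Q_{\eta a} = Q_{\eta\mu} = Q_{sa} = Q_{s\mu} = 0$.  Under these zeros
the Jacobian blocks $J_{\eta\mu}, J_{s\mu}, J_{a\eta}, J_{\mu\eta}$
vanish *identically* (each is a sum of products in which every factor
carries a mandated zero), so `check_sparse_form()` reports exact zeros
rather than small residuals, and `autonomous_flow()` can assemble the
$\alpha$-rows of the flow from particular states alone, to machine
precision.  Solenoidal coupling *within* the partition — between
$\eta$ and $s$, or between $a$ and $\mu$ — survives; suppressing it too
gives the fully block-diagonal special case reported as `condition3`.

`find_admissible_partitions()` searches labelings by backtracking with
pairwise pruning (a coupled pair of states restricts the label pairs it
may receive), which is exact and fast up to the stated 12-state limit.
No heuristic search is offered above that limit: the function's point is
certified enumeration, not discovery at scale.

## The free-energy lemma

For a blanket-compliant Gaussian system the conditional expectations
$\boldsymbol\mu(b) = E[\mu \mid b]$ form the internal statistical
manifold; each point parameterises a belief $q_{\boldsymbol\mu}(\eta)$
over external states.  The variational free energy of particular states
is computed in three closed forms, each by an independent route:

$$F(\pi) = \underbrace{E_q[\Im(\eta,\pi)]}_{\text{energy}}
         - \underbrace{H[q]}_{\text{entropy}}
         = \underbrace{\Im(\pi)}_{\text{surprisal}}
         + \underbrace{D[q \,\|\, p(\eta \mid b)]}_{\text{bound}}
         = \underbrace{E_q[\Im(\pi \mid \eta)]}_{\text{inaccuracy}}
         + \underbrace{D[q \,\|\, p(\eta)]}_{\text{complexity}}$$

Their agreement (to $10^{-8}$, typically $10^{-12}$) is enforced by the
test suite, together with $\mathrm{bound} \ge 0$ and
$F \ge \Im(\pi)$.  The `surprisal + bound` split uses
$p(\eta \mid b)$; it equals $p(\eta \mid \pi)$ exactly when
$H_{\mu\eta} = 0$, which is why the identity is stated for
blanket-compliant systems.  A one-dimensional adaptive-quadrature oracle
recomputes every expectation and divergence independently of the closed
forms.

Three regimes of the evidence bound $c(b) = D[q\,\|\,p(\eta\mid b)]$
matter:

1. `q_exact()` — the bound collapses to zero and the free-energy
   gradient flow *is* the surprisal gradient flow.
2. A variance-inflated, mean-matched Gaussian family — $c > 0$ but
   constant over the manifold (the KL depends only on the covariance
   ratio for a homoscedastic system), so the two gradient flows still
   coincide: the size of the bound does not matter, only its constancy.
3. A family whose parameters read the blanket — the gradient discrepancy
   equals $\nabla_\alpha c$ exactly, which `gradient_equivalence()`
   returns alongside both gradients.

One structural subtlety the implementation surfaced: in a sparse-form
system the posterior $p(\eta \mid b)$ depends on the *sensory* states
only ($\eta$'s graphical neighbours are $s$), so a blanket-independent
$q$ already has zero autonomous bound gradient.  A genuinely varying
bound requires a family whose parameters read active states; the tests
construct their witness accordingly.

The constancy of $c$ is never assumed: `evidence_bound_profile()`
reports the defect $\max c - \min c$ over a user grid and leaves the
judgement to the user, since no quantitative threshold exists for "varies
sufficiently slowly".

The internal-manifold coordinate is the conditional expectation of the
internal states, not the raw internal state.  Evaluating a variational
family at raw internal coordinates is possible but only behind the
explicit `heuristic_raw_internal` flag, because that reading conflates
the manifold with the fluctuating state on it.

## The macromolecular soup

`simulate_soup()` is a demonstration world: $n$ molecules, each carrying
a 3-D electrochemical state evolving as a stochastic Lorenz attractor
(classical parameters $\sigma = 10$, $\rho = 28$, $\beta = 8/3$;
unstated in the source material, so the textbook values are the
default), diffusively coupled with strength
$k(d) = k_0 e^{-d^2 / 2\ell^2}$ in the inter-molecule distance, plus
stochastic Newtonian motion forced by mixed electrochemical differences
between neighbours.  Reimplementation choices, stated once and fixed:

* **Geometry.** Two spatial dimensions; molecules initialised on a line
  with spacing $\ell$ (a small rod).  An anisotropic harmonic trap —
  weak along the rod, stiff across it — plus short-range repulsion and
  velocity damping keep the ensemble extended, cohesive and ordered.
  Without the lateral stiffness the rod blurs into a blob and the layer
  structure of the partition degrades.
* **Coupling strength.** $k_0 = 6$ at $\ell = 1.5$ puts adjacent
  attractors in the partial-synchronisation regime (pairwise
  correlations of matched components well above chance but far from
  identity), which is the regime in which generalised synchronisation
  across a blanket is visible at all.  This is a property of the stated
  world, chosen once; it was not tuned against any test statistic.
* **Forces.** The pairwise force is
  $g\,k(d_{ij})\,(w^\top(c_i - c_j))\,\hat u_{ij}$ with a fixed mixing
  vector $w = (1,0,0)$ and small gain $g$, the minimal reading of
  "forces based upon the difference in electrochemical states".
* **Noise streams.** Each molecule consumes its own seeded stream, so
  the decoupled limit reproduces isolated single-molecule runs
  bit-for-bit — the factorisation test is exact, not statistical.
* **Analysis window.** The final 512 time units by default; the mini
  configuration shortens the horizon (30 units, window 20) so that the
  full pipeline runs in seconds.

The analysis pipeline mirrors the figure it emulates: a deterministic
radial/graph partition of molecules into internal, active, sensory and
external (innermost molecules seed the internal set; coupling-graph
layers supply the blanket; by default the graph is the symmetrized
2-nearest-neighbour graph, which is robust to the slow breathing of the
rod), canonical correlation between internal electrochemical states and
external velocities ("motion" is read as velocity by default;
positions can be appended), a fifth-order polynomial synchronisation
manifold with 90% prediction intervals, and event-related averaging
time-locked to the six largest well-separated peaks of the first
canonical variate (greedy selection with an exclusion radius equal to
the epoch length).

What a green soup test establishes — and what it does not: the simulator
shows that a blanket-shaped coupling graph produces internal states that
carry statistically significant information about external motion
(first canonical correlation above a 1000-shuffle permutation null), and
that epoch averaging concentrates a reproducible waveform.  It does not
establish anything about biological macromolecules, nor reproduce any
specific published trajectory; integrators, seeds and force models
differ from other implementations by construction.

## Numerical choices

* Euler–Maruyama throughout, with the step size in the caller's hands;
  a divergence guard (default $10^6$ per coordinate) truncates and
  warns rather than propagating non-finite states.  At the default steps
  the integrator bias is far below the Monte-Carlo error of every
  statistic tested against (batch-means standard errors, 3-SE
  acceptance).
* Exact-algebra checks use a default tolerance of $10^{-8}$; sampling
  checks use three standard errors.  Canonical correlations are computed
  by SVD of the whitened cross-covariance, with eigenvalue-thresholded
  rank reduction (warning on deficiency) and a sign convention (first
  nonzero internal loading positive) that makes results deterministic.
* Free-energy gradients are computed by central differences with step
  $10^{-5}$ scaled by coordinate magnitude; closed-form Gaussian
  gradients serve as the cross-check in tests and are authoritative
  where both exist.
* JSON serialisation writes doubles at 17 significant digits, so system
  specs round-trip bit-identically.

## Limitations

Non-Gaussian steady states are supported only through user-supplied
surprisal callables with finite-difference derivatives; there is no
estimation of $H$ from data beyond the empirical-precision utility used
by the soup checks; state-dependent $Q(x)$, generalised coordinates of
motion, and path-integral treatments of planning are out of scope.
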