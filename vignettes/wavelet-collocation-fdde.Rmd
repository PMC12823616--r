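---
title: "Methods: Daubechies wavelet collocation for fractional delay systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Daubechies wavelet collocation for fractional delay systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefdde)
```

## The model and its assumptions

The flagship application is a delayed SIR system for short-term influenza
dynamics in a closed population of size $N$:

$$
\begin{aligned}
{}^C D^\alpha S(t) &= -\beta\, S(t)\, I(t-\tau) + \delta I(t),\\
{}^C D^\alpha I(t) &= \beta\, S(t)\, I(t-\tau) - (\delta+\gamma) I(t),\\
{}^C D^\alpha R(t) &= \gamma I(t),
\end{aligned}
$$

with Caputo derivatives of order $0<\alpha\le 1$, a discrete delay $\tau$
(the incubation period) in the transmission term, and reinfection at rate
$\delta$ (immunity after influenza infection wanes). Initial data are
*history functions* $\phi_1,\phi_2,\phi_3$ on $[-\tau,0]$. The modelling
assumptions are the standard ones for a few-weeks outbreak: no
demography, constant rates, homogeneous mixing. Rates are used at face
value; under Caputo dynamics their formal unit is time$^{-\alpha}$, and no
dimensional rescaling is applied — a run at a different $\alpha$ with the
same numerical rates is a different model, not a reparameterization.

The three right-hand sides cancel identically, so the exact dynamics
conserve $S+I+R=N$. In the discretization below the three equations share
one fractional-integration matrix, which transfers this cancellation to
the numerical solution: conservation holds to solver tolerance
(observed $\sim 10^{-15}$ relative), independent of resolution.

The built-in scenario fixes the histories ($620-5t$, $10+2t$, $70+3t$ on
$[-2,0]$), $\tau=2$, $N=700$ and horizon $T=10$. Two variants are
shipped, `"as_text"` (I starts at 10) and `"as_tables"` (I starts at 70),
because published statements of this configuration are internally
inconsistent about which compartment starts where; the package never
picks a side silently. The default rates $\beta=5\cdot10^{-4}$,
$\gamma=0.1$, $\delta=0.05$ and order $\alpha=0.9$ are this package's
illustrative placeholders — the scenario definition itself does not
determine them — and every function accepts explicit values.

## Basis construction

**Filters.** Daubechies low-pass filters of order $N\in[2,10]$ are
computed by spectral factorization of the half-band polynomial
(`polyroot`, complex Newton polishing of roots, minimal-phase root
selection) followed by a Gauss–Newton projection onto the defining
constraints (normalization $\sum h_k=\sqrt2$, double-shift
orthonormality, $N$ vanishing moments). The projection removes the
convolution roundoff that otherwise grows to $\sim10^{-12}$ at order 10;
after it, all constraints hold to machine precision at every supported
order. The db2 coefficients are pinned against their closed form in the
tests.

**Scaling functions.** There is no closed form for the Daubechies scaling
function; values at the integers are the eigenvector (eigenvalue 1) of
the two-scale transition operator, refined to a dyadic table of spacing
$2^{-12}$ through the exact two-scale relation. Evaluation interpolates
the table linearly. Derivative tables use central differences with *zero
extension* beyond the support; the uniform stencil preserves telescoping
identities (e.g. $\sum_k \varphi'(x-k)=0$) exactly at table points, which
in turn makes the differentiation matrix exact on polynomial
reconstructions. The refinement level 12 keeps the evaluation error far
below the collocation error for db$\ge$3; db2's limited Hölder
regularity makes its derivative tables unreliable, which is why db4 is
the default (small support, enough smoothness for Caputo orders
$\le 1$).

**Interval handling.** The basis on $[0,T]$ consists of periodized
scaling functions at level $J$ ($2^J$ functions, rescaled from $[0,1]$),
which keeps exact orthonormality and exact reproduction of constants. A
`full_mra` mode (coarse scaling functions plus wavelets up to level
$J-1$) spans the same space and is provided for completeness.
Periodization has a real cost: a non-periodic function acquires an $O(1)$
wrap-around jump, so its best approximation carries an
$O(2^{-J/2})$ seam error localized at the interval ends. The tests
measure this rather than wish it away: projecting $f(t)=t$ at $J=6$
reproduces $f$ to $10^{-10}$ in the interior while the global error is
$\sim 10^{-1}$ at the seam.

**Trend augmentation.** The solver expands the *Caputo derivative* of
each compartment (see below), which is generally non-periodic on
$[0,T]$. To keep the seam out of the solution, the solver's basis is
augmented by default with one shifted-Legendre linear column
(`augment = 1`; a quadratic column is available). The column's
fractional integral has a closed form, so it costs nothing in assembly
accuracy. On the Mittag-Leffler benchmark at $J=6$ this single column
improves the sup-norm error from $2.9\cdot10^{-3}$ to $6\cdot10^{-5}$
(at $\alpha=0.7$). The pure periodized basis remains the default of
`wavelet_basis()` itself.

One consequence worth knowing: appended trend columns make the *square*
interpolation matrix at the nodes increasingly ill-conditioned as $J$
grows (the wavelet block can almost interpolate the trend samples). The
solver is insensitive to this — its convergence check is the residual,
and the near-null direction has a vanishing effect on reconstructed
trajectories — but coefficient vectors themselves should not be
over-interpreted, and `augment = 2` at high $J$ is best avoided.

## Fractional operators

The Riemann–Liouville integral $I^\alpha$ is discretized by
product-trapezoidal quadrature: the integrand is piecewise linear on a
uniform fine grid and the weakly singular kernel
$(t-s)^{\alpha-1}$ is integrated against it exactly on every (possibly
clipped) panel. This is exact for piecewise-linear functions — hence
exact for constants and linear trend columns at any $\alpha$ — and
second-order for smooth ones. The Caputo derivative is implemented as
$I^{1-\alpha}\circ d/dt$, the $m=1$ case of its definition; the popular
operational-matrix shorthand "fractional integration composed with
differentiation" is read the same way, since applying $I^{\alpha}$ (order
$\alpha$) to a first derivative is dimensionally inconsistent with the
definition.

The collocation operator stores $D_\alpha[\ell,j] = ({}^CD^\alpha
\psi_j)(t_\ell)$ and $P_\alpha[\ell,j] = (I^\alpha\psi_j)(t_\ell)$,
assembled on a fine grid of $32\,n_b$ panels (minimum 1024). The
Galerkin matrix $\langle D^\alpha\psi_j,\psi_i\rangle$ is also available
and cross-checked against the physical-space matrix in the tests; the
residual is enforced pointwise at nodes, so the physical-space form is
what the solver uses.

**Mittag-Leffler function.** $E_{\alpha,\beta}(z)$ for real $z$,
$|z|\le 50$, uses the power series where its dominant term
($\sim e^{|z|^{1/\alpha}}$) keeps cancellation below $\sim10^{-10}$
(i.e. $|z| \le \min(5, 13.8^\alpha)$ for $\alpha<1$), and otherwise the
Hankel contour collapsed onto the negative real axis, plus the
exponential residue for $z>0$ and a $\beta$-reduction recursion for
$\beta>1$. Branches are validated against each other on their overlap
and against $e^z$, $\cos$, and $e^{z^2}\mathrm{erfc}(-z)$ closed forms.
For orders above 1 only the series branch exists; it is accurate on the
supported range for $\alpha\ge1.5$ but degrades for orders just above 1
at large negative arguments — outside this package's model range
($\alpha\le1$), where the only $\alpha>1$ use is the two-parameter
function $E_{\alpha,\alpha+1}$ with small arguments.

## Delay handling

Delayed values are produced by a sparse shift matrix whose row $\ell$
holds Lagrange weights at $s_\ell=t_\ell-\tau$. Default interpolation
order is 3 with the 4-point stencil shifted one-sided at the grid edges —
a deliberate departure from falling back to linear there, so that cubic
exactness (and with it the manufactured-solution residual checks) holds
on the whole grid. Rows with $s_\ell$ before the grid are left zero and
served by the history function; the solver augments the node grid with
$t=0$ so that shifted abscissae in $(0, t_1)$ are interpolated, never
extrapolated. A `cyclic` policy reproduces the textbook illustration in
which an integer delay-to-spacing ratio gives a permutation matrix that
cyclically shifts entries; wrapping pre-history onto future times has no
epidemiological meaning, so `history` is the solver's convention and
`cyclic` exists purely as a reproduction mode.

## The collocation solve

Unknowns are the coefficients of ${}^CD^\alpha X$ for each compartment
$X$; compartments are reconstructed as $X(t_\ell)=X(0)+[P_\alpha
a^{(X)}]_\ell$ with $X(0)$ taken pointwise from the history. Expanding
the derivative instead of the compartment enforces initial conditions
exactly and keeps the $t^{-\alpha}$-type singular behaviour of
$D^\alpha$ at the left endpoint out of the residual; on the span the two
formulations are algebraically equivalent. Collocation nodes are
midpoints $t_\ell=(\ell-\tfrac12)T/n_c$ with $n_c=n_b$ (square system;
the Caputo kernel is singular at $t=0$, so $t=0$ is never a node).

The nonlinear system is solved by damped Newton iteration from the zero
coefficient vector (constant compartments at their initial values). The
Jacobian is analytic: the Hadamard product $S\circ I_{\tau}$
differentiates into diagonal-times-matrix blocks. The line search halves
the step down to $1/64$ and the method falls back to relaxed fixed-point
iteration if the Jacobian ever becomes singular; an explicit error with
the residual history is raised on non-convergence. Defaults
(residual tolerance $10^{-10}$ in the infinity norm, 50 iterations) are
this package's choices; the scenario solves converge in about 3 Newton
steps to residuals near $10^{-14}$. The solver contains no randomness:
identical configurations give bit-identical output.

A finite-difference Jacobian is kept behind an internal debug entry
point and compared entrywise ($\le10^{-6}$) with the analytic one in the
tests.

## Verification design

Three independent baselines triangulate the solver:

* **Mittag-Leffler fixtures** (`ml_decay_problem`): with $\beta=\delta=0$
  the infected compartment relaxes as $I_0E_\alpha(-\gamma t^\alpha)$ and
  $R$ follows the fractional-integral identity through
  $E_{\alpha,\alpha+1}$. Closed form, genuinely fractional.
* **Fractional Adams–Bashforth–Moulton** (`abm_fdde`): the
  predictor–corrector with convolution weights, one corrector sweep
  (PECE), extended with delayed lookups (linear or Catmull–Rom) into the
  computed past. At $h=10^{-3}$ it reproduces the relaxation closed form
  to $\sim10^{-8}$, far below the comparison tolerances, so it serves as
  the oracle at fractional orders. Its delayed lookups use the same
  interpolation family as the shift matrix, so comparisons do not mix
  interpolation models.
* **RK4 by the method of steps** (`rk4_dde`): the classical fourth-order
  scheme at $\alpha=1$ with cubic-Hermite delayed lookups (slopes are the
  stored derivatives, valid at integer order only). Cross-checked in the
  tests against a general-purpose DDE integrator.

**Manufactured problems** (`manufactured_problem`) pick polynomial
triples of degree $\le3$ — capped there so every Caputo derivative has an
exact $\Gamma$-ratio closed form — and construct the forcing that makes
the triple exact. Substituting the triple into the assembled residual
(delays through the shift machinery, derivatives in closed form) yields
$\sim10^{-15}$, an end-to-end consistency check of the fractional, delay
and assembly chain. Recovery by the solver is a sharper statement and
depends on the span: a degree-1 triple at $\alpha=1$ lies exactly in the
reconstruction space (its derivative is constant) and is recovered to
$10^{-12}$; at $\alpha<1$ the derivative of a polynomial is a
$t^{p-\alpha}$ power function outside every finite wavelet span, so
recovery is then limited by the kink-at-zero interpolation error
(relative $\sim10^{-4}$ at $J=6$), and the exactness assertion is made
at integer order only.

**Refinement behaviour.** On the relaxation fixture at $\alpha=0.7$ the
$L^2$ error decreases strictly through $J=4\ldots7$ with an empirical
order of about $1.7$ in $n_b$. The limiting regularity is the
solution's own $t^\alpha$ term at the origin, not the basis: smooth
periodic targets converge much faster. Expectations of order $\ge1$ are
therefore conservative and honest for this problem class.

## What the fixtures do and do not show

All validation inputs are synthetic and deterministic: linear histories,
constant rates, closed-form or manufactured references. Passing them
shows the *scheme* converges and agrees with independent discretizations
of the same equations. It says nothing about real influenza data —
no observation noise, no parameter estimation, no behavioural change or
heterogeneity in transmission, no multi-strain structure. The delay is a
single shared constant; distributed or state-dependent delays are out of
scope, as are Atangana–Baleanu-type operators (the package implements
the Caputo calculus the scheme actually uses, and the Mittag-Leffler
function appears only in validation closed forms).

## Problem sizes

Defaults were chosen so a full validation pass stays lightweight: level
$J=6$ (195 unknowns) for scenario solves, oracle step $h=10^{-3}$
($10^4$ steps), refinement studies over $J=4\ldots7$, cascade tables at
refinement 12. A scenario solve takes well under a second; the complete
test battery, including all oracle comparisons, runs in well under a
minute on one core.
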