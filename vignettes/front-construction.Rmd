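---
title: "Constructing and validating exact traveling fronts of the three-component language-competition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating exact traveling fronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langfronts)
```

## The model and its assumptions

The package studies the interaction of two monolingual speaker
communities `u` and `w` with a bilingual community `v` on a
one-dimensional territory:

$$
\begin{aligned}
u_t &= d_1 u_{xx} + \beta_1 u(1-u) - \alpha_1 u w + \alpha_2 u v,\\
v_t &= v_{xx} + v(1-v) + (\kappa_1\alpha_3 + \kappa_2\alpha_1)\,u w
       - (\kappa_2\alpha_2 u + \kappa_1\alpha_4 w)\,v,\\
w_t &= d_3 w_{xx} + \beta_3 w(1-w) - \alpha_3 u w + \alpha_4 v w.
\end{aligned}
$$

Each component diffuses, grows logistically towards its **own** carrying
capacity, and exchanges speakers through bilinear conversion terms: the
$uw$ products feed the bilingual pool (two monolingual communities in
contact produce bilinguals), while $\alpha_2 uv$ and $\alpha_4 vw$
describe bilinguals reverting to a monolingual community, for instance
under a language policy favouring one side. The dimensionless form arises
from the dimensional model by scaling each component with its carrying
capacity $K_i$, time with $1/a_2$ (the bilingual growth rate) and space
with $\sqrt{\lambda_2/a_2}$; `nondimensionalize()` performs this map and
exposes both scales for converting solver output back.

Two structural assumptions matter throughout:

* $\alpha_1^2 + \alpha_3^2 \neq 0$. With both conversion channels to the
  bilingual pool switched off, the system is a diffusive Lotka–Volterra
  model — a different model class with different symmetry structure. The
  constructors reject such inputs with a diagnostic naming the DLVS
  degeneracy (a relaxation flag exists purely for regression tests).
* Frequencies are **not** clamped to $[0,1]$. The components are measured
  against *different* carrying capacities, so a perfectly valid front can
  have $u$ plateaux well above 1 (the worked example in the README has
  $u \to 1.107$). Only nonnegativity is demanded of admissible fronts.

The model has six spatially homogeneous equilibria with
$u_0 v_0 w_0 = 0$: extinction, the three one-community corner states, and
two mixed states pairing the bilingual community with one monolingual
community. Because the first and third equations have identical
structure, the relabelling $u \leftrightarrow w$ (with
$d_1 \leftrightarrow d_3$, $\beta_1 \leftrightarrow \beta_3$,
$\alpha_1 \leftrightarrow \alpha_3$, $\alpha_2 \leftrightarrow \alpha_4$,
$\kappa_1 \leftrightarrow \kappa_2$) maps the model family onto itself;
under it the six states fall into four essentially different classes.
`equivalence_classes()` implements the grouping through a swap-invariant
support signature — for generic parameters this reproduces the four
classes, and when a degenerate parameter choice collapses the mixed state
onto a corner the coincidence is reported as a duplicate rather than
silently merged or preserved. Interior equilibria (all three components
positive) are deliberately out of scope, as is any stability
classification.

## The traveling-wave reduction and the tanh method

Since the system admits only time and space translations as continuous
symmetries, the one genuinely spatial symmetry reduction is the plane
wave $u = U(\omega)$, $\omega = x - \mu t$, giving a second-order ODE
system in $\omega$ (`reduce_to_wave_ode()`). The package constructs exact
solutions with the tanh expansion: each profile is a polynomial in
$Y = \tanh\omega$, so that $Y' = 1 - Y^2$ keeps derivatives polynomial.
Balancing the second derivative of a degree-$N$ profile (degree $N+2$)
against the quadratic kinetics (degree $2N$) forces $N = 2$
(`balance_exponents()`); no search beyond $N \le 2$ is attempted.

Internally everything is written in $z = 1 - Y \in (0, 2)$, with
$\mathrm{d}/\mathrm{d}\omega = -z(2-z)\,\mathrm{d}/\mathrm{d}z$, because
the front shapes are simplest there: a "square front" is
$\sigma z^2$, the rising component is $1 - z/2$, and a pulse
($1 - Y^2$) is $z(2-z)$. Substituting an ansatz turns each equation
residual into a polynomial in $z$ whose coefficients are polynomials in
the model parameters and amplitudes; a front family exists exactly where
**every** coefficient vanishes.

### Exact arithmetic and the elimination solver

These coefficient systems are solved, not approximated. The package
carries its own exact sparse multivariate polynomial arithmetic over the
rationals (numerator/denominator pairs held in doubles, always
gcd-reduced, with a hard error far below the $2^{53}$ exact-integer
limit) together with rational-function arithmetic, exact multivariate
division, and serialization that round-trips losslessly.

`solve_constraints()` eliminates the unknown symbols sequentially: at
each step it picks an equation linear in the next unknown, solves it as a
rational function, and substitutes throughout. Three details make this
robust rather than fragile:

* **Degenerate-branch filtering.** Monomial factors in symbols assumed
  nonzero (amplitudes, diffusivities, …) are divided out; each such
  division is recorded as an excluded branch ("$\sigma_2 = 0$ excluded").
  A branch whose final solution forces a nonzero-assumed symbol to vanish
  identically (e.g. $\kappa_2 \equiv 0$) is likewise rejected — these are
  flat or collapsed profiles, not fronts.
* **Safe divisions.** Candidate picks are ranked by how provably nonzero
  the unknown's leading coefficient is: free of unsolved unknowns, or
  built from nonzero-assumed symbols, or — the interesting case —
  certified by showing that "coefficient $= 0$" has no common solution
  with the equation itself (a univariate Euclidean-remainder test). Only
  when nothing better exists does the solver divide by an uncertain
  coefficient, recording the assumption.
* **Backtracking.** The elimination is a depth-first search: a branch
  that stalls, turns inconsistent, or blows up in expression size is
  abandoned and the next-ranked candidate is tried. Spurious polynomial
  factors introduced by cleared denominators (and by numerators of
  nonzero solved symbols) are divided back out by exact division, which
  keeps expressions small and keeps late equations linear.

Every returned branch is re-verified numerically: at random
instantiations of its free symbols, all original coefficients drop to
relative $10^{-15}$ or so, and the branch is refused if they do not reach
$10^{-10}$.

### The four front families

`derive_case_constraints()` wraps the engine for the documented families
(the results are cached per session):

| family | shapes (in $z$) | free | notable forced relations |
|---|---|---|---|
| `1-general` | $u=\sigma_1 z^2$, $v=\sigma_2 z$, $w=1-z/2$ | $\mu, d_1, d_3, \alpha_2, \alpha_4$ | $\alpha_1 = 16d_1 - 4\mu + \beta_1$, $\alpha_3 = d_3\beta_1/(3d_1)$, $\kappa_1=(5-2\mu)/\alpha_4$, $\sigma_1 = 6d_1/\beta_1$, $\sigma_2=(24d_1-\beta_1)/(2\alpha_2)$ |
| `1-fixed` | all three squares | $\beta_1,\alpha_2,\alpha_3,\alpha_4,\kappa_2$ | $\mu=10$, $d_1=d_3=1$, $\alpha_1=\beta_1-24$ |
| `2` | squares for $u,v$; pulse $w$ | $d_1,\alpha_1,\alpha_2,\alpha_3,\kappa_2$ | $\mu=17/4$, $\beta_1=17-16d_1$, $2\beta_3+8d_3=17$, $\sigma_3=(17-40d_1)/(4\alpha_1)$ |
| `3` | $u=z^2/4$; pulses on $v$ (around 1) and $w$ | $d_1,\alpha_1,\alpha_3,\alpha_4$ | $\alpha_2=0$, $\mu=\alpha_3/4$, $\beta_1=\alpha_3-16d_1$, $\sigma_2=(24-\alpha_3)/(2(\alpha_3-8))$ |

Amplitudes that the connected steady states prescribe are built into the
ansatz ($w$'s amplitude $1/2$ in `1-general`, $u$'s $1/4$ in `3`, and the
mixed-state amplitudes of family `2`); the remaining amplitudes are
solved for independently and then *reconciled* against the steady-state
amplitude formulas
$\sigma_1 = (\beta_1+\alpha_2)/(2^{n_1}(\beta_1+\kappa_2\alpha_2^2))$
etc. For both Case-1 families the reconciliation is an exact
rational-function identity, which the test suite asserts; a mismatch
would be reported, not silently resolved. The engine reports the
degenerate branches it excluded; whether further *non*-degenerate
branches exist for the pulse families is not asserted — the search stops
at the first fully determined nondegenerate branch.

A note on provenance of the algebra: typeset restriction lists for these
families are notoriously easy to mis-transcribe (stacked fractions
flatten into ambiguous strings). The package therefore treats its own
symbolically derived branch as the authoritative form and uses the
unambiguous classical relations (the table above) as cross-checks in the
tests; all of them hold exactly.

## Admissibility and parameter selection

A derived branch is only a front if every coefficient and every profile
component is admissible. `validate_positivity()` collects the conditions:
positivity of $d_i, \beta_i, \kappa_i$ and amplitudes, nonnegativity of
the $\alpha_i$, the DLVS check, and per-family component conditions —
$\beta_1 < 24 d_1$ (nonnegative $v$) and $\kappa_2\alpha_2 \le 1$
(nonnegative mixed-state $v_0$) for the variable-speed family,
$1 + \sigma_2 \ge 0$ for the corner-connecting family (whose $v$ dips
below 1 when $\alpha_3 > 24$), and so on. `build_front()` refuses
inadmissible inputs, naming the violated condition.

For the variable-speed family the package implements the two selection
algorithms that *guarantee* admissibility, based on
$F = 10d_1 - \mu + 2\alpha$ and $G = 2\mu d_3 - 5d_3 + \alpha$ when
$\alpha_2=\alpha_4\equiv\alpha$:

* **Forward fronts** (`select_case_i()`, simplified in
  `select_remark4()`): $\mu \in (1/2, 5/2)$, slack $\varepsilon > 0$,
  $d_3 \ge (2\mu+\varepsilon)/(2\mu-1)$,
  $\alpha = (5-2\mu)d_3 + \varepsilon$ (so $G = \varepsilon$ exactly),
  then $d_1$ large enough that $40 d_1 > 4\mu + \alpha$ and
  $24 d_1 > \alpha$. The default slack $\varepsilon = 1$ matches the
  package's forward illustration ($\mu = 3/2$, $d = 2$,
  $\alpha = 5$); values above 1 emit a warning since the construction is
  motivated for small slack.
* **Backward fronts** (`select_case_ii()`): $\alpha_2 = 24 d_1$,
  $d_1, d_3 \in (0,1)$, $\mu < d_3/(2(d_3-1))$. The admissible
  $\alpha_4$ then forms an interval: $\beta_1 > 0$ gives exactly
  $\alpha_4 > (5-2\mu)d_3$, and $\beta_3 = 2(2d_3-\mu) - 2\alpha_4\sigma_2$
  eventually turns negative, closing the interval from above. Because the
  closed form of the upper end is unwieldy, the interval is determined
  numerically by root-finding on the minimum positivity margin
  (`admissible_alpha4_interval()`); the default
  $\alpha_4 = 1.6\times$ the lower threshold sits comfortably inside and
  reproduces the backward illustration ($d_1=d_3=1/2$, $\mu=-5$,
  $\alpha_2=\alpha_4=12$). Not every $(d_1, d_3, \mu)$ in the stated box
  is feasible — when no $\alpha_4$ works, the selector raises a named
  `alpha4-infeasible` diagnostic instead of returning a broken set.

Every selector returns the fully instantiated ten-coefficient parameter
set plus its positivity report; all preconditions fail with named
diagnostics (`mu-range`, `epsilon-range`, `d3-bound`, `d1-bound`,
`mu-bound`, `alpha4-bound`).

## Certification and numerical cross-validation

`certify_residual()` checks a front against the PDE itself:
$u_t - d_1 u_{xx} - f_1$ and its two analogues are evaluated with exact
closed-form derivatives (polynomial calculus in $z$, no finite
differences) at 400 collocation points on $\omega \in [-15, 15]$ — the
window is chosen because $\tanh$ saturates to machine precision beyond
$|\omega| \approx 19$, so all nontrivial variation is covered. Valid
fronts certify at $10^{-13}$; perturbing one coefficient by 1% raises the
residual above $10^{-4}$, so the certificate has teeth. The test suite
additionally cross-checks the closed-form-derivative route against
brute-force fourth-order finite differencing of the profiles (agreement
to $10^{-8}$ over random $\omega$), keeping the two derivative routes
independent.

The method-of-lines solver provides the dynamical cross-validation:
second-order central differences, no-flux boundaries via mirror ghost
nodes (second-order accurate, matching the natural boundary behaviour of
the fronts, whose spatial derivatives vanish as $x \to \pm\infty$), and a
stiff-capable sparse adaptive integrator at `rtol = 1e-8`,
`atol = 1e-10`. Conversion coefficients like $\alpha = 12$ make the
kinetics moderately stiff, hence the integrator choice. Validation runs
use domains wide enough ($[-20, 20]$ and $[-15, 25]$) to keep the front
away from the boundaries over the simulated horizon; the narrower
$[-4, 8]$ window of the illustrative figures is used only for plotting.
On 801 nodes the simulated backward front stays within $10^{-3}$ of the
translated closed form over a unit time horizon, grid refinement across
201/401/801 nodes shows the expected second-order convergence (observed
orders $\approx 2.0$), and level-crossing regression recovers both
illustration speeds ($3/2$ and $-5$) to a few parts in $10^4$.
`measure_front_speed()` fits the crossing position over the final half of
the record, by default tracking $w$ at level $1/2$ (it spans 0 to 1 in
the Case-1 families); for the pulse families, half the $u$ plateau is the
natural level.

## What the random draws do and do not show

The verification suite samples each family's admissible region
(`sample_front_params()`): box draws for parameters whose bounds are
explicit, rejection sampling against the positivity report where the
region is curved (families `2` and `3`, and the backward regime). Fixed
seeds make every randomized check reproducible, and the same seed always
yields the same verification report. These draws establish that the
algebra and the certification hold across the admissible regions — they
say nothing about real sociolinguistic data: the model here is
uncalibrated, the parameter regions are mathematical, and connecting the
fronts to census records would require estimating the dimensional
coefficients, which is outside this package's scope.

## Numerical choices, edge cases, limitations

* Steady states are verified at $10^{-12}$ (pure arithmetic, no
  discretization error); symbolic branch re-verification at $10^{-10}$;
  PDE certification threshold $10^{-10}$; solver tolerances as above.
  Nonnegativity of simulated fronts is asserted up to $-10^{-6}$,
  allowing discretization undershoot.
* Front evaluation is overflow-safe for $|\omega|$ up to and beyond 700
  because profiles are polynomials in $z = 1-\tanh\omega \in [0, 2]$.
* $\alpha_3 = 24$ in the corner-connecting family sends its $v$
  correction to zero ($v \equiv 1$) but also $\kappa_1 \to 0$, so it is
  the boundary of admissibility, approachable but excluded.
* The trajectory CSV writer prints doubles with `%.17g`, so written and
  re-read trajectories compare bit-for-bit.
* Limitations: no fronts connecting interior steady states, no stability
  analysis of fronts or equilibria, no exponent tuples beyond the
  balanced $N \le 2$, a single documented numerical scheme (with
  refinement tests) rather than a scheme zoo, and no 2D extension.
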