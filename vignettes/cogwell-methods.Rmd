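---
title: "Methods: the information-image potential-well model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the information-image potential-well model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogwell)
```

## The model and its assumptions

`cogwell` treats a unit of cognitive content — an *information image* — as
a particle-like oscillator in a one-dimensional finite potential well. The
analogy is deliberately phenomenological: none of the quantities carry
physical units, and the "quantum" apparatus is borrowed for its ability to
produce discrete activity levels, oscillatory state functions and barrier
threshold effects, not as a claim that cognition is quantum. Everything is
dimensionless with `h = m = 1` defaults, and all parameters are overridable
through the configuration layer.

The well of width `a` with barrier `U0` partitions space into Zone 1
(inside, the open interval `(-a/2, a/2)`) and Zone 2 (outside). An image
with energy `E` has kinetic speed `v1 = sqrt(2E/m)` inside and an
evanescent speed `|v2| = sqrt(2(U0 - E)/m)` outside, defined only for bound
images (`E < U0`); its activity frequency is `omega_q = 4*pi*E/h`. The
bound state inside is `A f(k x) cos(omega_q t + beta)` with wavenumber
`k = 2*pi*sqrt(2 m E)/h`, where the spatial form `f` is exposed as an
explicit *dialect*: `sine` is the classical standing-wave solution, while
`cosine` is the form used by every simulation and is therefore the default.
Some source material switches between the two without comment; making the
choice explicit keeps both reproducible.

Several of the printed equations this model descends from lose their
radical signs and fraction bars in typesetting; the package uses the
unique dimensionally consistent reconstructions implied by the derivation:
`v1` and `|v2|` as above, and the Zone-2 spatial equation
`phi'' - kappa^2 phi = 0` with `kappa = 2*pi*sqrt(2 m (U0 - E))/h`, the
direct analogue of the inside wavenumber with `E -> U0 - E`. The composite
piecewise state (`phi_piecewise`) is a distinct historical form whose
outside tail decays at `omega_q |v2|`; both decay rates are implemented
where they appear, and they intentionally differ.

The state function is never normalized as a probability amplitude; the
model uses it as a response amplitude, so only its shape matters and the
amplitude `A` is a free parameter. Whether activity should feed back into
`A` is left open upstream; here `A` is simply fittable.

## The influence pulse and the perturbed state

A second information flow acting on the base image is the Gaussian-windowed
cosine

`D(t) = H exp(-4 (t - t0)^2 / T^2) cos(omega_d (t - t0))`

with amplitude `H`, characteristic half-life `T > 0` and exposure frequency
`omega_d`. The pulse centre `t0` (default 0) is an addition of this
package: simulations need to align exposure onset with their time window.
`D` is even about `t0` and bounded by `|H|`; both identities are tested.

The perturbed state shifts the energy *inside the spatial wavenumber only*:

`phi_out(x, t) = A cos(2 pi x sqrt(2 m (E + D(t))) / h) cos(4 pi E t / h)`.

The temporal factor keeps the unperturbed `E` — that is how the final
formula is printed, and we follow it literally rather than also shifting
the temporal frequency, which would be a different model. With `H = 0` the
expression reduces exactly to the cosine-dialect bound state.

When `E + D(t) < 0` the wavenumber would turn imaginary and the spatial
cosine would continue analytically into unbounded `cosh` growth. That
branch is deliberately not implemented: a bounded rating response cannot
follow an unbounded state, and the source simulations never evaluate it.
The default `clamp_zero` policy clamps the effective energy to zero (the
spatial factor becomes 1) and warns; an `error` policy is available for
callers who prefer to treat the configuration as invalid. During fitting,
where the search deliberately explores such corners thousands of times,
the warning is suppressed.

## Dynamics: integration, the regularized barrier, exits

The equations of motion force the image with
`A omega0 sin(omega0 x) cos(omega_q t + beta)` inside the well plus an
impulsive barrier term `(2 U0 / a) * delta(2x/a - 1)` at the right wall,
and with the evanescent-tail forcing
`coef * omega_q |v2| exp(-omega_q |v2| x) cos(omega_q t + beta)` outside.
Design choices:

* **Dirac regularization.** The delta is replaced by a unit-integral
  Gaussian bump in the delta's argument `u = 2x/a - 1`, with width
  `delta_width` given in position units (default `a/100`). Integrating the
  resulting force across the wall yields exactly `U0` (the `a/2` Jacobian
  of the argument), which is verified by quadrature in the tests. A smooth
  bump, rather than an event-based impulse, keeps the ODE integrable by a
  standard fixed-step scheme and makes the regularization limit testable.
* **The bump is a wall term, not a zone term.** The delta sits exactly at
  the wall, so its regularization straddles both zones. The smooth zone
  forcings are dispatched exclusively by the current position, but the
  bump is added on both sides: truncating it at the wall would reintroduce
  the very force discontinuity the regularization exists to remove, and
  empirically destroys the convergence of the post-crossing velocity as
  `delta_width` shrinks.
* **Left wall.** The printed equation places an impulse only at the right
  wall; a mirrored term at `2x/a + 1 = 0` is available behind the
  `mirror_delta` flag (default off, following the equation literally).
  Similarly, the left-side Zone-2 forcing is implemented with the decaying
  orientation `exp(+kappa x)` for `x < -a/2`; the printed right-side form
  would diverge there.
* **Integration.** Classical fixed-step RK4 on `(x, v)`, force selected by
  zone at every stage evaluation, every step recorded, bit-identical given
  the configuration. A hot inner closure with hoisted constants is used by
  the integrator; a test asserts it equals the public force functions
  pointwise. If a wall crossing spans fewer than 10 steps of the bump
  width the simulation warns that the impulse is under-resolved.
* **Exits.** The threshold velocity is concretized as
  `v_p = sqrt(2 U0 / m)` (kinetic energy equal to the barrier).
  `detect_exit` scans recorded samples for `m v^2 / 2 >= U0` within
  `delta_width` of a wall; the "small increment" epsilon of the verbal exit
  condition has no quantitative role, so the comparison is `>=` exactly.
  The Zone-2 coefficients `B`, `C` are independent configuration values
  (default 0, the internal regime); whether they coincide with the
  bound-state tail coefficients is unstated upstream, so they are not
  tied.

## Response surfaces and slices

`sweep_surface` evaluates the perturbed state at a fixed position `x_eval`
over a time grid for each value of one swept pulse parameter (`omega_d` or
`H`), reproducing the structure of exposure-frequency and
exposure-amplitude simulations. Two conventions are fixed here because the
source leaves them open: the evaluation point defaults to `0.25 * a` (a
point strictly inside the well where the spatial factor is nontrivial —
at `x = 0` every sweep row collapses to `A cos(4 pi E t / h)`), and the
reference frequency "0.8" is read as the *base image's* temporal frequency
(`4 pi E / h = 0.8`, the `default_config()` energy) with `omega_d` swept.
Slicing is nearest-grid-point, never interpolated, so a slice is exactly a
row or column of computed values and refining a grid leaves shared samples
bit-identical.

## Fitting

The objective is plain unweighted least squares,
`sum((scale * model(s_i; theta) - y_i)^2)`, with `scale` fixed to 1 unless
it is listed as a parameter. Two procedures are provided:

* `fit_local`: derivative-free Nelder-Mead descent (golden-section in one
  dimension) with box constraints enforced by clamping proposals, a
  relative tolerance of `1e-8` and an evaluation budget (default 2000,
  exhaustion flags the result not-converged). The returned point is the
  best point ever evaluated, so the descent contract — never worse than
  the start — holds unconditionally.
* `fit_grid_adaptive`: the discrete grid search with dynamically shrinking
  steps. Each start evaluates a full Cartesian grid
  (`n_points_per_axis = 7` per axis by default) over its box, re-centres a
  box shrunk by `shrink_factor = 0.5` per axis on the best point (clipped
  into bounds, preserving width), and repeats `n_refinements = 6` times.
  Ties break to the lowest lexicographic grid index, for determinism. The
  multi-start design reconciles two requirements — random restarts and an
  exact degenerate case: start 1 always covers the full bounds (so with
  `n_starts = 1, n_refinements = 0` the procedure is *exactly* the
  coarse-grid argmin, verified against brute-force enumeration), and
  starts 2..n use seeded uniform centres with boxes of half the bounds
  span.

Documented identifiability symmetries: `A` and `scale` enter the objective
multiplicatively (fix one when both are present), and the response is even
in `omega_d`, so recovery is asserted modulo sign. With 7 points per axis
the centre of every symmetric box is itself a grid point; a true parameter
vector lying on the initial grid is therefore preserved through all
refinements, which is how the recovery tests pin exact recovery without
moving thresholds.

## The synthetic rating experiment

The generator emulates the *structure* of a multimodal affective-rating
study: 227 subjects, eight stimulus-pair sessions (the fixed design
table), each of the two blocks per session rated on a bounded valence
scale. Emulation choices, none of which are published quantities:

* **Scale.** The standard 9-point SAM valence convention, `[1, 9]`,
  configurable.
* **Nominal block valences.** Extreme positive 8 and negative 2,
  symmetric about the midpoint 5.
* **Bivalent integration.** Components are centred on the midpoint,
  negative centred components amplified by `lambda_neg = 1.5`, combined as
  a weighted mean (`w_p = w_s = 0.5`) re-anchored at the midpoint, and
  clipped to the scale. This reproduces the two reported phenomena — a
  pronounced nonlinearity and dominance of the negative component — with
  the simplest rule that has both; the upstream work reports the
  phenomena but no generative equation.
* **Noise.** Additive Gaussian per rating (`noise_sd`, default 1 scale
  unit), then clipping. With `noise_sd = 0` the pipeline closes exactly:
  the per-group summary equals the integration rule's values, which is the
  fixed-point test.

What the generator does *not* emulate: item-level stimulus content,
subject covariates, arousal/dominance scales, inter-stimulus pauses and
session scheduling, or any drift/order effects. Passing tests therefore
show that the *pipeline* (generate, summarize, sweep, slice, fit) is
correct and reproducible, not that the model fits human data.

The summary groups by combination and presentation slot (16 groups,
ordered by combination then slot) with a sequential index 1..16; the fit
treats that index directly as the slice coordinate, since no mapping from
session index to model coordinate is defined upstream.

For end-to-end evaluation the pipeline has a `model` target mode: the true
group means are taken from the model curve at a known parameter vector
(offset to the scale midpoint and clipped) and pushed through the same
rating machinery, so the fitted objective can be compared against the
objective of the generating parameters on the same noisy summary — the
closed-loop benchmark used in the acceptance checks.

## Numerical choices and problem sizes

* ODE-residual checks use second-order central differences on 10^4-point
  grids, giving residuals around `1e-7` relative — comfortably inside the
  `1e-6` assertion without being tuned to it.
* The conservation benchmark (static forcing, `omega_q = 0`) runs 10^4 RK4
  steps at `dt = 1e-3` and cross-checks the end state against a 10x finer
  reference; observed drift is at the `1e-14` level.
* The regularization benchmark quarters `delta_width` twice from `a/100`
  with `dt` scaled proportionally (`sigma/400`), measuring post-crossing
  velocity under a fast-oscillating interior forcing (`omega_q = 6`) so
  the sigma-dependence is well above integration noise.
* The recovery benchmark uses a 40-point time grid on `[0, 20]` and the
  default search (5 starts x 7 grids x 7^5 points ≈ 5.9x10^5 evaluations,
  a few seconds); the pipeline benchmark uses the 16-point summary curve.
* Derived sub-seeds (`seed + 999983 * k mod 2^31 - 1`) give each pipeline
  stage an independent, reproducible stream from one run seed.

## Known limitations

* Single energy level, single image, one well: no multi-level spectra and
  no coupling of two individuals' wells.
* The perturbed state keeps `E` in the temporal factor by construction;
  alternative readings (shifting the temporal frequency too) are not
  implemented.
* `fit_grid_adaptive` is a local-refinement heuristic; with few starts it
  can miss the global optimum of a rugged objective. The evaluation count
  grows as `n_points_per_axis^p`, so fitting many more than five
  parameters requires rethinking the grid.
* The synthetic experiment is an emulation for pipeline testing; none of
  its parameters are empirical estimates.
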