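---
title: "A potential-energy model of gradient-walking energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A potential-energy model of gradient-walking energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradewalk)
```

## The question

Oxygen-uptake experiments have long shown that walking is cheapest not on
level ground but on a mild descent, around −10 %. `gradewalk` implements a
mechanical explanation: every step lifts the body centre of mass, and on a
gentle downhill the potential energy released by the slope can pay for that
lift exactly. The model is deliberately minimal — potential energy only —
and its value is that this minimal model already reproduces the observed
optimum and links it to step length.

## Why potential energy only

At walking speeds the kinetic energy cycled per step is small. At a cruise
speed of 1.25 m/s the body carries ½v² ≈ 0.78 J/kg, but only the per-step
speed fluctuation is actually braked and re-supplied: with speeds swinging
between 1.20 and 1.30 m/s that is (v₊² − v₋²)/2 ≈ 0.125 J/kg per step. The
centre of mass meanwhile rises and falls 8–10 cm per step, a potential
oscillation of 0.78–0.98 J/kg — five to ten times larger under level-walking
conditions. `magnitude_report()` assembles exactly this comparison:

```{r}
magnitude_report(v = 1.25, dv = 0.10, delta_y = 0.10)
```

The fluctuation is centred on the cruise speed (`v ± dv/2`), the convention
consistent with the 1.20–1.30 m/s example; an asymmetric convention would
change the per-step kinetic figure slightly but not the conclusion. Note
that at the steepest-descent fluctuation (`dv = 0.18` m/s) combined with the
smallest oscillation (8 cm) the dominance drops to about 3.5×, so the 5–10×
claim should be read as a level-walking statement; the property tests check
both facts separately.

## The step model

A walker with leg length $l$ takes steps of length $l/k$, where the
dimensionless step parameter $k$ is typically 1.35 ± 0.20 (larger $k$,
shorter step). In single support the stance leg is straight and the centre
of mass is at its highest, $y_{\max} = y_0 + l$ ($y_0$ is the trunk offset
from hip to centre of mass). In double support the hip height is the
Pythagorean leg of a triangle with hypotenuse $l$ and base $l/2k$, so

$$\Delta y \;=\; l\left(1 - \sqrt{1 - \tfrac{1}{4k^2}}\right),$$

independent of $y_0$ and of the gradient. The geometry requires
$k \ge 0.5$; at $k = 0.5$ the step spans the full $2l$ and the hip reaches
the ground — a degenerate but mathematically valid limit that the solvers
treat as a boundary case.

One caveat worth stating: at the comfortable midpoint ($l = 0.9$ m,
$k = 1.35$) the formula gives $\Delta y \approx 6.4$ cm, somewhat below the
8–10 cm oscillation measured in adults. The rigid-leg compass geometry
understates the oscillation; the package follows the geometric formula
everywhere and keeps the 8–10 cm figures only in the order-of-magnitude
module, where they are inputs, not predictions.

Per step, the model charges two potential-energy terms ($g$ = 9.81 m/s²
by default):

* oscillation: $\Delta U_{\mathrm{osc}} = m g \Delta y \ge 0$;
* gradient: $\Delta U_{\mathrm{grad}} = m g\, i\, (l/k) / \sqrt{1 + i^2}$,
  where the gradient $i$ is rise over horizontal run (negative downhill)
  and $(l/k)/\sqrt{1+i^2}$ is the horizontal projection of the step.

Their sum $U_{\mathrm{tot}}$ is converted to a positive muscular cost by
the piecewise braking function

$$\varepsilon = \begin{cases} U_{\mathrm{tot}} & U_{\mathrm{tot}} > 0\\
-\,U_{\mathrm{tot}}/f & U_{\mathrm{tot}} < 0\end{cases}$$

with efficiency factor $f = 5$ by default: negative (eccentric) work is
four to five times cheaper than positive work, so absorbing 100 J of
surplus costs about 20 J. Both branches vanish at $U_{\mathrm{tot}} = 0$,
so $\varepsilon$ is continuous, non-negative and V-shaped in $i$ — the
kink *is* the optimum. The factor is configurable because the physiological
literature brackets it at 4–5; all headline numbers use 5.

## The optimal gradient, three ways

Setting $U_{\mathrm{tot}} = 0$ and dropping the near-unity
$\sqrt{1 + i^2}$ gives the closed form

$$i(k) = k\sqrt{1 - \tfrac{1}{4k^2}} - k = \sqrt{k^2 - \tfrac14} - k,$$

always in $(-0.5, 0]$ and increasing in $k$: long steps (k ≈ 1.10) are
cheapest near −12 %, short steps (k ≈ 1.5) near −8.6 %, and the
comfortable midpoint k = 1.35 lands at −9.6 %, i.e. the classic −10 %.

```{r}
solve_optimal_gradient(1.35)
```

Three solvers are kept deliberately independent:

* `optimal_gradient_closed_form()` — the formula above;
* `optimal_gradient_exact()` — a bracketed root of the *full* balance
  (retaining $\sqrt{1+i^2}$), via `uniroot()` at tolerance 1e−12;
* `optimal_gradient_numeric()` — a grid argmin of the ε curve refined by
  golden-section search, which never looks at the root equations at all.

Their mutual agreement (≤ 0.004 over the comfortable range; closed vs
exact ≤ 0.003, a quantified version of the claim that dropping the root
costs nothing) is asserted in the test suite, and the cost at the exact
root is zero to 1e−9 J/kg — by construction, since the model's minimum is
exactly the break-even point. That zero is the model's idealisation, not a
physiological prediction: real walking at the optimal gradient still costs
metabolic energy; the model only prices the potential-energy budget.

### Numerical choices

The nominal root bracket is $(-0.5+10^{-9}, -10^{-12})$, since $i(k)$ lies
in $(-0.5, 0)$ for every $k > 0.5$ — with one subtlety: for $k$ within
about 0.003 of the 0.5 boundary the *exact* root falls just below −0.5
(the closed form does not), so the bracket is allowed to extend downward
(`extendInt = "upX"`; the balance is strictly increasing in $i$, so the
root stays unique). The numeric argmin requires at least 1000 grid points
and flags boundary hits (`on_boundary`) rather than silently reporting an
edge; because ε scales linearly with mass, its result is mass-invariant.
$U_{\mathrm{tot}}$ exactly 0 maps to ε = 0, which both branches agree on.

## Step-length strategy

Inverting the closed form (square $\sqrt{k^2 - 1/4} = k + i$) gives
$k(i) = -(\tfrac14 + i^2)/(2i)$ — an algebraic derivation made here, not
taken from the source model, and exact: the round trip $k \to i \to k$
holds to 1e−10 across the tested range. `recommend_step_length()` turns a
downhill gradient into the step length that makes it optimal and checks it
against the comfort band:

```{r}
recommend_step_length(-0.10, body_params(leg_length = 0.9))
```

Two published comfort bands are exposed: `k_comfort_default`
([1.15, 1.55], from 1.35 ± 0.20, the default) and `k_comfort_strategy`
([1.10, 1.50], the band quoted when stretching the optimum from −8 % to
−12 %). For a 0.9 m leg the default band corresponds to steps of roughly
0.58–0.78 m; at k = 1.5 exactly 0.60 m. Gradients at or above level return
a structured `"no_optimum"` advice rather than an error, so sweeping a
route profile never throws; descents steeper than about −13 % would demand
k < 1 (steps wider than comfortable), and the advice says so and clamps to
the nearest comfortable k.

## Sweep tables and the synthetic cohort

`sweep_epsilon_vs_gradient()` tabulates the V-shaped cost curves (default
ks 1, 1.25, 1.5 over ±30 %, 601 points) and `sweep_optimum_vs_k()` the
optimum curve. The absolute scale of the cost curves depends on the mass
and leg length used to draw them — values the figure-style defaults leave
open — so sweeps default to m = 1 kg (per-unit-mass energies) and
l = 0.9 m and always embed the full parameter set in their metadata; curve
*shapes* and minima locations are parameter-independent, and only those
are asserted against reference values. Energies are joules per step for
the configured mass. Tables write to CSV (12 significant digits, `#`
metadata header) or JSON (full precision) and round-trip losslessly to
1e−10 via `read_sweep_table()`.

`generate_cohort()` draws uniform leg lengths (0.75–1.00 m, spanning
typical adult anthropometry) and step parameters (the comfort band
1.15–1.55) from a seeded local RNG stream, restoring the caller's random
state. It emulates between-subject variation in the two parameters the
model is sensitive to — nothing else: no speed, age, load or surface
effects, no within-subject step-to-step variability. Passing property
tests on the cohort therefore show that the *model's* invariants hold
across plausible bodies, not that the model fits any real cohort.

The test suite runs the property checks at 10⁴-point gradient grids and
10⁴-point k grids (seconds on one core); the acceptance script evaluates
closed-form scalars only.

## Limitations

* No kinetic-energy term: the model's central simplification, justified
  above for low speeds, not valid for running or fast descents.
* No step-phase timing adaptation on gradients: the lift per step is taken
  as gradient-independent.
* Mechanical potential-energy cost only — no metabolic rate or oxygen
  uptake prediction, and ε = 0 at the optimum is a budget statement, not
  a claim that walking there is free.
* The rigid-leg geometry understates the observed centre-of-mass
  oscillation (6.4 vs 8–10 cm at the comfortable midpoint).
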