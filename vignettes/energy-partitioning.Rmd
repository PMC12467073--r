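---
title: "Rate-dependent work-energy partitioning with ratework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rate-dependent work-energy partitioning with ratework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratework)
```

## The model

Classical mechanics prices a loading event by force times displacement and is
silent about how fast the displacement was imposed. Soft biological matter is
not: muscle force falls with shortening velocity, and tissues, membranes and
hydrogels resist faster deformation harder and convert more of the input work
into heat. `ratework` quantifies that rate dependence for the two simplest
constitutive laws in the field's toolbox.

**Kelvin–Voigt element.** A linear spring (stiffness $k$, N/m) in parallel
with a dashpot (damping coefficient $\eta$, N·s/m):

$$F(t) = k\,x(t) + \eta\,\dot x(t) + F_\mathrm{adh}(x),$$

with an optional adhesion term for membrane-indentation problems. The work
done driving the element from $x = 0$ to $x = D$ splits into a recoverable
and an irreversible part,

$$W_\mathrm{total} = \underbrace{\tfrac12 k D^2}_{W_\mathrm{el}}
  + \underbrace{\eta \int_0^T \dot x^2\,\mathrm dt}_{W_\mathrm{visc}}
  + \int_0^D F_\mathrm{adh}\,\mathrm dx .$$

For the linear ramp $x(t) = D\,t/T$ — the only first-class loading protocol
in the package — the viscous integral collapses to $W_\mathrm{visc} =
\eta D^2 / T$. Elastic storage is rate-invariant; dissipation is inversely
proportional to the loading duration. The two are equal at the crossover
time $T^* = 2\eta/k$ (`crossover_time()`): ramps faster than $T^*$ are
viscous-dominated, slower ramps elastic-dominated.

**Hill muscle.** Concentric shortening obeys the hyperbola
$(F + a)(v + b) = (F_\mathrm{max} + a)\,b$, so the force available at
velocity $v$ is $F(v) = (F_\mathrm{max}+a)b/(v+b) - a$, falling from
$F_\mathrm{max}$ at $v = 0$ to zero at $v_\mathrm{max} = b\,F_\mathrm{max}/a$.
The mechanical work of a contraction shortening a distance $D$ at constant
$v$ is $W(v) = F(v)\,D$ (`hill_work()`): faster contractions do strictly
less mechanical work. The Hill model has no internal elastic/viscous split,
so only $W_\mathrm{total}$ is reported for muscle scenarios.

### Assumptions

* Loading only: displacement is non-decreasing, and unloading/hysteresis
  loops are rejected rather than modelled.
* No inertia: no simulated scenario carries a mass, so kinetic-energy
  bookkeeping is omitted.
* Concentric Hill regime only: eccentric lengthening ($v<0$) and
  super-maximal shortening ($v>v_\mathrm{max}$) raise errors instead of
  extrapolating a law that is only validated for shortening.
* Linear constitutive coefficients: nonlinear $k(x)$ from Hertzian or
  membrane-bending contact is an extension point, not implemented.

## Parameters and their defaults

| Parameter | Units | Meaning | Representative values |
|---|---|---|---|
| `k` | N/m | elastic stiffness | 1000 (tendon-like), 0.010 (cell membrane + cortex) |
| `eta` | N·s/m | viscous damping | 50 (tendon-like), 1e-6 (membrane) |
| `D` | m | total imposed displacement / indentation depth | 0.10 (tissue stretch), 50–200 nm (nanoparticle) |
| `T` | s | loading duration, the central control variable | 1.0 vs 0.01 (tissue), 0.1 vs 1e-4 (nanoparticle) |
| `fmax`, `a`, `b` | N, N, m/s | Hill parameters | 100, 10, 0.5 |
| `n` | – | samples on the time grid | 10001 |

All computation is SI internally; `from_nm()` and `from_ms()` make unit
conversion explicit where scenario tables are quoted in nm or ms.

## Built-in scenarios

The package ships three scenario builders whose defaults *are* the scenario
definitions; they are fixed reference conditions, not tuning knobs.

`reference_rows()` — five tissue/muscle benchmarks: an ideal Hookean spring
(`k = 1000` N/m, `D = 0.10` m; 5 J stored regardless of rate), the same
element with `eta = 50` N·s/m loaded over 1 s (0.5 J dissipated, a 10%
surcharge) and over 0.01 s (50 J dissipated, ten times the stored energy),
and a Hill muscle (`Fmax = 100` N, `a = 10` N, `b = 0.5` m/s) shortening
5 cm at 0.10 m/s (4.0833 J) versus 0.50 m/s (2.25 J).

`np_scenarios()` — the nanoparticle size–speed grid: small (50 nm) and
large (200 nm) particles, each entered slowly (0.1 s, passive uptake) and
fast (1e-4 s, forced delivery). Two conventions deserve emphasis:

* **Indentation depth equals particle diameter.** Full engulfment requires
  a local membrane displacement of about one diameter, so the 50 nm
  scenario indents 50 nm deep. `D` plays the double role of size and depth.
* **Coefficients scale linearly in diameter** from the 50 nm reference
  (`k = 0.01` N/m, `eta = 5e-7` N·s/m). A contact-area argument could
  equally motivate a quadratic rule; the linear rule is the one consistent
  with the reference energy table (a 4-fold size increase multiplies both
  coefficients by 4), so that is what `scale_np_params()` implements, with
  Hertz/JKR contact left as an explicit non-goal.

At the fast duration the grid happens to sit exactly at the crossover:
$2\eta/k = 1\times10^{-4}$ s for both sizes (the ratio $\eta/k$ is
preserved by linear scaling), so the fast cells print
$W_\mathrm{visc} = W_\mathrm{el}$.

`worked_example_np()` — the standalone 100 nm indentation example
(`k = 0.010` N/m, `eta = 1.0e-6` N·s/m). Its stiffness is *not* what the
diameter-scaling rule would give at 100 nm (0.02 N/m); the two parameter
sets are deliberately kept as distinct fixtures rather than reconciled,
because each is quoted independently and both reproduce their own published
energies. Shortening the entry time from 0.1 s to 1e-4 s raises dissipation
by exactly $10^3$ and tips the budget from elastic- to viscous-dominated.

```{r worked-example}
worked_example_np(n = 1001)[, c("label", "T_s", "w_el", "w_visc")]
```

## Numerical choices

* **Uniform grid, trapezoidal quadrature** for every work integral
  ($\int k x\,\mathrm dx$, $\int \eta \dot x^2\,\mathrm dt$,
  $\int F_\mathrm{adh}\,\mathrm dx$, $\int F\,\mathrm dx$). On a linear
  ramp all integrands except the exponential-adhesion one are affine, for
  which the trapezoid rule is exact up to float rounding; in general the
  error decays as $O(n^{-2})$, and the test suite verifies both facts.
* **Default `n = 10001`** keeps numeric-versus-analytic agreement below
  1e-6 relative on every built-in scenario while a full grid evaluation
  still runs in milliseconds.
* **Velocity at `t = 0`** is the right limit `D/T`: the closed forms assume
  constant velocity over the whole ramp, so the force trace starts with the
  finite dashpot jump `eta*D/T`. The jump is a property of the idealized
  protocol and is documented rather than smoothed.
* **Tolerances.** Analytic identities (conservation, crossover balance,
  Hill residual) are asserted at 1e-9 relative or tighter; the numerical
  route against closed forms at 1e-6 on the default grid.
* **Degenerate inputs.** `D = 0` produces a valid all-zero trace and
  budget; `n = 2` is a legal (coarse) grid; `k = 0` makes the crossover
  time undefined and errors; `a = 0` would make $v_\mathrm{max}$ unbounded
  and is rejected at construction.

## Design choices made where the design was open

* **Adhesion forms.** The indentation force law only stipulates an optional
  additive $F_\mathrm{adh}(x)$, "possibly distance-dependent", without a
  functional form. The package defaults to no adhesion and offers two
  plug-ins — constant ($f_0$ for $x>0$) and exponential
  ($f_0 e^{-x/\lambda}$) — as deliberately simple artifact choices. The
  exponential form doubles as the curved integrand that makes quadrature
  convergence testable.
* **Only linear ramps are first-class.** Spikes, oscillations and sustained
  holds are named qualitatively in the surrounding literature but carry no
  quantitative targets here; `sample_trace()` accepts any monotone
  `t, x, v` history, which is the extension interface.
* **Errors over extrapolation** everywhere a law's domain ends (negative
  indentation, eccentric velocities, unloading), on the view that silent
  extrapolation of constitutive laws is the costlier failure in practice.

## What the scenarios do and do not show

The built-in scenarios are closed-form-checkable idealizations: single
loading events, linear coefficients, no inertia, no rupture criterion, no
thermal bookkeeping of where the dissipated energy goes. Agreement of the
numerical partition with the analytic expressions validates the machinery,
not the biology: real membranes are heterogeneous, nonlinear and actively
remodelling, and real tissue dissipation includes poroelastic fluid flow
and frictional pathways that a single dashpot lumps together. The package's
claims are therefore about the *rate scaling* of the energy budget — the
$1/T$ law, the rate-invariance of storage, the crossover at $2\eta/k$, and
the monotone fall of muscle work with velocity — which are exactly the
properties the test suite pins down.

## Known limitations

* Kelvin–Voigt only; the standard-linear-solid generalization (which adds
  stress relaxation) is out of scope.
* No unloading, so hysteresis-loop areas cannot be computed.
* The Hill constants carry no physiological provenance beyond the benchmark
  values; treat muscle results as illustrative of the velocity scaling.
* Dissipated energy is reported as a single viscous term; its downstream
  fate (heat, remodelling, damage) is not modelled.
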