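---
title: "Diffusion-limited growth kinetics of ligament mineral grains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-limited growth kinetics of ligament mineral grains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainclock)
```

## The model

Calcified deposits in the yellow ligaments of the spine — hydroxyapatite-like
mineral (HAP) and, in some patients, calcium pyrophosphate dehydrate (CPPD) —
grow on crystallization centres at sites of collagen micro-damage. The grains
are modelled as spheres whose growth is limited by diffusive transport of
free calcium from the extracellular fluid to the grain surface, with no
chemical reaction resistance: every ion reaching the surface is incorporated.

Under spherical symmetry and the quasi-static approximation, the calcium
concentration field around a grain of radius $a$ is the steady absorbing-sphere
profile

$$c(r) = c_0\left(1 - \frac{a}{r}\right),$$

zero at the surface and approaching the far-field free-calcium concentration
$c_0$. The surface flux density is $J = D c_0 / a$ and the total mass inflow
$I = 4\pi a D c_0$. Equating the inflow to the grain's mass gain
$\tfrac{d}{dt}\left(\tfrac{4}{3}\pi a^3 \rho\right)$ gives the growth law and
its closed-form solution for a point nucleus ($a = 0$ at $t = 0$):

$$\frac{da}{dt} = \frac{D c_0}{a \rho}, \qquad
  t(a) = \frac{a^2 \rho}{2 D c_0}, \qquad
  a(t) = \sqrt{\frac{2 D c_0 t}{\rho}}.$$

Growth time is quadratic in radius and linear in grain density; the rate
falls as $1/(a\rho)$. A useful exact identity couples the two:
$\frac{da}{dt}\cdot t = a/2$.

```{r closed-forms}
seconds_to_years(growth_time(0.1, 2.61))   # 1 mm radius, densest CPPD: ~6 yr
seconds_to_years(growth_time(0.04, 2.61))  # 0.4 mm radius: under a year
2 * 10 * radius_at_time(years_to_seconds(4), 2.61)  # diameter after 4 yr, mm
```

## Parameters and units

All internal computation is in CGS units (cm, g, s); micrometres,
millimetres and calendar units are converted only at input/output
boundaries. The two physical constants live in a `growth_env()`:

* `D = 1.65e-6` cm²/s — the calcium diffusion coefficient in muscle-like
  soft tissue, used as a proxy for ligament;
* `c0 = 4.2e-5` g/cm³ (42 mg/l) — the free (uncomplexed) calcium
  concentration, about half of total extracellular calcium.

Both are overridable programmatically or through a YAML config
(`read_growth_config()`). Times convert with a 365.25-day year and a
month of one-twelfth of a year; the model is calendar-free and this
convention moves multi-year results by under 0.3%, well inside the
2–3 significant figures the inputs carry.

Grain radii in the measured data span 0.02–0.1 cm and densities
1.78–2.61 g/cm³ depending on phase and case. When only a per-case density
*range* is published, a density policy (`midpoint` default, or
`min`/`max`/`explicit`) picks the value used for rate tables; the policy
and the density actually used are recorded in every output row.
`implied_density()` audits published rate cells by inverting the growth
law; cells whose implied density falls outside the published per-case
range are treated as internally inconsistent and excluded from
reproduction rather than matched by guessing an unpublished density.

## Quasi-static validity and the numerical oracles

The closed forms assume the concentration field relaxes instantly around
a slowly growing grain. Two small parameters justify this:
$c_0/\rho \approx 2\times10^{-5}$ (the interface advances five orders of
magnitude slower than ions arrive) and the timescale separation
$t_\mathrm{growth}/(a^2/D) = \rho/(2c_0) \approx 3\times10^{4}$
(`quasistatic_report()`).

Two independent numerical routes verify the implementation:

* `integrate_growth_ode()` integrates $da/dt = Dc_0/(a\rho)$ adaptively
  (lsoda) from a finite nucleus and reports the maximum relative
  deviation from the analytic trajectory (≤ 1e−6 at default tolerance).
  The origin $a_0 = 0$ is singular for the ODE; a 1 µm nucleus is the
  default stand-in when "from zero" behaviour is wanted, and the closed
  form covers the origin exactly.
* `solve_radial_diffusion()` solves the full time-dependent radial
  diffusion problem around a *static* grain (backward Euler on the
  $u = cr$ plane-diffusion transform; explicit stepping available with an
  enforced stability check, refused otherwise). Holding the grain static
  is deliberate: it isolates exactly the quasi-static approximation the
  closed forms make, and interface motion is negligible on diffusion
  relaxation times because $c_0/\rho$ is tiny. A moving-boundary (Stefan)
  solver is out of scope.

One numerical subtlety is worth recording. The exact flux onto an
absorbing sphere in an initially undepleted infinite medium is
$J(t) = Dc_0\left(\frac1a + \frac{1}{\sqrt{\pi D t}}\right)$: the
depletion-layer transient decays only as $1/\sqrt{t}$, so at
$t = 100\,a^2/D$ the flux still exceeds the quasi-static $Dc_0/a$ by
5.6%, and 1% agreement is reached only beyond $t \approx 3\times10^{3}
a^2/D$. Likewise the truncated far field ($c(R) = c_0$ at the default
$R = 20a$) biases the steady flux up by $1/(1-a/R) - 1 \approx 5\%$.
The solver is therefore validated against the exact transient (to <1%
at $t = 100\,a^2/D$) and against the finite-domain steady profile
$c_0(1-a/r)/(1-a/R)$ (to solver precision); agreement with $Dc_0/a$
itself to 1% is demonstrated on growth timescales, where the model
operates. Time nodes are quadratically graded towards $t=0$ to resolve
the $1/\sqrt{t}$ transient; the mass balance (absorbed = far-field
influx + domain depletion) closes to better than 0.5% at default
resolution.

## Measurement error and sub-voxel policy

Micro-CT measures radii on a voxel grid (13.5 µm standard, 2 µm
fine-resolution mode); the maximum radius error is half a voxel.
First-order propagation through $t(a)$ doubles the relative error:
$\Delta t = 2t\,\Delta a/a$, so $\Delta t/t = \mathrm{voxel}/a$
(`propagate_radius_error()`, and per-grain in `growth_time_table()`).
Grains measured below one voxel are flagged `sub_voxel` and not dated —
their relative error is unbounded — rather than dropped or imputed.

## The synthetic generator and what it does (not) show

`generate_population()` forward-simulates the population structure the
analysis assumes: per-phase uniform densities over the published
envelopes (CPPD 2.15–2.61, HAP 1.78–2.20 g/cm³ — uniform because only
ranges and a coarse histogram are published, making it the
least-assumptive choice), a deterministic CPPD:HAP count allocation at
5.5:1 (the data show "more than five times" as many CPPD grains per
100 mm³), nucleation times uniform over the 6 years before extraction
(the span of observed growth times; the staggered-nucleation
*distribution* is an artifact choice, not an observed quantity), ages
drawn per group to match the sampled cohorts (30–40 control, 55–81
stenosis), and voxel quantization of the measured radii (round to
nearest multiple, consistent with the half-voxel maximum error). The
seed is part of the spec and echoed into every artifact; generation is
reproducible and leaves the caller's RNG stream untouched.

`recovery_experiment()` closes the loop: it inverts $t(a)$ on the
*measured* radii with the true per-grain densities and compares inferred
nucleation times to the hidden truth. Every error must satisfy the
half-voxel bound. The experiment reports the first-order bound
$2t\,\Delta a/a$ alongside the exact quantization bound
$t(a + \mathrm{voxel}/2) - t(a)$ — the same half-voxel bound computed
without linearization, larger by the factor $1 + \mathrm{voxel}/(4a)$ —
and asserts errors against the exact one, since near-worst-case
quantization draws do occur in populations of hundreds of grains. With
the true density replaced by a phase-midpoint value, recovery acquires a
systematic relative error $|\rho_\mathrm{mid}-\rho|/\rho$ (up to ~10%
for the CPPD envelope); this is reported, not asserted small.

What passing these tests shows is internal consistency of the pipeline
under the model's own assumptions. Real grains are non-spherical, share
a finite calcium supply, may partially dissolve or ripen, and nucleate
under biology the model does not represent; none of that is simulated,
so recovery performance here is an upper bound on what field data would
allow.

## Problem sizes and numerical defaults

Default test and experiment sizes are chosen so the whole suite runs in
seconds while keeping every check sharp: populations of 60–300 grains
(720 at the generator defaults), 3 seeds × 2 voxel sizes for the
recovery assertions, 20 random parameter tuples for the ODE oracle, and
diffusion grids of 150–800 radial nodes with as many time steps.
Closed-form comparisons use relative tolerance 1e−9 to 1e−12; matches
against published 2–3-significant-figure values use the printed
precision (rounding or ~1%); the mass-balance and convergence checks use
the thresholds stated above. Grid-convergence is measured against the
analytic transient at $R = 40a$, where far-field truncation is
negligible at the comparison time.

## Known limitations

* Single-ion growth medium: calcium speciation, inhibitors and other
  ions are outside the model; $c_0$ enters as given.
* No grain–grain competition, dissolution, Ostwald ripening or
  non-spherical shapes.
* The ligament diffusion coefficient is approximated by the muscle
  value; viscosity differences between the tissues are not modelled.
* Published per-case density ranges under-determine per-grain densities;
  rate-table reproduction is limited to internally consistent cells, and
  the density policy is an explicit, recorded choice.
* Reported growth-time bounds in the source data disagree in direction
  between summary statements ("more than" vs "up to" 4/5.5 years); the
  package reports computed values (4.07 yr at $a=0.1$, $\rho=1.78$) and
  takes no side.
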