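# grainclock

Dating mineral deposits in calcified spine ligaments from their size.

Ligamenta flava (the yellow ligaments between vertebral arches) develop
pathological calcifications: mostly hydroxyapatite-like mineral (HAP),
in some patients also calcium pyrophosphate dehydrate (CPPD). Micro-CT
gives each grain a radius `a` (0.02–0.1 cm in the measured cohorts) and
a density `ρ` (1.78–2.61 g/cm³), but not its age. Treating each grain as
a sphere whose growth is limited by diffusion of free calcium onto its
surface gives closed forms that turn size into time:

```
da/dt = D·c₀ / (a·ρ)        growth rate
t(a)  = a²·ρ / (2·D·c₀)     time to grow from nucleation to radius a
a(t)  = √(2·D·c₀·t / ρ)     radius after time t
```

with `D = 1.65×10⁻⁶ cm²/s` (calcium diffusion in muscle-like soft
tissue) and `c₀ = 4.2×10⁻⁵ g/cm³` (free, uncomplexed calcium in
extracellular fluid). The package implements these closed forms with
strict CGS unit handling; verifies them against two independent
numerical oracles (an adaptive ODE integration of the growth law, and a
finite-difference solver for the full time-dependent radial diffusion
problem); turns per-grain micro-CT tables into growth-rate tables,
growth-time tables with half-voxel error bars, and density histograms;
and generates seeded synthetic grain populations with voxel quantization
for nucleation-time recovery experiments. It is written for researchers
modelling soft-tissue mineralization who want the kinetics, the error
propagation, and the verification in one tested place.

## Worked example

Growth rate at the smallest and largest measured radii, for a grain
density of 1.98 g/cm³:

```r
library(grainclock)
signif(growth_rate(c(0.02, 0.1), 1.98), 3)
#> [1] 1.75e-09 3.50e-10
```

A 200 µm-radius grain grows in under a year; a 1 mm grain of the densest
CPPD takes about six years, with a half-voxel (13.5 µm) error bar of
about a month:

```r
rec <- tibble::tibble(case_id = "CPPD-81", age_years = 81,
                      group = "stenosis", phase = "CPPD",
                      radius_cm = c(0.02, 0.1), density_g_cm3 = 2.61,
                      voxel_um = 13.5)
growth_time_table(rec)[, c("radius_cm", "growth_time_years", "dt_years")]
#> # A tibble: 2 × 3
#>   radius_cm growth_time_years dt_years
#>       <dbl>             <dbl>    <dbl>
#> 1      0.02             0.239   0.0161
#> 2      0.1              5.97    0.0806
```

So the 1 mm grain nucleated 5.97 ± 0.08 years before extraction — large
enough to see in clinical imaging only years after the process started.

Per-case rate tables resolve a density from each case's published range
(policy recorded per row); `rate_table(ligament_cases(), policy =
"explicit", rho_explicit = 1.95)` reproduces the internally consistent
published cells, e.g. 1.78×10⁻⁹ cm/s at a = 0.02 cm.

A synthetic population with hidden nucleation times checks the whole
pipeline end to end — every inferred nucleation time must land inside
the half-voxel quantization bound:

```r
glance(recovery_experiment(population_spec(seed = 7)))
#> # A tibble: 1 × 8
#>   n_grains n_sub_voxel voxel_um  seed max_abs_error_s mean_abs_error_s max_bound_s all_within_bound
#> 1      720           0     13.5     7        2264624.          789839.    2557161. TRUE
```

(2.26×10⁶ s ≈ 0.07 years worst-case dating error at 13.5 µm voxels.)

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "grainclock.R", package = "grainclock")`, e.g.
`Rscript grainclock.R growth-time --a-cm 0.1 --rho 2.61 --json`.

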