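Package: grainclock
Title: Diffusion-Limited Growth Kinetics of Mineral Grains in Calcified
    Ligaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form diffusion-limited growth model for spherical
    mineral grains (hydroxyapatite-like and calcium pyrophosphate
    dehydrate) in calcified spine ligaments. Computes growth times and
    growth rates from micro-CT grain radii and densities, propagates
    half-voxel measurement error, reproduces per-case rate tables and
    radius-versus-time growth curves, and verifies the quasi-static
    closed forms against an ODE integrator and a finite-difference
    radial diffusion solver. Includes a seeded synthetic grain-population
    generator with voxel quantization for nucleation-time recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
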