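# Small in-memory grain tables used across test files.

# six valid grains covering both phases and both patient groups
grain_fixture <- function() {
  tibble::tibble(
    case_id = c("CPPD-72", "CPPD-72", "HAP-control-36", "HAP-control-36",
                "HAP-stenosis-59", "HAP-stenosis-59"),
    age_years = c(72, 72, 36, 36, 59, 59),
    group = c("stenosis", "stenosis", "control", "control",
              "stenosis", "stenosis"),
    phase = c("CPPD", "CPPD", "HAP", "HAP", "HAP", "HAP"),
    radius_cm = c(0.02, 0.1, 0.03, 0.08, 0.05, 0.1),
    density_g_cm3 = c(2.15, 2.25, 1.85, 2.0, 1.9, 1.95),
    voxel_um = 13.5
  )
}

# a case emulating the published CPPD-72 row: densities inside [2.15, 2.25],
# radii spanning the full printed 0.02-0.1 cm range
cppd72_fixture <- function(n = 20, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    case_id = "CPPD-72",
    age_years = 72,
    group = "stenosis",
    phase = "CPPD",
    radius_cm = c(0.02, 0.1, runif(n - 2, 0.02, 0.1)),
    density_g_cm3 = runif(n, 2.15, 2.25),
    voxel_um = 13.5
  )
}
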