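test_that("population specs validate their inputs", {
  expect_s3_class(population_spec(), "population_spec")
  expect_error(population_spec(cppd_hap_ratio = 0), "positive")
  expect_error(population_spec(nucleation_window_years = -1), "positive")
  expect_error(population_spec(rho_range_cppd = c(2.6, 2.1)), "min <= max")
})

test_that("generation is deterministic given the spec seed", {
  spec <- population_spec(grains_per_case = 30, seed = 99)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_identical(p1$records, p2$records)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_population(population_spec(grains_per_case = 30, seed = 100))
  expect_false(identical(p1$records$radius_cm, p3$records$radius_cm))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_population(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("generated grains respect the forward model and spec ranges", {
  spec <- population_spec(grains_per_case = 120, seed = 5)
  pop <- generate_population(spec)
  env <- growth_env()
  # every true radius is the closed-form radius at the grain's age
  elapsed <- -pop$truth$true_nucleation_offset_s
  expect_equal(pop$truth$true_radius_cm,
               radius_at_time(elapsed, pop$truth$true_density_g_cm3, env),
               tolerance = 1e-12)
  # per-grain bound at the window edge
  expect_true(all(pop$truth$true_radius_cm <=
                    radius_at_time(years_to_seconds(6),
                                   pop$truth$true_density_g_cm3, env) + 1e-15))
  # densities inside their phase envelopes
  cppd <- pop$records$phase == "CPPD"
  expect_true(all(pop$truth$true_density_g_cm3[cppd] >= 2.15 &
                    pop$truth$true_density_g_cm3[cppd] <= 2.61))
  expect_true(all(pop$truth$true_density_g_cm3[!cppd] >= 1.78 &
                    pop$truth$true_density_g_cm3[!cppd] <= 2.20))
  # nucleation offsets inside the window, in the past
  expect_true(all(pop$truth$true_nucleation_offset_s <= 0))
  expect_true(all(pop$truth$true_nucleation_offset_s >=
                    -years_to_seconds(6)))
})

test_that("phase counts follow the deterministic CPPD:HAP allocation", {
  pop <- generate_population(population_spec(n_cases_per_group = 1,
                                             grains_per_case = 300, seed = 2))
  n_cppd <- sum(pop$records$phase == "CPPD")
  # 5:1 with 600 grains means at least 500 CPPD
  expect_gte(n_cppd, 500)
  # count ratio within 2% of the spec ratio for a large population
  big <- generate_population(population_spec(n_cases_per_group = 5,
                                             grains_per_case = 1000, seed = 3))
  ratio <- sum(big$records$phase == "CPPD") / sum(big$records$phase == "HAP")
  expect_equal(ratio, 5.5, tolerance = 0.02)
})

test_that("voxel quantization rounds to the nearest multiple within half a voxel", {
  expect_equal(quantize_to_voxels(0.021, 13.5), 16 * 13.5e-4)
  expect_equal(quantize_to_voxels(0.021, 0), 0.021)
  expect_equal(quantize_to_voxels(10 * 13.5e-4, 13.5), 10 * 13.5e-4)
  set.seed(8)
  a <- runif(500, 0, 0.1)
  q <- quantize_to_voxels(a, 13.5)
  expect_true(all(abs(q - a) <= 13.5e-4 / 2 + 1e-15))
  expect_true(all(abs(q / 13.5e-4 - round(q / 13.5e-4)) < 1e-9))
  # measured = quantized truth inside a generated population
  pop <- generate_population(population_spec(grains_per_case = 50, seed = 13))
  expect_equal(pop$records$radius_cm,
               quantize_to_voxels(pop$truth$true_radius_cm, 13.5))
  expect_true(all(abs(pop$records$radius_cm - pop$truth$true_radius_cm) <=
                    13.5e-4 / 2 + 1e-15))
})

test_that("nucleation times are recovered within the half-voxel bound", {
  for (seed in c(1, 7, 23)) {
    for (voxel in c(13.5, 2)) {
      rec <- recovery_experiment(
        population_spec(grains_per_case = 80, voxel_um = voxel, seed = seed))
      expect_true(rec$all_within_bound)
      keep <- !rec$per_grain$sub_voxel
      expect_true(all(rec$per_grain$abs_error_s[keep] <=
                        rec$per_grain$bound_exact_s[keep]))
    }
  }
})

test_that("fine voxels recover almost exactly; zero voxel exactly", {
  rec2 <- recovery_experiment(population_spec(grains_per_case = 100,
                                              voxel_um = 2, seed = 4))
  expect_lt(seconds_to_years(rec2$max_abs_error_s), 0.02)
  rec0 <- recovery_experiment(population_spec(grains_per_case = 100,
                                              voxel_um = 0, seed = 4))
  expect_lt(seconds_to_years(rec0$max_abs_error_s), 1e-9)
  # coarser voxel gives the larger worst-case error
  rec13 <- recovery_experiment(population_spec(grains_per_case = 100,
                                               voxel_um = 13.5, seed = 4))
  expect_gt(rec13$max_abs_error_s, rec2$max_abs_error_s)
})

test_that("sub-voxel grains are excluded and counted, not dated", {
  # a short window at coarse voxels produces unquantifiable small grains
  spec <- population_spec(grains_per_case = 200,
                          nucleation_window_years = 0.3,
                          voxel_um = 13.5, seed = 6)
  rec <- recovery_experiment(spec)
  expect_gt(rec$n_sub_voxel, 0)
  expect_true(rec$all_within_bound)
  gl <- glance(rec)
  expect_equal(gl$n_sub_voxel, rec$n_sub_voxel)
})

test_that("a mis-specified density biases recovery proportionally", {
  # inverting with the phase-midpoint density instead of the true grain
  # density leaves a systematic error up to t * delta_rho / rho
  spec <- population_spec(grains_per_case = 150, voxel_um = 0, seed = 9)
  pop <- generate_population(spec)
  rho_mid <- mean(spec$rho_range_cppd)
  cppd <- pop$records$phase == "CPPD"
  t_hat <- growth_time(pop$records$radius_cm[cppd], rho_mid)
  t_true <- -pop$truth$true_nucleation_offset_s[cppd]
  rel_err <- abs(t_hat - t_true) / t_true
  rho_true <- pop$truth$true_density_g_cm3[cppd]
  expect_equal(rel_err, abs(rho_mid - rho_true) / rho_true, tolerance = 1e-9)
  expect_lt(max(rel_err),
            (rho_mid - spec$rho_range_cppd[1]) / spec$rho_range_cppd[1] + 1e-9)
})

test_that("populations survive the full CSV -> analysis pipeline", {
  spec <- population_spec(grains_per_case = 60, seed = 17)
  pop <- generate_population(spec)
  prefix <- file.path(withr::local_tempdir(), "pop")
  paths <- write_population(pop, prefix)
  expect_true(all(file.exists(paths)))
  echo <- jsonlite::read_json(paths[3])
  expect_equal(echo$seed, 17)
  expect_equal(echo$voxel_um, 13.5)

  back <- read_grain_table(paths[1])
  expect_equal(nrow(attr(back, "rejections")), 0)
  tab <- growth_time_table(back)
  truth <- readr::read_csv(paths[2], show_col_types = FALSE)
  ok <- !tab$sub_voxel
  err <- abs(tab$nucleation_offset_s[ok] - truth$true_nucleation_offset_s[ok])
  half <- 13.5e-4 / 2
  bound <- growth_time(back$radius_cm[ok] + half,
                       truth$true_density_g_cm3[ok]) -
    growth_time(back$radius_cm[ok], truth$true_density_g_cm3[ok])
  expect_true(all(err <= bound))
})
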