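test_that("scenario presets resolve to the identified energy levels", {
  p <- activity_params()
  expect_equal(scenario_config("sedentary")$scenario_energy, p$W0)
  expect_equal(scenario_config("intermittent")$scenario_energy, 3.7e-4)
  expect_equal(scenario_config("continuous")$scenario_energy, 3.78e-4)
  expect_error(scenario_config("custom"), "scenario_energy")
})

test_that("YAML and JSON configs load with defaults, units and key checking", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("name: intermittent", "dt_days: 0.2"), y)
  cfg <- load_config(y)
  expect_equal(cfg$scenario_energy, 3.7e-4)
  expect_equal(cfg$dt, 0.2)
  expect_equal(cfg$duration, 56)         # default filled
  expect_equal(cfg$energy_mode, "global")

  writeLines("mystery_knob: 3", y)
  expect_error(load_config(y), "mystery_knob")

  j <- tempfile(fileext = ".json")
  writeLines('{"name": "continuous", "delay_mode": "slow"}', j)
  cfgj <- load_config(j)
  expect_equal(cfgj$scenario_energy, 3.78e-4)
  expect_equal(cfgj$delay$mode, "slow")
  expect_equal(cfgj$delay$coefficient, 1e-5)

  # empty custom file -> all documented defaults
  writeLines("", y)
  cfg0 <- load_config(y)
  expect_equal(cfg0$duration, 56)
  expect_equal(cfg0$mesh_size, 0.1)
  expect_error(load_config(tempfile()), "not found")
})

test_that("fixtures are deterministic and honor their contracts", {
  m <- coarse_mesh(0.1, 1L)
  base <- make_fixture("arctan", mesh = m)
  expect_equal(base$density, initial_density_field(m))
  sh0 <- make_fixture("shifted", shift = 0, mesh = m)
  expect_equal(sh0$density, base$density)
  # seeded noise reproduces exactly and does not disturb the global RNG
  set.seed(99); before <- runif(1)
  n1 <- make_fixture("arctan", noise_amplitude = 0.02, seed = 7, mesh = m)
  n2 <- make_fixture("arctan", noise_amplitude = 0.02, seed = 7, mesh = m)
  n3 <- make_fixture("arctan", noise_amplitude = 0.02, seed = 8, mesh = m)
  expect_identical(n1$density, n2$density)
  expect_false(identical(n1$density, n3$density))
  set.seed(99); expect_identical(before, runif(1))
  expect_error(make_fixture("arctan", noise_amplitude = 5, seed = 7, mesh = m),
               "out-of-range")
  tw <- make_fixture("two_ring", mesh = m)
  expect_setequal(unique(tw$density), c(0.5, 1))
})

test_that("runs re-execute byte-identically and export a complete bundle", {
  d1 <- file.path(tempdir(), "runA"); d2 <- file.path(tempdir(), "runB")
  cfg <- fast_config("intermittent", duration = 7)
  export_result(run_scenario(cfg), d1)
  export_result(run_scenario(cfg), d2)
  for (f in c("timeseries.csv", "fields.vtk", "run_manifest.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  manifest <- jsonlite::read_json(file.path(d1, "run_manifest.json"))
  expect_equal(manifest$scenario_energy_mJ, 3.7e-4)
  expect_equal(manifest$activity$A1, 1992.36)
  ts <- utils::read.csv(file.path(d1, "timeseries.csv"))
  expect_true(all(c("time_days", "mean_density", "front_radius_mm",
                    "global_ob_activity", "global_oc_activity") %in% names(ts)))
  expect_true(all(diff(ts$time_days) > 0))
})

test_that("legacy VTK output is structurally valid", {
  m <- coarse_mesh(0.5, 2L)
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, cell_data = list(rho = rep(0.5, m$n_elem)),
            point_data = list(uz = seq_len(m$n_node) * 0.1))
  lines <- readLines(f)
  expect_identical(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl(sprintf("^POINTS %d double$", m$n_node), lines)))
  expect_true(any(grepl(sprintf("^CELLS %d %d$", m$n_elem, 5 * m$n_elem),
                        lines)))
  expect_true(any(grepl("^SCALARS rho double 1$", lines)))
  # every cell is a VTK_QUAD
  ct <- which(grepl("^CELL_TYPES", lines))
  expect_true(all(lines[(ct + 1):(ct + m$n_elem)] == "9"))
})

test_that("command-line driver runs its subcommands end to end", {
  out <- tempfile(fileext = ".csv")
  expect_identical(run_cli(c("profile", "--radii", "0,0.5,1.5",
                             "--out", out)), 0L)
  prof <- utils::read.csv(out)
  expect_equal(prof$density, c(density_profile(0), 0.56, density_profile(1.5)),
               tolerance = 1e-9)

  dir <- file.path(tempdir(), "cli_run")
  invisible(capture.output(
    code <- suppressMessages(run_cli(c("run", "--scenario", "sedentary",
                                       "--days", "2", "--dt", "0.25",
                                       "--out", dir)))))
  expect_identical(code, 0L)
  ts <- utils::read.csv(file.path(dir, "timeseries.csv"))
  expect_equal(ts$mean_density[1], ts$mean_density[nrow(ts)],
               tolerance = 1e-12)

  cal <- file.path(tempdir(), "cli_cal")
  invisible(capture.output(
    code <- suppressMessages(run_cli(c("calibrate", "--out", cal)))))
  expect_identical(code, 0L)
  expect_true(file.exists(file.path(cal, "calibration.csv")))

  # bad input paths exit non-zero with usage text
  expect_identical(suppressMessages(run_cli(character())), 2L)
  expect_identical(suppressMessages(run_cli(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(run_cli(c("run", "--days"))), 2L)
})
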