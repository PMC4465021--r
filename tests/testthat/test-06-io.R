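test_that("config round-trips through YAML", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario:",
    "  preset: bottle1",
    "solver:",
    "  dt: 0.2",
    "run:",
    "  end_time: 20",
    "  sample_interval: 10"), cfg_file)
  cfg <- load_config(cfg_file)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$options$dt, 0.2)
  # preset scenario matches bottle_scenario structurally
  ref <- bottle_scenario("bottle1")
  expect_equal(cfg$scenario$dims, ref$dims)
  expect_equal(cfg$scenario$initial_temperatures, ref$initial_temperatures)

  out <- tempfile(fileext = ".yaml")
  write_config(cfg, out)
  cfg2 <- load_config(out)
  expect_equal(cfg2$scenario$dims, cfg$scenario$dims)
  expect_equal(cfg2$options[order(names(cfg2$options))],
               cfg$options[order(names(cfg$options))])
  expect_equal(cfg2$run$end_time, cfg$run$end_time)
})

test_that("material values survive the config format at full precision", {
  cfg_file <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: bottle2", "run:", "  end_time: 10",
               "  sample_interval: 5"), cfg_file)
  cfg <- load_config(cfg_file)
  out <- tempfile(fileext = ".yaml")
  write_config(cfg, out)
  cfg2 <- load_config(out)
  for (nm in names(cfg$scenario$materials)) {
    m1 <- cfg$scenario$materials[[nm]]; m2 <- cfg2$scenario$materials[[nm]]
    expect_identical(m1$rho, m2$rho)
    expect_identical(m1$cp, m2$cp)
    expect_identical(m1$k, m2$k)
    expect_identical(m1$beta, m2$beta)
    expect_identical(m1$mu, m2$mu)
  }
})

test_that("invalid configurations are rejected with the key path", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("scenario: bottle1", "solver:", "  dt: -0.1",
               "run:", "  end_time: 10", "  sample_interval: 5"), f)
  expect_error(load_config(f), "solver.dt")
  writeLines(c("scenario: bottle1", "solver:", "  warp_speed: 9",
               "run:", "  end_time: 10", "  sample_interval: 5"), f)
  expect_error(load_config(f), "solver.warp_speed")
  writeLines(c("scenario: bottle1",
               "run:", "  end_time: 2", "  sample_interval: 5"), f)
  expect_error(load_config(f), "end_time")
  expect_error(load_config(tempfile()), "not found")
})

test_that("metrics CSV round-trips at full precision", {
  m <- data.frame(time_s = c(0, 10), pat_C = c(4, 12.3456789012345),
                  frac_above_40 = c(0, 1 / 3), t_min_C = c(4, 5),
                  t_max_C = c(4, 77.7))
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(m, f)
  txt <- readLines(f)
  expect_equal(txt[1], "time_s,pat_C,frac_above_40,t_min_C,t_max_C")
  expect_equal(length(txt), 3)
  m2 <- read_metrics_csv(f)
  expect_equal(m2, m, tolerance = 1e-14)
})

test_that("write_outputs produces CSV, VTK and a checksum manifest", {
  run <- simulate_warming(bottle_scenario("bottle1"), quick_options(),
                          end_time = 4, sample_interval = 2,
                          target_cells = 700, snapshot_times = 4)
  dir <- tempfile()
  man <- write_outputs(run, dir)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "snapshot_4s.vtk")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_equal(length(man$files), 2)
  # VTK file is well-formed legacy ASCII
  vtk <- readLines(file.path(dir, "snapshot_4s.vtk"), n = 4)
  expect_equal(vtk[1], "# vtk DataFile Version 3.0")
  expect_equal(vtk[3], "ASCII")
  # checksums match the files on disk
  for (f in man$files)
    expect_equal(unname(tools::md5sum(file.path(dir, f$path))), f$md5)
})

test_that("two runs from one configuration yield identical CSVs", {
  sc <- bottle_scenario("bottle1")
  f1 <- tempfile(); f2 <- tempfile()
  r1 <- simulate_warming(sc, quick_options(), end_time = 4,
                         sample_interval = 2, target_cells = 700)
  r2 <- simulate_warming(sc, quick_options(), end_time = 4,
                         sample_interval = 2, target_cells = 700)
  write_metrics_csv(r1$metrics, f1)
  write_metrics_csv(r2$metrics, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("sampling contract yields one CSV row per sample time", {
  run <- simulate_warming(bottle_scenario("bottle1"), quick_options(),
                          end_time = 6, sample_interval = 2,
                          target_cells = 700)
  expect_equal(run$metrics$time_s, c(0, 2, 4, 6))
  f <- tempfile()
  write_metrics_csv(run$metrics, f)
  expect_equal(length(readLines(f)), 5)   # header + 4 rows
})
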