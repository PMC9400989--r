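test_that("raw matrices round-trip losslessly through their text format", {
  scn <- small_scenario()
  raw <- simulate_experiment(scn, 0.03, H = 1.3, seed = 6L)
  f <- withr::local_tempfile(fileext = ".dat")
  write_matrix(raw, f)
  back <- read_matrix(f)
  expect_equal(back$S, raw$S, ignore_attr = TRUE)
  expect_equal(back$depth_axis, raw$depth_axis)
  expect_equal(back$freq_axis, raw$freq_axis)
  expect_equal(back$t_E, raw$t_E)
  expect_equal(back$sigma, raw$sigma)
  expect_equal(back$provenance$tau_M, 0.03)
})

test_that("malformed matrix files yield descriptive parse errors", {
  scn <- small_scenario()
  raw <- simulate_experiment(scn, 0.03, seed = 6L)
  f <- withr::local_tempfile(fileext = ".dat")

  write_matrix(raw, f)
  lines <- readLines(f)
  short <- lines[-length(lines)]
  writeLines(short, f)
  expect_error(read_matrix(f), "matrix rows")

  writeLines(sub("^# depth_axis_m = [0-9.e+-]+ ", "# depth_axis_m = ", lines), f)
  expect_error(read_matrix(f), "depth axis length")

  body_start <- sum(grepl("^#", lines))
  lines2 <- lines
  lines2[body_start + 3] <- sub("[0-9.e+-]+$", "NaN", lines2[body_start + 3])
  writeLines(lines2, f)
  expect_error(read_matrix(f), "non-finite entry in matrix row 3")

  expect_error(read_matrix(file.path(tempdir(), "missing.dat")), "no such file")
})

test_that("coil files and configs parse with units and strict keys", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# image of a uniform sample", "0e0 1.0", "1e-4 4.0", "2e-4 2.0"), f)
  coil <- read_coil(f)
  expect_equal(max(coil$sensitivity), 1)
  expect_equal(eval_coil(coil, 1e-4), 1)

  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# run configuration",
               "instrument.B0_T = 0.3",
               "instrument.G_Tm = 7.28",
               "encoding.delta_max_us = 160",
               "cpmg.tE_us = 600",
               "sample.k_per_s = 14",
               "sample.intra.p = 0.24",
               "scenario.tauM_ms = 10 30 100",
               "scenario.snr = 280",
               "scenario.seed = 4",
               "pipeline.n_z = 64"), cfg)
  scn <- read_config(cfg)
  expect_s3_class(scn, "scenario")
  expect_equal(scn$encoding$delta_max, 160e-6)
  expect_equal(scn$cpmg$t_E, 600e-6)
  expect_equal(scn$tau_M, c(0.010, 0.030, 0.100))
  expect_equal(scn$seed, 4L)
  expect_equal(scn$n_z, 64L)

  writeLines("instrument.B0_tesla = 0.3", cfg)
  expect_error(read_config(cfg), "unknown config key")
})

test_that("the CLI chains simulate, invert and kinetics reproducibly", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "run.cfg")
  writeLines(c("scenario.tauM_ms = 10 30 100", "scenario.snr = 280",
               "pipeline.n_z = 64", "pipeline.n_substeps = 16",
               "cpmg.n_echoes = 32"), cfg)
  out1 <- file.path(dir, "d1"); out2 <- file.path(dir, "d2")
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--config", cfg, "--seed", "11", "--out", out1))), 0L)
  expect_equal(suppressMessages(
    run_cli(c("simulate", "--config", cfg, "--seed", "11", "--out", out2))), 0L)
  raws <- list.files(out1, pattern = "^raw_", full.names = TRUE)
  expect_length(raws, 3)
  for (f in basename(raws))
    expect_identical(readLines(file.path(out1, f)), readLines(file.path(out2, f)))

  maps_f <- file.path(dir, "maps.tsv")
  expect_equal(suppressMessages(
    run_cli(c("invert", "--config", cfg, "--out", maps_f, raws))), 0L)
  fit_f <- file.path(dir, "fit.txt")
  expect_equal(suppressMessages(
    run_cli(c("kinetics", "--out", fit_f, maps_f))), 0L)
  lines <- readLines(fit_f)
  k_hat <- as.numeric(sub(".*= ", "", grep("^k_per_s", lines, value = TRUE)))
  expect_gt(k_hat, 5); expect_lt(k_hat, 30)

  # one map only: a kinetics fit is refused
  one_map <- file.path(dir, "one.tsv")
  expect_equal(suppressMessages(
    run_cli(c("invert", "--config", cfg, "--out", one_map, raws[1]))), 0L)
  expect_gt(suppressMessages(
    run_cli(c("kinetics", "--out", fit_f, one_map))), 0L)
})

test_that("CLI usage and error paths exit with documented statuses", {
  out <- capture.output(st_help <- run_cli("--help"))
  expect_equal(st_help, 0L)
  expect_true(any(grepl("subcommands", out)))
  st_bad <- suppressMessages(run_cli("frobnicate"))
  expect_equal(st_bad, 2L)
  expect_equal(suppressMessages(run_cli(c("simulate", "--bogus"))), 2L)
  expect_equal(suppressMessages(
    run_cli(c("invert", "--out", "x", file.path(tempdir(), "nope.dat")))), 3L)
})
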