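# Synthetic e-nose campaign generator.

test_that("the default schedule is the 60/200/500 s cycle", {
  sch <- phase_schedule()
  expect_equal(sch$total_s, 760)
  expect_equal(sch$t_injection_s, 60)
  expect_equal(sch$t_purge_s, 260)
  expect_length(schedule_times(sch), 760)
  expect_error(phase_schedule(baseline_s = -1), "positive")
  expect_error(phase_schedule(sample_period_s = 0), "positive")
})

test_that("a noiseless transient follows its closed form exactly", {
  tau_r <- 20
  tau_d <- 80
  tr <- toy_transient(depth = 0.5, tau_rise = tau_r, tau_recovery = tau_d)
  Ri <- 1e5
  Rf <- 5e4
  t <- tr$t
  expected <- ifelse(t < 60, Ri,
    ifelse(t < 260,
      Rf + (Ri - Rf) * exp(-(t - 60) / tau_r),
      Ri + (Rf + (Ri - Rf) * exp(-200 / tau_r) - Ri) * exp(-(t - 260) / tau_d)
    )
  )
  expect_equal(max(abs(tr$R - expected)), 0)
  expect_true(all(tr$R > 0))
  # plateau: late-injection samples sit at Rf
  expect_equal(tr$R[t == 259], Rf, tolerance = 1e-3)
})

test_that("time to 90% of the response equals tau * ln(10) for first-order kinetics", {
  tr <- toy_transient(depth = 0.5, tau_rise = 20)
  # dense numerical crossing search, independent of extract_features
  tt <- seq(60, 260, by = 0.001)
  Rdense <- 5e4 + 5e4 * exp(-(tt - 60) / 20)
  t90 <- tt[which(Rdense <= 1e5 - 0.9 * 5e4)[1]] - 60
  expect_equal(t90, 20 * log(10), tolerance = 1e-3)
})

test_that("class effect is monotone for a monotone sensor", {
  s1 <- default_sensor_array()[1, ] # S1: depth increases C1 -> C3
  tr1 <- generate_transient("C1", s1)
  tr3 <- generate_transient("C3", s1)
  # deeper response = lower plateau
  expect_lt(min(tr3$R), min(tr1$R))
})

test_that("invalid kinetics and depths are rejected", {
  expect_error(toy_transient(depth = 0), "depth")
  expect_error(toy_transient(depth = 1.2), "depth")
  expect_error(toy_transient(tau_rise = 0), "constants")
  expect_error(
    generate_transient("C9", default_sensor_array()[1, ]),
    "class"
  )
})

test_that("generated constituent tables respect their class ranges", {
  spec <- list(C1 = list(range = c(2, 9), n_genotypes = 4L))
  cfg <- generator_config(n_genotypes = 4L, class_spec = spec, rng_seed = 3)
  tab <- generate_constituent_table(cfg)
  lab <- label_dataset(tab)
  expect_true(all(lab$total_percent >= 2 & lab$total_percent <= 9))
  expect_true(all(as.character(lab$class) == "C1"))
  # six nonnegative key-constituent rows summing to the drawn total
  expect_equal(tab$constituent, key_constituents())
  expect_true(all(as.matrix(tab[, -1]) >= 0))
})

test_that("fixture mode returns the reference panel verbatim", {
  cfg <- generator_config()
  expect_identical(
    generate_constituent_table(cfg, mode = "fixture"),
    rose_constituent_table()
  )
})

test_that("infeasible class ranges are configuration errors", {
  expect_error(
    generator_config(
      n_genotypes = 2L,
      class_spec = list(C1 = list(range = c(9, 2), n_genotypes = 2L))
    ),
    "infeasible"
  )
  expect_error(
    generator_config(
      n_genotypes = 2L,
      class_spec = list(C1 = list(range = c(5, 20), n_genotypes = 2L))
    ),
    "inside"
  )
})

test_that("dataset size is genotypes x replicates with rule-derived labels", {
  cfg <- generator_config(
    n_genotypes = 2L, replicates_per_genotype = 3L,
    class_spec = list(
      C1 = list(range = c(2, 9), n_genotypes = 1L),
      C3 = list(range = c(55, 80), n_genotypes = 1L)
    ),
    rng_seed = 5
  )
  ds <- generate_dataset(cfg)
  expect_length(ds$measurements, 6)
  expect_equal(as.vector(table(ds$labels$class)), c(3, 0, 3))
  expect_length(ds$measurements[[1]]$transients, 7)
})

test_that("the reference-panel campaign yields 150 measurements split 60/45/45", {
  ds <- generate_dataset(generator_config(rng_seed = 11), constituents = "fixture")
  expect_length(ds$measurements, 150)
  expect_equal(as.vector(table(ds$labels$class)), c(60, 45, 45))
})

test_that("a fixed seed reproduces the dataset and its CSV export byte for byte", {
  cfg <- generator_config(
    n_genotypes = 2L, replicates_per_genotype = 2L,
    class_spec = list(
      C1 = list(range = c(2, 9), n_genotypes = 1L),
      C2 = list(range = c(12, 45), n_genotypes = 1L)
    ),
    rng_seed = 99
  )
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$labels, ds2$labels)
  expect_identical(
    ds1$measurements[["m001"]]$transients[["S3"]]$R,
    ds2$measurements[["m001"]]$transients[["S3"]]$R
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_enose_csv(ds1, d1)
  write_enose_csv(ds2, d2)
  for (f in c("measurements.csv", "labels.csv", "constituents.csv")) {
    expect_identical(
      readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
      readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    )
  }
  back <- read_enose_csv(d1, schedule = cfg$schedule)
  expect_equal(
    back$measurements[["m001"]]$transients[["S3"]]$R,
    ds1$measurements[["m001"]]$transients[["S3"]]$R
  )
})

test_that("generator configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_genotypes: 10", "replicates_per_genotype: 4", "noise_cv: 0.05",
    "rng_seed: 12", "schedule:", "  baseline_s: 30", "  injection_s: 100",
    "  recovery_s: 250", "  sample_period_s: 1"
  ), f)
  cfg <- read_generator_config(f)
  expect_equal(cfg$replicates_per_genotype, 4L)
  expect_equal(cfg$noise_cv, 0.05)
  expect_equal(cfg$schedule$total_s, 380)
})
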