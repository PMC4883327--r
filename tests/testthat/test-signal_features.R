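# Phase segmentation and the seven per-sensor response features.

test_that("phases split at 60 s and 260 s, half-open on the right", {
  tr <- toy_transient()
  ph <- segment_phases(tr)
  expect_equal(range(tr$t[ph$baseline]), c(0, 59))
  expect_equal(range(tr$t[ph$injection]), c(60, 259))
  expect_equal(range(tr$t[ph$recovery]), c(260, 759))
  # disjoint and exhaustive
  all_idx <- sort(c(ph$baseline, ph$injection, ph$recovery))
  expect_identical(all_idx, seq_along(tr$t))
})

test_that("boundary indices scale with the sampling rate", {
  sch <- phase_schedule(sample_period_s = 0.5)
  tr <- toy_transient(schedule = sch)
  ph <- segment_phases(tr)
  expect_length(ph$baseline, 120)
  expect_length(ph$injection, 400)
})

test_that("a truncated recording is an error", {
  tr <- toy_transient()
  tr$t <- tr$t[tr$t < 500]
  tr$R <- tr$R[seq_along(tr$t)]
  expect_error(segment_phases(tr), "span")
})

test_that("steady-state features follow the closed forms", {
  f <- extract_features(toy_transient(depth = 0.5))
  expect_equal(unname(f["f1"]), 2, tolerance = 1e-3)
  expect_equal(unname(f["f2"]), 5e4, tolerance = 1e-3)
  expect_equal(unname(f["f3"]), 0.5, tolerance = 1e-3)
  expect_equal(unname(f["f4"]), 1e-5, tolerance = 1e-3)
  expect_equal(unname(f["f5"]), 1, tolerance = 1e-3)
})

test_that("a flat curve gives identity features and phase-duration times", {
  tr <- toy_transient(depth = 0.5)
  tr$R <- rep(1e5, length(tr$t))
  w <- capture_warnings(f <- extract_features(tr))
  expect_length(w, 2)
  expect_match(w[1], "response")
  expect_match(w[2], "recovery")
  expect_equal(unname(f["f1"]), 1)
  expect_equal(unname(f[c("f2", "f3", "f4", "f5")]), rep(0, 4))
  expect_equal(unname(f["f6"]), 200)
  expect_equal(unname(f["f7"]), 500)
})

test_that("response time recovers tau * ln(10) for first-order kinetics", {
  f <- extract_features(toy_transient(depth = 0.5, tau_rise = 20))
  expect_lt(abs(f[["f6"]] - 20 * log(10)), 1) # within one sample period
  f7_expect <- 80 * log(10)
  f <- extract_features(toy_transient(depth = 0.5, tau_recovery = 80))
  expect_lt(abs(f[["f7"]] - f7_expect), 1)
})

test_that("algebraic identities hold on random transients", {
  withr::with_seed(7, {
    for (i in 1:50) {
      tr <- toy_transient(
        depth = stats::runif(1, 0.05, 0.9),
        noise_cv = stats::runif(1, 0, 0.05)
      )
      f <- suppressWarnings(extract_features(tr))
      Ri <- attr(f, "Ri")
      Rf <- attr(f, "Rf")
      expect_equal(f[["f5"]], f[["f1"]] - 1, tolerance = 1e-9)
      expect_equal(f[["f3"]], 1 - 1 / f[["f1"]], tolerance = 1e-9)
      expect_equal(f[["f4"]], f[["f2"]] / (Ri * Rf), tolerance = 1e-9)
    }
  })
})

test_that("resistance-decreasing responses give positive features", {
  withr::with_seed(8, {
    for (i in 1:10) {
      f <- extract_features(toy_transient(depth = stats::runif(1, 0.1, 0.9)))
      expect_gt(f[["f1"]], 1)
      expect_gt(f[["f2"]], 0)
      expect_true(f[["f3"]] > 0 && f[["f3"]] < 1)
      expect_gt(f[["f4"]], 0)
      expect_gt(f[["f5"]], 0)
    }
  })
})

test_that("dimensionless and kinetic features are scale-equivariant", {
  tr <- toy_transient(depth = 0.4, noise_cv = 0.02)
  f1 <- extract_features(tr)
  tr$R <- tr$R * 3.7
  f2 <- extract_features(tr)
  for (nm in c("f1", "f3", "f5", "f6", "f7")) {
    expect_equal(f1[[nm]], f2[[nm]], tolerance = 1e-12, label = nm)
  }
  expect_equal(f2[["f2"]], 3.7 * f1[["f2"]], tolerance = 1e-12)
})

test_that("the feature matrix is measurements x 49 in sensor-major order", {
  cfg <- generator_config(
    n_genotypes = 2L, replicates_per_genotype = 2L,
    class_spec = list(
      C1 = list(range = c(2, 9), n_genotypes = 1L),
      C3 = list(range = c(55, 80), n_genotypes = 1L)
    ),
    rng_seed = 21
  )
  ds <- generate_dataset(cfg)
  fm <- build_feature_matrix(ds)
  expect_equal(dim(fm$X), c(4, 49))
  expect_equal(colnames(fm$X)[1:8], c(paste0("S1f", 1:7), "S2f1"))
  expect_equal(as.character(fm$y), c("C1", "C1", "C3", "C3"))

  one <- build_feature_matrix(ds$measurements[1])
  expect_equal(dim(one$X), c(1, 49))

  dup <- ds$measurements[c(1, 1)]
  expect_error(build_feature_matrix(dup), "duplicate")

  broken <- ds$measurements
  broken[[1]]$transients$S4 <- NULL
  expect_error(build_feature_matrix(broken), "S4")
})

test_that("column-max scaling maps to [0,1] and is idempotent", {
  X <- cbind(a = c(2, 4, 8), b = c(5, 5, 5), c = c(0, 0, 0))
  n1 <- normalize_columns(X)
  expect_equal(unname(n1[, "a"]), c(0.25, 0.5, 1))
  expect_equal(unname(n1[, "b"]), c(1, 1, 1))
  expect_equal(unname(n1[, "c"]), c(0, 0, 0))
  n2 <- normalize_columns(n1)
  expect_equal(as.vector(n2), as.vector(n1))
})

test_that("negative columns fall back to min-max with a warning", {
  X <- cbind(a = c(-1, 0, 3), b = c(1, 2, 4))
  expect_warning(n <- normalize_columns(X), "min-max")
  expect_equal(unname(n[, "a"]), c(0, 0.25, 1))
  expect_equal(unname(n[, "b"]), c(0.25, 0.5, 1))
})

test_that("stored normalization stats replay onto new rows, clipped to [0,1]", {
  X <- cbind(a = c(2, 4), b = c(1, 10))
  n <- normalize_columns(X)
  st <- attr(n, "norm_stats")
  new <- normalize_columns(cbind(a = 8, b = 5), stats = st)
  expect_equal(unname(new[1, ]), c(1, 0.5)) # 8/4 clipped to 1, 5/10
})
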