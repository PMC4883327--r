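# Fuzzy ARTMAP: complement coding, choice/match/learn primitives, training,
# prediction, incremental updates, serialization.

test_that("complement coding doubles the vector and fixes the norm at M", {
  expect_equal(complement_code(c(0.3, 0.7)), c(0.3, 0.7, 0.7, 0.3))
  M <- 5
  expect_equal(complement_code(rep(0, M)), c(rep(0, M), rep(1, M)))
  withr::with_seed(1, {
    for (i in 1:20) {
      a <- stats::runif(sample(1:10, 1))
      expect_equal(sum(complement_code(a)), length(a))
    }
  })
  expect_error(complement_code(c(x1 = 0.5, x2 = 1.3)), "x2")
  expect_error(complement_code(c(-0.1)), "outside")
})

test_that("choice and match behave as the fuzzy ART formulas dictate", {
  I <- complement_code(c(0.6, 0.4)) # |I| = 2, dim 4
  alpha <- 0.001
  w_unc <- rep(1, 4)
  expect_equal(
    rosenose:::artmap_choice(I, matrix(w_unc), sum(w_unc), alpha),
    2 / 4.001,
    tolerance = 1e-12
  )
  expect_equal(
    rosenose:::artmap_choice(I, matrix(I), sum(I), alpha),
    2 / 2.001,
    tolerance = 1e-12
  )
  w_disjoint <- c(0, 0, 0, 0)
  expect_equal(rosenose:::artmap_choice(I, matrix(w_disjoint), 0, alpha), 0)
  # match: exact weight and uncommitted both resonate fully
  expect_equal(rosenose:::artmap_match(I, I), 1)
  expect_equal(rosenose:::artmap_match(I, w_unc), 1)
})

test_that("learning is the fuzzy-min update and is idempotent at beta = 1", {
  I <- c(0.4, 0.8)
  expect_equal(rosenose:::artmap_learn(c(1, 1), I, 1), I)
  expect_equal(rosenose:::artmap_learn(I, I, 1), I)
  expect_equal(rosenose:::artmap_learn(c(1, 1), I, 0.5), c(0.7, 0.9))
})

test_that("two patterns with two classes commit two categories and recall perfectly", {
  X <- rbind(c(0.2, 0.8), c(0.9, 0.1))
  y <- c("C1", "C2")
  m <- fuzzy_artmap(X, y)
  expect_equal(ncol(m$weights), 2)
  expect_equal(as.character(predict(m, X)), y)
})

test_that("training recall is 100% on any consistent dataset", {
  b <- make_unit_clusters(n_per = 20, p = 5, seed = 13)
  m <- fuzzy_artmap(b$X, b$y)
  expect_equal(mean(predict(m, b$X) == b$y), 1)
  expect_lte(ncol(m$weights), nrow(b$X))
})

test_that("training is deterministic and stable after convergence", {
  b <- make_unit_clusters(n_per = 12, p = 4, seed = 14)
  m1 <- fuzzy_artmap(b$X, b$y)
  m2 <- fuzzy_artmap(b$X, b$y)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$category_class, m2$category_class)
  # re-presenting the training set changes nothing (fast-learn stability)
  m3 <- artmap_update(m1, b$X, b$y)
  expect_identical(m3$weights, m1$weights)
})

test_that("weights only shrink as training proceeds", {
  b <- make_unit_clusters(n_per = 15, p = 4, seed = 15)
  half <- seq_len(30)
  m1 <- fuzzy_artmap(b$X[half, ], b$y[half])
  m2 <- artmap_update(m1, b$X[-half, ], b$y[-half])
  shared <- seq_len(ncol(m1$weights))
  expect_true(all(m2$weights[, shared] <= m1$weights[, shared] + 1e-15))
})

test_that("online updates match batch training category-for-category", {
  b <- make_unit_clusters(n_per = 15, p = 4, seed = 16)
  batch <- fuzzy_artmap(b$X, b$y, hyper = artmap_hyperparams(max_epochs = 1))
  first <- seq_len(20)
  online <- fuzzy_artmap(b$X[first, ], b$y[first], hyper = artmap_hyperparams(max_epochs = 1))
  online <- artmap_update(online, b$X[-first, ], b$y[-first])
  expect_equal(ncol(online$weights), ncol(batch$weights))
})

test_that("prediction follows the map field and breaks ties to the lowest index", {
  X <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  m <- fuzzy_artmap(X, c("C1", "C2"))
  # single-category model: collapse to the first category only
  m1 <- m
  m1$weights <- m$weights[, 1, drop = FALSE]
  m1$category_class <- m$category_class[1]
  p <- predict(m1, rbind(c(0.9, 0.9), c(0.1, 0.1)))
  expect_equal(as.character(p), c("C1", "C1"))
  # duplicating a committed weight vector at a higher index changes nothing
  m2 <- m
  m2$weights <- cbind(m$weights, m$weights[, 1])
  m2$category_class <- c(m$category_class, 2L) # duplicate maps elsewhere
  expect_equal(
    as.character(predict(m2, X)),
    as.character(predict(m, X))
  )
})

test_that("malformed inputs are rejected", {
  X <- rbind(c(0.2, 0.8), c(0.9, 0.1))
  m <- fuzzy_artmap(X, c("a", "b"))
  expect_error(fuzzy_artmap(rbind(c(1.2, 0)), "a"), "\\[0, 1\\]")
  expect_error(predict(m, rbind(c(2, 0))), "\\[0, 1\\]")
  expect_error(predict(m, matrix(0.5, 1, 3)), "dimension")
  m0 <- m
  m0$weights <- m$weights[, 0, drop = FALSE]
  m0$category_class <- integer(0)
  expect_error(predict(m0, X), "no committed categories")
  expect_error(artmap_hyperparams(alpha = 0), "alpha")
})

test_that("models round-trip through JSON with identical behaviour", {
  b <- make_unit_clusters(n_per = 8, p = 3, seed = 17)
  m <- fuzzy_artmap(b$X, b$y)
  f <- withr::local_tempfile(fileext = ".json")
  write_artmap(m, f)
  m2 <- read_artmap(f)
  expect_equal(m2$weights, unname(m$weights))
  expect_identical(m2$category_class, m$category_class)
  expect_equal(as.character(predict(m2, b$X)), as.character(predict(m, b$X)))
  # restored models keep learning incrementally
  m3 <- artmap_update(m2, b$X, b$y)
  expect_equal(ncol(m3$weights), ncol(m2$weights))
})

test_that("a seeded shuffle changes only the presentation order, reproducibly", {
  b <- make_unit_clusters(n_per = 10, p = 4, seed = 18)
  s1 <- fuzzy_artmap(b$X, b$y, shuffle = TRUE, seed = 5)
  s2 <- fuzzy_artmap(b$X, b$y, shuffle = TRUE, seed = 5)
  expect_identical(s1$weights, s2$weights)
  expect_equal(mean(predict(s1, b$X) == b$y), 1)
})
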