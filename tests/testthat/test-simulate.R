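test_that("diet grids have the predicted combinatorial size", {
  expect_identical(nrow(make_diet_grid(7, 0.25)), 210L)
  g <- make_diet_grid(2, 1)
  expect_identical(nrow(g), 2L)
  expect_setequal(split(g, row(g)), list(c(0, 1), c(1, 0)))
  for (I in 2:5) {
    for (inc in c(0.5, 0.25, 0.2)) {
      gI <- round(1 / inc)
      expect_identical(nrow(make_diet_grid(I, inc)),
                       as.integer(choose(I + gI - 1, gI)))
    }
  }
  expect_error(make_diet_grid(3, 0.3), "integer")
  expect_error(make_diet_grid(1, 0.5), "at least 2")
})

test_that("the 3-type 0.1-increment grid matches exhaustive enumeration", {
  g <- make_diet_grid(3, 0.1)
  brute <- expand.grid(a = 0:10, b = 0:10, c = 0:10)
  brute <- brute[rowSums(brute) == 10, ]
  expect_identical(nrow(g), nrow(brute))
  got <- apply(attr(g, "units"), 1, paste, collapse = ",")
  want <- apply(as.matrix(brute), 1, paste, collapse = ",")
  expect_setequal(got, want)
})

test_that("grid rows sum exactly to one in integer units", {
  for (I in c(3, 7)) {
    g <- make_diet_grid(I, 0.25)
    units <- attr(g, "units")
    expect_true(all(rowSums(units) == attr(g, "g")))
    expect_lt(max(abs(rowSums(g) - 1)), 1e-12)
    # ascending lexicographic enumeration
    key <- units %*% (nrow(units) + 1)^rev(seq_len(I) - 1)
    expect_true(all(diff(key) > 0))
  }
})

test_that("random calibration coefficients are scaled chi-square(1) draws", {
  cc <- random_cc(32, seed = 5)
  expect_lt(abs(sum(cc) - 32), 1e-12)
  expect_true(all(cc >= 0.02))
  expect_identical(cc, random_cc(32, seed = 5))
  expect_false(identical(cc, random_cc(32, seed = 6)))
  # heavy right tail of chi-square(1): most draws below 1, a few large
  expect_gt(max(cc), 2)
  expect_gt(mean(cc < 1), 0.5)
})

test_that("synthetic prey libraries satisfy the library contract", {
  lib <- synth_prey_library(I = 7, K = 32, n_per_type = 10, seed = 4)
  expect_s3_class(lib, "prey_library")
  expect_identical(dim(lib$sig), c(70L, 32L))
  expect_identical(dim(lib$means), c(7L, 32L))
  expect_simplex_rows(lib$sig)
  expect_simplex_rows(lib$means)
  expect_true(all(table(lib$prey_type) == 10))
  expect_error(synth_prey_library(I = 8, K = 8, n_per_type = 2), "K > I")
})

test_that("zero separation collapses all type means onto one composition", {
  lib <- synth_prey_library(I = 4, K = 9, n_per_type = 3, separation = 0,
                            within_sd = 0, seed = 8)
  expect_lt(max(abs(sweep(lib$means, 2, lib$means[1, ]))), 1e-12)
})

test_that("between-type Aitchison separation grows with the knob", {
  mean_pairwise <- function(sep) {
    ds <- vapply(1:6, function(seed) {
      m <- synth_prey_library(I = 5, K = 12, n_per_type = 2,
                              separation = sep, within_sd = 0,
                              seed = seed)$means
      pairs <- utils::combn(5, 2)
      mean(apply(pairs, 2, function(p) {
        sqrt(aitchison_sq_distance(m[p[1], ], m[p[2], ]))
      }))
    }, numeric(1))
    mean(ds)
  }
  d <- vapply(c(0.2, 1, 3), mean_pairwise, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("generated predators are the documented two-step construction", {
  sc <- tiny_scenario()
  X <- sc$lib$means
  # oracle: mixture in prey space, elementwise product, closure
  for (j in c(1, 7, nrow(sc$diets))) {
    mix <- as.vector(sc$diets[j, ] %*% X)
    y <- mix * sc$cc
    expect_equal(unname(sc$pred$sig[j, ]), y / sum(y), tolerance = 1e-12)
  }
  expect_simplex_rows(sc$pred$sig)
  # vertex diet with unit coefficients reproduces the prey mean exactly
  I <- nrow(X)
  vertex <- generate_predators(diag(I), sc$lib, rep(1, ncol(X)))
  expect_equal(unname(vertex$sig), unname(X), tolerance = 1e-12)
  # deterministic, and invariant to rescaling the coefficients
  again <- generate_predators(sc$diets, sc$lib, sc$cc)
  expect_identical(again$sig, sc$pred$sig)
  scaled <- generate_predators(sc$diets, sc$lib, 5 * sc$cc)
  expect_equal(scaled$sig, sc$pred$sig, tolerance = 1e-12)
  expect_error(generate_predators(sc$diets[, 1:2], sc$lib, sc$cc),
               "prey types")
})

test_that("packaged realistic diets are valid low-diversity fixtures", {
  m <- realistic_diet_fixture("mammal")
  f <- realistic_diet_fixture("fish")
  expect_identical(dim(m), c(4L, 7L))
  expect_identical(dim(f), c(4L, 28L))
  expect_simplex_rows(m, tol = 1e-12)
  expect_simplex_rows(f, tol = 1e-12)
  # low diversity: a dominant type and several (near-)zero components
  expect_true(all(apply(m, 1, max) >= 0.4))
  expect_true(all(rowSums(f == 0) >= 20))
})

test_that("simulate then fit recovers the generating parameters end to end", {
  sc <- tiny_scenario(I = 4, K = 10, seed = 31)
  fit <- fit_joint(sc$pred, sc$lib)
  expect_lt(max(abs(fit$diet - sc$truth)), 1e-8)
  expect_lt(max(abs(fit$cc - sc$cc)), 1e-8)
})
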