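test_that("zero and missing proportions are replaced by the small constant", {
  expect_equal(preprocess_signature(c(0.2, 0, 0.8), renormalize = FALSE),
               c(0.2, 0.005, 0.8))
  expect_equal(preprocess_signature(c(0.2, NA, 0.8), renormalize = FALSE),
               c(0.2, 0.005, 0.8))
  expect_equal(preprocess_signature(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(preprocess_signature(c(0.2, 0, 0.8), replacement = 0.01,
                                    renormalize = FALSE)[2], 0.01)
  expect_error(preprocess_signature(c(0, 0, NA)), "empty signature")
  expect_error(preprocess_signature(numeric(0)), "empty signature")
  expect_error(preprocess_signature(c(0.2, -0.1)), "negative")
  expect_error(preprocess_signature(c(0.5, 0.5), replacement = 0), "positive")
})

test_that("preprocessing closes signatures to exactly unit sum", {
  for (seed in 1:5) {
    set.seed(seed)
    raw <- 0.95 * closure(runif(10))
    raw[sample(10, 3)] <- 0
    out <- prepare_signature(raw)
    expect_length(out, 11L)
    expect_true(all(out > 0))
    expect_lt(abs(Reduce(`+`, as.list(out)) - 1), 1e-9)
  }
  expect_lt(abs(sum(prepare_signature(c(0, 0.5, 0.5))) - 1), 1e-9)
})

test_that("augmentation appends one minus the dietary subset sum", {
  out <- augment_signature(c(0.6, 0.35))
  expect_equal(out, c(0.6, 0.35, 0.05))
  # subset summing to exactly 1: augmentation slot gets the replacement
  # constant, then the vector is reclosed
  full <- augment_signature(c(0.4, 0.6))
  expect_equal(full[3], 0.005 / 1.005)
  expect_lt(abs(sum(full) - 1), 1e-12)
  expect_error(augment_signature(c(0.7, 0.5)), "exceed unity")
  expect_error(augment_signature(c(0.2, NA)), "non-missing")
})

test_that("a 31-fatty-acid dietary suite yields signatures of length 32", {
  set.seed(1)
  raw <- closure(runif(31)) * 0.96   # dietary subset carries 96% of mass
  out <- prepare_signature(raw)
  expect_length(out, 32L)
  expect_equal(unname(out[32]), 0.04)
})

test_that("augmentation mass comes from the pre-replacement sum", {
  # one zero slot: the augmentation slot must reflect the measured 0.9,
  # not the post-replacement 0.905
  out <- prepare_signature(c(0.4, 0, 0.5))
  expect_equal(unname(out[4]) * (0.9 + 0.005 + 0.1), 0.1)
})

test_that("geometric mean matches closed forms and a brute-force oracle", {
  expect_equal(geometric_mean(rep(0.25, 4)), 0.25)
  expect_equal(geometric_mean(c(0.1, 0.9)), sqrt(0.09))
  set.seed(42)
  x <- runif(20, 0.001, 1)
  expect_equal(geometric_mean(x), prod(x)^(1 / 20), tolerance = 1e-12)
  expect_error(geometric_mean(c(0.5, 0)), "positive")
})

test_that("squared Aitchison distance matches an independent clr oracle", {
  a <- c(0.1, 0.2, 0.3, 0.4)
  b <- c(0.4, 0.3, 0.2, 0.1)
  expect_equal(aitchison_sq_distance(a, b), oracle_aitchison_sq(a, b))
  expect_equal(aitchison_sq_distance(a, a), 0)
  expect_error(aitchison_sq_distance(a, b[1:3]), "length")
})

test_that("Aitchison distance is symmetric, scale invariant and
           permutation equivariant", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- runif(6, 0.01, 1)
    b <- runif(6, 0.01, 1)
    alpha <- runif(1, 0.1, 10)
    d <- aitchison_sq_distance(a, b)
    expect_gte(d, 0)
    expect_equal(aitchison_sq_distance(b, a), d)
    expect_equal(aitchison_sq_distance(alpha * a, b), d, tolerance = 1e-12)
    perm <- sample(6)
    expect_equal(aitchison_sq_distance(a[perm], b[perm]), d,
                 tolerance = 1e-12)
  }
  # proportional compositions are equal after closure
  expect_lt(aitchison_sq_distance(c(0.2, 0.3, 0.5), 2 * c(0.2, 0.3, 0.5)),
            1e-25)
})
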