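test_that("estimability threshold matches the degrees-of-freedom bound", {
  expect_identical(min_predators(32, 7), 2L)
  expect_identical(min_predators(42, 28), 3L)
  expect_identical(min_predators(10, 9), 9L)   # K = I + 1 gives K - 1
  expect_error(min_predators(7, 7), "underdetermined")
  expect_error(min_predators(5, 7), "underdetermined")
})

test_that("parameter counting reproduces the model bookkeeping", {
  expect_identical(count_parameters(210, 7, 32), 1291L)
  expect_identical(count_parameters(210, 28, 42), 5711L)
  expect_identical(count_parameters(4, 7, 32), 55L)
  expect_identical(count_parameters(4, 28, 42), 149L)
  expect_identical(count_parameters(1, 2, 3), 3L)
})

test_that("dof covering parameters is equivalent to the J threshold", {
  for (K in c(6, 11, 17, 32)) {
    for (I in c(2, 3, 5, K - 1)) {
      for (J in 1:12) {
        dof_ok <- J * (K - 1) >= count_parameters(J, I, K)
        expect_identical(dof_ok, J >= min_predators(K, I),
                         info = sprintf("J=%d I=%d K=%d", J, I, K))
      }
    }
  }
})

test_that("objective Q matches an explicit per-predator oracle", {
  sc <- tiny_scenario()
  set.seed(11)
  d <- matrix(rexp(nrow(sc$pred$sig) * 3), ncol = 3)
  d <- d / rowSums(d)
  cc <- runif(8, 0.3, 3)
  q <- objective_q(d, cc, sc$pred, sc$lib)
  expect_equal(q, oracle_q(d, cc, sc$pred$sig, sc$lib$means),
               tolerance = 1e-12)
  # zero at the generating parameters (truth expressed in predator space)
  expect_lt(objective_q(sc$truth, sc$cc, sc$pred, sc$lib), 1e-25)
  # invariant under predator reordering
  perm <- sample(nrow(sc$pred$sig))
  expect_equal(objective_q(d[perm, ], cc, sc$pred$sig[perm, ], sc$lib), q,
               tolerance = 1e-12)
})

test_that("joint fit recovers diets and coefficients from noise-free data", {
  sc <- tiny_scenario()
  fit <- fit_joint(sc$pred, sc$lib)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-20)
  expect_lt(max(abs(fit$diet - sc$truth)), 1e-8)
  expect_lt(max(abs(fit$cc - sc$cc)), 1e-8)
  # descent: the solution is no worse than the standard initial point
  q0 <- objective_q(matrix(1 / 3, nrow(sc$pred$sig), 3), rep(1, 8),
                    sc$pred, sc$lib)
  expect_lt(fit$objective, q0)
  # feasibility of the returned parameters
  expect_simplex_rows(fit$diet, tol = 1e-8)
  expect_true(all(fit$cc >= 0.02 - 1e-10))
  expect_lt(abs(sum(fit$cc) - 8), 1e-8)
})

test_that("generation in the model's own mixture equation is also recovered", {
  sc <- tiny_scenario()
  pred <- generate_predators(sc$diets, sc$lib, sc$cc, space = "predator")
  fit <- fit_joint(pred, sc$lib)
  expect_lt(max(abs(fit$diet - sc$diets)), 1e-8)
  expect_lt(max(abs(fit$cc - sc$cc)), 1e-8)
})

test_that("a single predator is refused: diets and coefficients confound", {
  sc <- tiny_scenario()
  one <- predator_sample(sc$pred$sig[1, , drop = FALSE])
  expect_error(fit_joint(one, sc$lib), "at least 2 predators")
})

test_that("samples below the estimability threshold name the minimum", {
  lib <- synth_prey_library(I = 9, K = 10, n_per_type = 3, seed = 2)
  cc <- random_cc(10, seed = 3)
  diets <- make_diet_grid(9, 1)[1:5, ]
  pred <- generate_predators(diets, lib, cc)
  expect_error(fit_joint(pred, lib), "at least 9 predators")
})

test_that("identical predator signatures trigger a confounding warning", {
  sc <- tiny_scenario()
  Y <- sc$pred$sig[rep(1L, 6L), ]
  rownames(Y) <- sprintf("p%d", 1:6)
  expect_warning(
    fit_joint(predator_sample(Y), sc$lib, fit_config(n_starts = 3)),
    "non-identifiable"
  )
})

test_that("conditioning on the true coefficients reproduces the joint fit", {
  sc <- tiny_scenario()
  fc <- fit_conditioned(sc$pred, sc$lib, sc$cc)
  expect_true(fc$converged)
  expect_lt(max(abs(fc$diet - sc$truth)), 1e-8)
  fj <- fit_joint(sc$pred, sc$lib)
  expect_lt(max(abs(fc$diet - fj$diet)), 1e-7)
})

test_that("conditioned estimation separates over predators", {
  sc <- tiny_scenario()
  sub <- predator_sample(sc$pred$sig[4:6, ])
  full <- fit_conditioned(sc$pred, sc$lib, sc$cc)
  part <- fit_conditioned(sub, sc$lib, sc$cc)
  expect_equal(unname(part$diet), unname(full$diet[4:6, ]), tolerance = 1e-9)
  expect_equal(unname(part$per_predator_q),
               unname(full$per_predator_q[4:6]), tolerance = 1e-12)
})

test_that("conditioning on wrong coefficients biases diet estimates", {
  sc <- tiny_scenario()
  wrong <- fit_conditioned(sc$pred, sc$lib, rep(1, 8))
  expect_gt(max(abs(wrong$diet - sc$truth)), 1e-3)
})

test_that("per-class summaries average diets with standard errors", {
  d <- rbind(c(1, 0), c(0, 1))
  s <- summarize_by_class(d, c("a", "a"))
  expect_equal(unname(s$mean["a", ]), c(0.5, 0.5))
  expect_equal(unname(s$se["a", ]), c(0.5, 0.5))
  # single-member class: mean is the row itself, SE reported as 0
  s1 <- summarize_by_class(d, c("a", "b"))
  expect_equal(unname(s1$mean["b", ]), c(0, 1))
  expect_equal(unname(s1$se["b", ]), c(0, 0))
  expect_equal(unname(s1$n), c(1L, 1L))
  # random matrix against a direct tapply oracle
  set.seed(9)
  dm <- matrix(rexp(40), 10, 4); dm <- dm / rowSums(dm)
  cl <- rep(c("x", "y"), each = 5)
  s2 <- summarize_by_class(dm, cl)
  for (g in c("x", "y")) {
    rows <- dm[cl == g, ]
    expect_equal(unname(s2$mean[g, ]), unname(colMeans(rows)))
    expect_equal(unname(s2$se[g, ]),
                 unname(apply(rows, 2, sd) / sqrt(5)), tolerance = 1e-12)
  }
  expect_simplex_rows(s2$mean, tol = 1e-12)
  # empty factor levels are dropped with a warning
  expect_warning(summarize_by_class(d, factor(c("a", "a"), c("a", "ghost"))),
                 "ghost")
})
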