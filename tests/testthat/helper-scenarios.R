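# Shared fixtures, built in code: a small but non-trivial recovery scenario
# (3 prey types, 8 fatty acids, the full 0.25 diet grid) and an independent
# centred-log-ratio implementation used as an oracle for distance and
# objective values.

tiny_scenario <- function(I = 3, K = 8, seed = 7, increment = 0.25,
                          separation = 1.2, n_per_type = 5) {
  lib <- synth_prey_library(I, K, n_per_type = n_per_type,
                            separation = separation, seed = seed)
  cc <- random_cc(K, seed = seed + 1)
  diets <- make_diet_grid(I, increment)
  rownames(diets) <- sprintf("p%03d", seq_len(nrow(diets)))
  pred <- generate_predators(diets, lib, cc, id = rownames(diets))
  list(lib = lib, cc = cc, diets = diets, pred = pred,
       truth = attr(pred, "diet_predator_space"))
}

# Independent clr: closure then log-ratios against the geometric mean,
# written without reusing any package internals.
oracle_clr <- function(x) {
  p <- x / sum(x)
  log(p) - sum(log(p)) / length(p)
}

oracle_aitchison_sq <- function(a, b) sum((oracle_clr(a) - oracle_clr(b))^2)

# Independent objective: explicit double loop over predators and fatty acids.
oracle_q <- function(diet, cc, Y, X) {
  total <- 0
  for (j in seq_len(nrow(Y))) {
    tm <- sweep(X, 2, cc, "*")
    tm <- tm / rowSums(tm)
    yhat <- as.vector(diet[j, ] %*% tm)
    total <- total + oracle_aitchison_sq(yhat, Y[j, ])
  }
  total
}

expect_simplex_rows <- function(m, tol = 1e-9) {
  expect_true(all(m >= 0))
  expect_lt(max(abs(rowSums(m) - 1)), tol)
}
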