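# Joint and conditioned estimation of diets and calibration coefficients.

#' Minimum predator sample size for joint estimability
#'
#' The predator signatures carry `J * (K - 1)` degrees of freedom while the
#' joint model has `J * (I - 1) + (K - 1)` free parameters, so all
#' parameters are estimable only when `J >= (K - 1) / (K - I)` (requiring
#' more fatty acids than prey types, `K > I`).
#'
#' @param K Number of fatty acid proportions per signature (including the
#'   augmentation component).
#' @param I Number of prey types.
#' @return Smallest integer `J` satisfying the bound.
#' @export
min_predators <- function(K, I) {
  if (I < 2) stop("a prey library needs at least 2 prey types")
  if (K <= I) {
    stop("model underdetermined: need more fatty acids than prey types")
  }
  as.integer(ceiling((K - 1) / (K - I)))
}

#' Free-parameter count of the joint model
#'
#' `J * (I - 1)` free diet proportions (each predator's diet sums to 1) plus
#' `K - 1` free calibration coefficients (one lost to the sum constraint).
#'
#' @param J Number of predators.
#' @param I Number of prey types.
#' @param K Number of fatty acid proportions per signature.
#' @return Integer parameter count.
#' @export
count_parameters <- function(J, I, K) {
  stopifnot(J >= 1, I >= 1, K >= 1)
  as.integer(J * (I - 1) + (K - 1))
}

#' Joint objective function Q
#'
#' The squared Aitchison distance between observed and modelled predator
#' signatures, summed over predators:
#' `Q = sum_j sum_k [log(yhat_jk / gm(yhat_j)) - log(y_jk / gm(y_j))]^2`,
#' where `yhat_j` is the mixture of calibration-transformed mean prey
#' signatures weighted by predator `j`'s diet proportions.
#'
#' @param diet J x I matrix (or length-I vector) of diet proportions.
#' @param cc Length-K vector of positive calibration coefficients.
#' @param predators A [predator_sample()] or J x K signature matrix.
#' @param mean_signatures A [prey_library()] or I x K matrix of mean prey
#'   signatures.
#' @return Non-negative scalar.
#' @export
objective_q <- function(diet, cc, predators, mean_signatures) {
  Y <- as_predator_matrix(predators)
  X <- as_mean_matrix(mean_signatures)
  if (is.null(dim(diet))) diet <- matrix(diet, nrow = nrow(Y), ncol = length(diet),
                                         byrow = TRUE)
  Yhat <- predict_predator(diet, to_predator_space(X, cc))
  if (any(Yhat <= 0)) stop("modelled proportions must be strictly positive")
  sum((clr_rows(Yhat) - clr_rows(Y))^2)
}

#' Fit configuration
#'
#' Optimization settings for [fit_joint()] and [fit_conditioned()].  The
#' defaults reproduce the published set-up: diets initialized at `1/I`,
#' coefficients at 1, coefficients bounded below by 0.02 and constrained to
#' sum to `K`.
#'
#' @param cc_lower_bound Lower bound on each calibration coefficient
#'   (default 0.02), bounding them away from zero.
#' @param cc_sum Sum constraint on the coefficients; `NULL` (default) means
#'   `K`, the number of fatty acids.
#' @param tol_grad Convergence tolerance on the projected first-order
#'   optimality measure (default 1e-12).
#' @param q_floor Objective value treated as the numerical floor; descent
#'   stops once `Q` falls below it.  The default `NULL` scales the floor
#'   with problem size as `J * K * (100 * .Machine$double.eps)^2`, the level
#'   below which accumulated rounding noise in the log-ratio residuals makes
#'   further descent meaningless.
#' @param maxit Maximum solver iterations (default 5000).
#' @param n_starts Number of optimization starts; starts beyond the first
#'   are drawn from random feasible points and used to diagnose
#'   non-identifiability (default 1).
#' @param seed Seed for the randomized starts (default 1).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(cc_lower_bound = 0.02, cc_sum = NULL,
                       tol_grad = 1e-12, q_floor = NULL,
                       maxit = 5000L, n_starts = 1L, seed = 1L) {
  stopifnot(tol_grad > 0, is.null(q_floor) || q_floor >= 0,
            maxit >= 1, n_starts >= 1, cc_lower_bound > 0)
  structure(list(cc_lower_bound = cc_lower_bound, cc_sum = cc_sum,
                 tol_grad = tol_grad, q_floor = q_floor,
                 maxit = as.integer(maxit), n_starts = as.integer(n_starts),
                 seed = as.integer(seed)),
            class = "fit_config")
}

check_fa_labels <- function(pred_fa, prey_fa) {
  if (!is.null(pred_fa) && !is.null(prey_fa) &&
      !identical(unname(pred_fa), unname(prey_fa))) {
    stop("fatty acid labels of predators and prey library differ ",
         "(same names in the same order are required)")
  }
}

#' Jointly estimate diet proportions and calibration coefficients
#'
#' Minimizes the objective [objective_q()] simultaneously over all predator
#' diets and a single set of calibration coefficients shared by all
#' predators, subject to each diet row lying on the simplex and the
#' coefficients satisfying `cc >= cc_lower_bound` and `sum(cc) = cc_sum`.
#' Requires more predators than the estimability threshold
#' [min_predators()]; with a single predator, diets and coefficients are
#' completely confounded and estimation is refused.
#'
#' With `n_starts > 1`, the default start (diets `1/I`, coefficients 1) is
#' supplemented by randomized feasible starts.  If several starts reach the
#' same objective but materially different parameters, a non-identifiability
#' warning is raised (this is the expected behaviour when the predator
#' signatures carry too few distinct diets).
#'
#' @inheritParams objective_q
#' @param predators A [predator_sample()] or J x K matrix.
#' @param library A [prey_library()] or I x K matrix of mean prey signatures.
#' @param config A [fit_config()].
#' @return An object of class `qfasa_fit` with elements `diet` (J x I
#'   matrix), `cc` (named length-K vector), `objective`, `converged`,
#'   `iterations`, `message`, `per_start` (one row per optimization start),
#'   `n_parameters`, `dof`, `min_J` and the echoed `config`.
#' @export
fit_joint <- function(predators, library, config = fit_config()) {
  Y <- as_predator_matrix(predators)
  X <- as_mean_matrix(library)
  if (inherits(predators, "predator_sample") && inherits(library, "prey_library")) {
    check_fa_labels(predators$fa, library$fa)
  }
  J <- nrow(Y); K <- ncol(Y); I <- nrow(X)
  if (ncol(X) != K) stop("prey and predator signatures differ in length")
  Jmin <- min_predators(K, I)
  if (J < Jmin) {
    stop(sprintf(paste0("joint estimation requires at least %d predators ",
                        "for K=%d fatty acids and I=%d prey types (got %d); ",
                        "diet proportions and calibration coefficients are ",
                        "confounded below this threshold"),
                 Jmin, K, I, J))
  }
  cc_sum <- if (is.null(config$cc_sum)) K else config$cc_sum
  lb <- config$cc_lower_bound

  starts <- list(list(diet = matrix(1 / I, J, I), cc = rep(cc_sum / K, K)))
  if (config$n_starts > 1L) {
    rs <- with_seed(config$seed, lapply(seq_len(config$n_starts - 1L), function(s) {
      d <- matrix(stats::rexp(J * I), J, I)
      list(diet = d / rowSums(d),
           cc = lb + (cc_sum - K * lb) * closure(stats::rexp(K)))
    }))
    starts <- c(starts, rs)
  }

  fits <- lapply(starts, function(st) {
    qj_solve(Y, X, diet0 = st$diet, cc0 = st$cc, fix_cc = FALSE,
             lb_cc = lb, cc_sum = cc_sum, tol_grad = config$tol_grad,
             maxit = config$maxit, q_floor = config$q_floor)
  })
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  best <- which.min(objs)
  fit <- fits[[best]]

  par_diff <- vapply(fits, function(f) {
    max(abs(f$diet - fit$diet), abs(f$cc - fit$cc))
  }, numeric(1))
  per_start <- data.frame(
    start = seq_along(fits),
    objective = objs,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    iterations = vapply(fits, `[[`, integer(1), "iterations"),
    max_diff_from_best = par_diff
  )
  ambiguous <- per_start$objective - fit$objective < 1e-10 &
    per_start$max_diff_from_best > 1e-4
  if (any(ambiguous)) {
    warning(paste0("multiple starts reach the same objective with different ",
                   "parameters: diets and calibration coefficients appear ",
                   "confounded (non-identifiable); the predator sample may ",
                   "carry too few distinct diets"), call. = FALSE)
  }

  dimnames(fit$diet) <- list(rownames(Y),
                             if (inherits(library, "prey_library"))
                               library$prey_types else rownames(X))
  names(fit$cc) <- colnames(Y)
  structure(
    list(diet = fit$diet, cc = fit$cc, objective = fit$objective,
         converged = fit$converged, iterations = fit$iterations,
         message = fit$message, grad_norm = fit$grad_norm,
         per_predator_q = rowSums(fit$residuals^2),
         per_start = per_start, mode = "joint",
         J = J, I = I, K = K,
         n_parameters = count_parameters(J, I, K),
         dof = as.integer(J * (K - 1)), min_J = Jmin,
         config = config),
    class = "qfasa_fit"
  )
}

#' Estimate diets with calibration coefficients held fixed
#'
#' Classical (conditioned) QFASA estimation in the predator space: each
#' predator's diet is estimated by minimizing its own squared Aitchison
#' distance with the calibration coefficients fixed at supplied values
#' (e.g. feeding-trial estimates).  Because the objective separates over
#' predators when the coefficients are fixed, the joint minimization
#' performed here is identical to fitting each predator independently.
#'
#' @inheritParams fit_joint
#' @param cc_fixed Length-K vector of positive calibration coefficients to
#'   condition on.
#' @return A `qfasa_fit` object (see [fit_joint()]) with `mode =
#'   "conditioned"`, the fixed `cc` echoed, and `per_predator_q` holding
#'   each predator's minimized distance.
#' @export
fit_conditioned <- function(predators, library, cc_fixed,
                            config = fit_config()) {
  Y <- as_predator_matrix(predators)
  X <- as_mean_matrix(library)
  if (inherits(predators, "predator_sample") && inherits(library, "prey_library")) {
    check_fa_labels(predators$fa, library$fa)
  }
  J <- nrow(Y); K <- ncol(Y); I <- nrow(X)
  cc_fixed <- as.numeric(cc_fixed)
  if (length(cc_fixed) != K) stop("cc_fixed must have one value per fatty acid")
  if (any(is.na(cc_fixed)) || any(cc_fixed <= 0)) {
    stop("calibration coefficients must be strictly positive")
  }
  if (K <= I) stop("model underdetermined: need more fatty acids than prey types")
  fit <- qj_solve(Y, X, cc0 = cc_fixed, fix_cc = TRUE,
                  tol_grad = config$tol_grad, maxit = config$maxit,
                  q_floor = config$q_floor)
  dimnames(fit$diet) <- list(rownames(Y),
                             if (inherits(library, "prey_library"))
                               library$prey_types else rownames(X))
  names(fit$cc) <- colnames(Y)
  structure(
    list(diet = fit$diet, cc = fit$cc, objective = fit$objective,
         converged = fit$converged, iterations = fit$iterations,
         message = fit$message, grad_norm = fit$grad_norm,
         per_predator_q = rowSums(fit$residuals^2),
         per_start = NULL, mode = "conditioned",
         J = J, I = I, K = K,
         n_parameters = as.integer(J * (I - 1)),
         dof = as.integer(J * (K - 1)), min_J = NA_integer_,
         config = config),
    class = "qfasa_fit"
  )
}

#' @export
print.qfasa_fit <- function(x, ...) {
  cat(sprintf("QFASA %s fit: J=%d predators, I=%d prey types, K=%d fatty acids\n",
              x$mode, x$J, x$I, x$K))
  cat(sprintf("  objective Q = %.6g  (%s after %d iterations)\n",
              x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  parameters = %d, data dof = %d%s\n", x$n_parameters, x$dof,
              if (is.na(x$min_J)) "" else sprintf(", minimum J = %d", x$min_J)))
  if (!is.null(x$per_start) && nrow(x$per_start) > 1L) {
    cat(sprintf("  multistart: %d starts, objective range [%.3g, %.3g]\n",
                nrow(x$per_start), min(x$per_start$objective),
                max(x$per_start$objective)))
  }
  invisible(x)
}

#' Per-class mean diets with standard errors
#'
#' Averages individual diet estimates within predator classes (e.g.
#' age--sex classes) and reports the standard error of the mean
#' (`sd / sqrt(n)`) per prey type.  Classes with a single member get a
#' standard error of 0 and are flagged by `n = 1`.
#'
#' @param diet J x I matrix of diet proportions (e.g. `fit$diet`).
#' @param classes Length-J vector of class labels.
#' @return A list of class `diet_class_summary` with `mean` (C x I, rows
#'   summing to 1), `se` (C x I) and `n` (members per class).
#' @export
summarize_by_class <- function(diet, classes) {
  diet <- as.matrix(diet)
  if (length(classes) != nrow(diet)) {
    stop("one class label is required per predator")
  }
  if (!is.factor(classes)) classes <- factor(classes)
  empty <- levels(classes)[table(classes) == 0]
  if (length(empty)) {
    warning("excluding empty classes: ", paste(empty, collapse = ", "))
    classes <- droplevels(classes)
  }
  n <- as.vector(table(classes))
  mean_diet <- rowsum(diet, classes) / n
  sq <- rowsum(diet^2, classes)
  var_diet <- (sq - n * mean_diet^2) / pmax(n - 1, 1)
  var_diet[var_diet < 0] <- 0
  se <- sqrt(var_diet) / sqrt(n)
  se[n == 1, ] <- 0
  names(n) <- rownames(mean_diet)
  structure(list(mean = mean_diet, se = se, n = n),
            class = "diet_class_summary")
}

#' @export
print.diet_class_summary <- function(x, digits = 3, ...) {
  cat("Per-class mean diet (standard errors in parentheses):\n")
  for (cl in rownames(x$mean)) {
    cat(sprintf("  %s (n=%d):\n", cl, x$n[[cl]]))
    line <- sprintf("    %s = %.*f (%.*f)", colnames(x$mean),
                    digits, x$mean[cl, ], digits, x$se[cl, ])
    cat(paste(line, collapse = "\n"), "\n")
  }
  invisible(x)
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
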