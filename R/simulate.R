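# Simulation machinery: diet grids, random calibration coefficients,
# synthetic prey libraries and noise-free predator signatures.  These
# generate validation inputs with known truth so that parameter recovery by
# the joint model can be measured exactly.

#' Enumerate a regular grid of diets on the simplex
#'
#' All diet vectors over `I` prey types whose components are multiples of
#' `increment`, in ascending lexicographic order.  The enumeration is done
#' in integer units of `g = 1/increment` so each grid row sums to exactly 1
#' by construction; the integer representation is attached as
#' `attr(, "units")`.  The grid has `choose(I + g - 1, g)` rows.
#'
#' @param I Number of prey types (at least 2).
#' @param increment Grid spacing; `1/increment` must be an integer.
#' @return Matrix with `I` columns, one diet per row, with attributes
#'   `units` (integer matrix) and `g` (units per whole).
#' @export
make_diet_grid <- function(I, increment) {
  if (I < 2) stop("a diet grid needs at least 2 prey types")
  g <- 1 / increment
  if (abs(g - round(g)) > 1e-9) {
    stop("1/increment must be an integer (e.g. increment 0.25, 0.1)")
  }
  g <- as.integer(round(g))
  units <- compositions_of(g, I)
  grid <- units / g
  attr(grid, "units") <- units
  attr(grid, "g") <- g
  grid
}

# All length-`parts` vectors of non-negative integers summing to `total`,
# ascending lexicographic order.  Memoized on (total, parts): subproblems
# repeat heavily across the recursion.
compositions_of <- function(total, parts, memo = new.env(parent = emptyenv())) {
  key <- paste(total, parts)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (parts == 1L) {
    matrix(as.integer(total), 1L, 1L)
  } else {
    do.call(rbind, lapply(0:total, function(first) {
      cbind(as.integer(first),
            compositions_of(total - first, parts - 1L, memo))
    }))
  }
  dimnames(out) <- NULL
  memo[[key]] <- out
  out
}

#' Draw random calibration coefficients
#'
#' Coefficients are sampled from a chi-square density with one degree of
#' freedom and scaled to sum to the number of fatty acids `K`.  Raw draws
#' below `lower_bound` are redrawn so that the generated truth lies strictly
#' inside the feasible region of the estimator (which bounds coefficients
#' below by the same constant); without the redraw the truth could sit on or
#' outside the boundary and recovery error would be bounded away from zero.
#'
#' @param K Number of fatty acids.
#' @param seed Optional seed; the global RNG state is restored afterwards.
#' @param lower_bound Feasibility bound (default 0.02).
#' @return Length-K positive vector summing to `K`.
#' @export
random_cc <- function(K, seed = NULL, lower_bound = 0.02) {
  if (K < 2) stop("at least 2 fatty acids are required")
  with_seed(seed, {
    repeat {
      x <- stats::rchisq(K, df = 1)
      for (tries in 1:1000) {
        low <- x < lower_bound
        if (!any(low)) break
        x[low] <- stats::rchisq(sum(low), df = 1)
      }
      x <- x * (K / sum(x))
      if (all(x >= lower_bound)) return(x)
    }
  })
}

#' Generate a synthetic prey library
#'
#' Stands in for real prey libraries (which are not distributed) while
#' emulating their dimensional structure: `I` prey types, signatures of
#' length `K` (the last slot playing the role of the augmentation
#' component), `n_per_type` specimens per type.  Per-type mean compositions
#' are built by perturbing a common lognormal baseline in log space by
#' `separation` times a standard normal draw, so the expected pairwise
#' Aitchison distance between type means grows with `separation`
#' (`separation = 0` collapses all types onto one mean -- the worst case
#' for estimation).  Specimens scatter around their type mean by a
#' logistic-normal perturbation with log-scale standard deviation
#' `within_sd`.
#'
#' @param I Number of prey types.
#' @param K Signature length (must exceed `I`).
#' @param n_per_type Specimens per prey type.
#' @param separation Between-type spread on the log scale (default 1).
#' @param seed Optional seed; global RNG state is restored.
#' @param within_sd Within-type log-scale standard deviation (default 0.25).
#' @param base_sd Log-scale spread of the baseline composition, controlling
#'   how uneven the average signature is (default 1.5, giving a few dominant
#'   and many trace fatty acids as in real libraries).
#' @return A [prey_library()].
#' @export
synth_prey_library <- function(I, K, n_per_type = 50, separation = 1,
                               seed = NULL, within_sd = 0.25, base_sd = 1.5) {
  if (K <= I) stop("need more fatty acids than prey types (K > I)")
  if (n_per_type < 1) stop("n_per_type must be at least 1")
  with_seed(seed, {
    base <- stats::rnorm(K, sd = base_sd)
    type_log <- matrix(base, I, K, byrow = TRUE) +
      separation * matrix(stats::rnorm(I * K), I, K)
    spec_log <- type_log[rep(seq_len(I), each = n_per_type), , drop = FALSE] +
      within_sd * matrix(stats::rnorm(I * n_per_type * K), I * n_per_type, K)
    sig <- close_rows(exp(spec_log))
    colnames(sig) <- c(sprintf("fa_%02d", seq_len(K - 1L)), "aug")
    types <- sprintf("prey_%02d", rep(seq_len(I), each = n_per_type))
    prey_library(sig, prey_type = types,
                 specimen_id = sprintf("%s_s%03d", types,
                                       rep(seq_len(n_per_type), times = I)))
  })
}

#' Construct noise-free predator signatures from known diets
#'
#' Follows the published construction: each predator signature is computed
#' in the prey space as a mixture of the mean prey signatures weighted by
#' the diet proportions, then mapped to the predator space with the
#' calibration coefficients (`space = "prey"`, the default).  With
#' `space = "predator"` the mixture is instead taken over the transformed
#' means, i.e. the model's own mixture equation.
#'
#' The two constructions describe the same signatures under diet weights
#' that differ by the prey-type scaling factors `sum_k(c_k * xbar_ik)` (see
#' [diet_prey_to_predator_space()]).  Because estimation is performed in the
#' predator space, the diets recovered by [fit_joint()] from prey-space
#' generated signatures equal `diet_prey_to_predator_space(diets, means,
#' cc)`; that re-expression is attached to the result as
#' `attr(, "diet_predator_space")`.
#'
#' @param diets J x I matrix (or list of vectors) of diet proportions.
#' @param library A [prey_library()] or I x K matrix of mean prey signatures.
#' @param cc Length-K positive calibration coefficients.
#' @param space Space in which the mixture is formed (see above).
#' @param id Optional predator identifiers.
#' @param class Optional class label per predator.
#' @return A [predator_sample()]; noise-free, deterministic in its inputs,
#'   and invariant to rescaling `cc`.
#' @export
generate_predators <- function(diets, library, cc,
                               space = c("prey", "predator"),
                               id = NULL, class = NULL) {
  space <- match.arg(space)
  X <- as_mean_matrix(library)
  if (is.list(diets)) diets <- do.call(rbind, diets)
  diets <- as.matrix(diets)
  if (ncol(diets) != nrow(X)) {
    stop("diet columns must match the number of prey types")
  }
  if (any(diets < 0) || any(abs(rowSums(diets) - 1) > 1e-9)) {
    stop("each diet must be non-negative and sum to 1")
  }
  cc <- as.numeric(cc)
  if (length(cc) != ncol(X)) stop("one calibration coefficient per fatty acid")
  Y <- if (space == "prey") {
    to_predator_space(diets %*% X, cc)
  } else {
    diets %*% to_predator_space(X, cc)
  }
  colnames(Y) <- colnames(X)
  out <- predator_sample(Y, id = id, class = class)
  attr(out, "diet_predator_space") <- if (space == "prey") {
    diet_prey_to_predator_space(diets, X, cc)
  } else {
    diets
  }
  out
}

#' Packaged low-diversity test diets
#'
#' Four diets per library configuration with the qualitative structure of
#' realistic marine-predator diets: one or two dominant prey types and
#' several near-zero contributions.  These are synthetic fixture values
#' shipped with the package for near-threshold (J = 4) stress tests of the
#' joint model; they are stand-ins, not published diet estimates.
#'
#' @param case `"mammal"` (I = 7 prey types, polar-bear-like) or `"fish"`
#'   (I = 28 prey types, gray-seal-like).
#' @return 4 x I matrix of diet proportions, rows summing to 1.
#' @export
realistic_diet_fixture <- function(case = c("mammal", "fish")) {
  case <- match.arg(case)
  if (case == "mammal") {
    prey <- c("bearded_seal", "beluga", "bowhead", "ribbon_seal",
              "ringed_seal", "spotted_seal", "walrus")
    d <- rbind(
      adult_female    = c(0.20, 0.02, 0.00, 0.01, 0.70, 0.02, 0.05),
      adult_male      = c(0.35, 0.05, 0.01, 0.00, 0.45, 0.04, 0.10),
      subadult_female = c(0.10, 0.01, 0.00, 0.03, 0.80, 0.06, 0.00),
      subadult_male   = c(0.15, 0.02, 0.01, 0.02, 0.72, 0.08, 0.00)
    )
    colnames(d) <- prey
  } else {
    I <- 28L
    prey <- sprintf("prey_%02d", seq_len(I))
    d <- matrix(0, 4L, I, dimnames = list(
      c("spring_female", "spring_male", "fall_female", "fall_male"), prey))
    # dominant sand-lance-like type plus a handful of minor contributors
    d["spring_female", c(1, 4, 9, 13, 20)] <- c(0.55, 0.20, 0.10, 0.10, 0.05)
    d["spring_male",   c(1, 4, 7, 13, 24)] <- c(0.45, 0.25, 0.05, 0.15, 0.10)
    d["fall_female",   c(2, 4, 9, 16, 20)] <- c(0.10, 0.50, 0.20, 0.15, 0.05)
    d["fall_male",     c(2, 4, 9, 11, 24)] <- c(0.15, 0.40, 0.25, 0.12, 0.08)
  }
  stopifnot(all(abs(rowSums(d) - 1) < 1e-12))
  d
}
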