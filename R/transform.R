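# Calibration-coefficient transforms between the prey and predator spaces,
# and the mixture prediction of predator signatures.
#
# Calibration coefficients c_k account for the differential metabolism of
# individual fatty acids.  Multiplying a prey composition elementwise by c
# and reclosing maps it to the predator space; dividing maps back.  Only the
# relative magnitudes of the coefficients matter (closure absorbs any common
# scale), which is why estimation constrains their sum.

#' Transform mean prey signatures to the predator space
#'
#' Each row `x` becomes `(c * x) / sum(c * x)`.  The mapping is invariant to
#' rescaling `cc` by any positive constant.
#'
#' @param mean_signatures I x K matrix of mean prey signatures (rows sum to
#'   1, strictly positive), or a single signature vector.
#' @param cc Positive numeric vector of K calibration coefficients.
#' @return Matrix (or vector) of transformed signatures, rows summing to 1.
#' @export
to_predator_space <- function(mean_signatures, cc) {
  transform_space(mean_signatures, cc, divide = FALSE)
}

#' Transform a predator signature to the prey space
#'
#' Elementwise division by the calibration coefficients followed by closure;
#' the inverse of [to_predator_space()].
#'
#' @param predator_signature Signature vector or matrix of signatures (rows).
#' @inheritParams to_predator_space
#' @return Signature(s) in the prey space.
#' @export
to_prey_space <- function(predator_signature, cc) {
  transform_space(predator_signature, cc, divide = TRUE)
}

transform_space <- function(x, cc, divide) {
  cc <- as.numeric(cc)
  if (any(is.na(cc)) || any(cc <= 0)) {
    stop("calibration coefficients must be strictly positive")
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), nrow = 1L,
                       dimnames = list(NULL, names(x))) else as.matrix(x)
  if (ncol(m) != length(cc)) {
    stop("calibration coefficients and signatures differ in length")
  }
  if (any(is.na(m)) || any(m <= 0)) stop("signatures must be strictly positive")
  t <- if (divide) sweep(m, 2L, cc, "/") else sweep(m, 2L, cc, "*")
  t <- close_rows(t)
  if (vec) t[1L, ] else t
}

#' Predict a predator signature from a diet
#'
#' Models predator signatures as a mixture of the transformed mean prey
#' signatures weighted by the diet proportions: `yhat = diet %*%
#' transformed_means`.  A convex combination of compositions, so the output
#' lies on the simplex.
#'
#' @param diet Length-I diet vector (proportions summing to 1) or J x I diet
#'   matrix.
#' @param transformed_means I x K matrix of prey mean signatures in the
#'   predator space (see [to_predator_space()]).
#' @return Predicted signature vector, or J x K matrix for a diet matrix.
#' @export
predict_predator <- function(diet, transformed_means) {
  tm <- as.matrix(transformed_means)
  vec <- is.null(dim(diet))
  d <- if (vec) matrix(as.numeric(diet), nrow = 1L) else as.matrix(diet)
  if (ncol(d) != nrow(tm)) {
    stop("diet length does not match the number of prey types")
  }
  if (any(d < 0) || any(abs(rowSums(d) - 1) > 1e-6)) {
    stop("diet proportions must be non-negative and sum to 1")
  }
  out <- d %*% tm
  rownames(out) <- rownames(d)
  if (vec) out[1L, ] else out
}

#' Rescale calibration coefficients to a fixed sum
#'
#' The transform between spaces is invariant to the overall scale of the
#' coefficients, so a sum constraint (conventionally `sum(cc) = K`) is used
#' to identify them.
#'
#' @param cc Positive numeric vector.
#' @param sum_to Target sum (default `length(cc)`).
#' @return Rescaled coefficients summing to `sum_to`.
#' @export
rescale_cc <- function(cc, sum_to = length(cc)) {
  if (any(cc <= 0)) stop("calibration coefficients must be strictly positive")
  cc * (sum_to / sum(cc))
}

#' Re-express diets between the prey and predator spaces
#'
#' A predator signature generated in the prey space as a mixture with
#' weights `pi` and then transformed to the predator space is *identical* to
#' a predator-space mixture of the transformed prey means with weights
#' proportional to `pi_i * sum_k(c_k * xbar_ik)`.  These functions convert
#' diet weights between the two parameterizations; they are exact algebraic
#' identities, not estimates.
#'
#' @param diet Diet vector or J x I matrix (prey-space weights for
#'   `diet_prey_to_predator_space`, predator-space weights for the inverse).
#' @param mean_signatures I x K matrix of prey means (prey space).
#' @inheritParams to_predator_space
#' @return Diet(s) of the same shape in the other parameterization.
#' @export
diet_prey_to_predator_space <- function(diet, mean_signatures, cc) {
  reweight_diet(diet, as.vector(as_mean_matrix(mean_signatures) %*% cc))
}

#' @rdname diet_prey_to_predator_space
#' @export
diet_predator_to_prey_space <- function(diet, mean_signatures, cc) {
  reweight_diet(diet, 1 / as.vector(as_mean_matrix(mean_signatures) %*% cc))
}

reweight_diet <- function(diet, w) {
  vec <- is.null(dim(diet))
  d <- if (vec) matrix(as.numeric(diet), nrow = 1L) else as.matrix(diet)
  if (ncol(d) != length(w)) stop("diet length does not match the prey library")
  out <- close_rows(sweep(d, 2L, w, "*"))
  dimnames(out) <- dimnames(d)
  if (vec) out[1L, ] else out
}
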