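# Compositional primitives for fatty acid signature analysis.
#
# A "signature" is a vector of fatty acid proportions that sums to 1.  All
# distance computations use the Aitchison geometry of the simplex, so every
# proportion must be strictly positive after preprocessing.

#' Close a positive vector to the unit simplex
#'
#' Divides a positive vector by its sum so the result sums to 1 (the closure
#' operation of compositional data analysis).
#'
#' @param x Numeric vector with non-negative entries and positive sum.
#' @return Numeric vector summing to 1.
#' @export
closure <- function(x) {
  if (!is.numeric(x) || any(x < 0) || sum(x) <= 0) {
    stop("closure requires a non-negative vector with positive sum")
  }
  x / sum(x)
}

close_rows <- function(m) m / rowSums(m)

#' Replace zero and missing proportions in a raw signature
#'
#' Fatty acid proportions equal to zero (or missing) are replaced by a small
#' positive constant so that log-ratio operations are defined, then the vector
#' is reclosed to sum to 1.  Set `renormalize = FALSE` to obtain the replaced
#' vector before closure (used internally by [prepare_signature()], where a
#' single closure is applied after augmentation).
#'
#' @param raw Numeric vector of proportions, possibly containing zeros or `NA`.
#' @param replacement Small positive constant substituted for zeros and
#'   missing values (default 0.005).
#' @param renormalize Reclose the result to sum to 1? Default `TRUE`.
#' @return Numeric vector with all entries strictly positive.
#' @export
preprocess_signature <- function(raw, replacement = 0.005, renormalize = TRUE) {
  if (!is.numeric(raw) && !all(is.na(raw))) stop("signature must be numeric")
  if (replacement <= 0) stop("replacement constant must be positive")
  raw <- as.numeric(raw)
  if (length(raw) == 0L || all(is.na(raw) | raw == 0)) stop("empty signature")
  if (any(raw < 0, na.rm = TRUE)) stop("negative proportions are not allowed")
  out <- raw
  out[is.na(out) | out == 0] <- replacement
  if (renormalize) out <- closure(out)
  out
}

#' Augment a dietary-subset signature to full length
#'
#' Appends an augmentation component equal to one minus the sum of the
#' dietary fatty acid proportions, so the augmented signature closes to 1.
#' A non-positive augmentation component (subset summing to exactly 1, or
#' overshooting by at most `tol`) is replaced by the zero-replacement
#' constant; the result is then reclosed.
#'
#' @param sig Numeric vector of dietary-subset proportions (sum at most 1).
#' @param replacement Constant substituted for a non-positive augmentation
#'   component (default 0.005).
#' @param tol Tolerated overshoot of the subset sum above 1 (default 1e-6,
#'   absorbing CSV rounding).
#' @param label Name for the appended component (default `"aug"`).
#' @return Numeric vector of length `length(sig) + 1` summing to 1.
#' @export
augment_signature <- function(sig, replacement = 0.005, tol = 1e-6,
                              label = "aug") {
  if (any(is.na(sig)) || any(sig < 0)) {
    stop("augmentation requires non-negative, non-missing proportions")
  }
  s <- sum(sig)
  if (s > 1 + tol) stop("proportions exceed unity")
  aug <- 1 - min(s, 1)
  if (aug <= 0) aug <- replacement
  out <- c(sig, aug)
  if (!is.null(names(sig))) names(out) <- c(names(sig), label)
  closure(out)
}

#' Prepare a raw signature for analysis
#'
#' Full preprocessing pipeline for one raw signature over the dietary fatty
#' acid subset: (1) zeros and missing values are replaced by `replacement`;
#' (2) the augmentation component is computed from the *original*
#' (pre-replacement) subset sum, missing values contributing zero mass;
#' (3) the full vector is closed to sum exactly 1.  Computing the
#' augmentation from the original sum keeps it faithful to the measured
#' mass; the single final closure guarantees positivity and unit sum.
#'
#' @inheritParams preprocess_signature
#' @param augment Append the augmentation component? Default `TRUE`.
#' @return Numeric vector of strictly positive proportions summing to 1
#'   (length `length(raw) + 1` when `augment = TRUE`).
#' @export
prepare_signature <- function(raw, replacement = 0.005, augment = TRUE) {
  raw <- as.numeric0(raw)
  if (length(raw) == 0L || all(is.na(raw) | raw == 0)) stop("empty signature")
  if (any(raw < 0, na.rm = TRUE)) stop("negative proportions are not allowed")
  repl <- preprocess_signature(raw, replacement, renormalize = FALSE)
  if (!augment) return(closure(repl))
  s <- sum(raw, na.rm = TRUE)
  if (s > 1 + 1e-6) stop("proportions exceed unity")
  aug <- 1 - min(s, 1)
  if (aug <= 0) aug <- replacement
  out <- c(repl, aug)
  if (!is.null(names(raw))) names(out) <- c(names(raw), "aug")
  closure(out)
}

as.numeric0 <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  x
}

#' Prepare a matrix of raw signatures row-wise
#'
#' @param m Numeric matrix, one raw signature per row.
#' @inheritParams prepare_signature
#' @return Matrix of prepared signatures (one extra column when augmenting).
#' @export
prepare_signatures <- function(m, replacement = 0.005, augment = TRUE) {
  m <- as.matrix(m)
  out <- t(apply(m, 1L, prepare_signature,
                 replacement = replacement, augment = augment))
  rownames(out) <- rownames(m)
  out
}

#' Geometric mean of a signature
#'
#' @param sig Numeric vector with strictly positive entries.
#' @return `exp(mean(log(sig)))`.
#' @export
geometric_mean <- function(sig) {
  if (any(is.na(sig)) || any(sig <= 0)) {
    stop("geometric mean requires strictly positive entries")
  }
  exp(mean(log(sig)))
}

#' Centred log-ratio transform
#'
#' @param sig Strictly positive numeric vector (closure-invariant: the input
#'   need not sum to 1).
#' @return `log(sig) - mean(log(sig))`.
#' @export
clr <- function(sig) {
  if (any(is.na(sig)) || any(sig <= 0)) {
    stop("clr requires strictly positive entries")
  }
  l <- log(sig)
  l - mean(l)
}

clr_rows <- function(m) {
  l <- log(m)
  l - rowMeans(l)
}

#' Squared Aitchison distance between two signatures
#'
#' The squared Euclidean distance between the centred log-ratio transforms
#' of two compositions; the inner (per-predator) term of the model's
#' objective function.  Scale invariant: inputs are closed before
#' transformation.
#'
#' @param a,b Strictly positive numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
aitchison_sq_distance <- function(a, b) {
  if (length(a) != length(b)) stop("signatures differ in length")
  sum((clr(a) - clr(b))^2)
}
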