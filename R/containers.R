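# Prey library and predator sample containers.

#' Build a prey library
#'
#' A prey library holds prey signatures grouped by prey type together with
#' the per-type mean signatures used for diet estimation.  Mean signatures
#' are the arithmetic mean of the (prepared) specimen signatures per fatty
#' acid, reclosed to sum to 1, following the original QFASA convention.
#'
#' @param signatures Numeric matrix of signatures, one specimen per row
#'   (columns are fatty acids), or a data frame whose non-signature columns
#'   are named in `prey_type`/`specimen_id`.
#' @param prey_type Character or factor of prey type labels, one per row.
#' @param specimen_id Optional specimen identifiers (default: row names or
#'   `spec_1 ...`).
#' @param prepare Run [prepare_signature()] on each row (zero replacement and
#'   augmentation)? Default `FALSE`: rows are assumed already prepared and
#'   are only validated.
#' @param replacement Zero-replacement constant when `prepare = TRUE`.
#' @return An object of class `prey_library` with elements `sig` (n x K
#'   matrix), `prey_type` (factor), `means` (I x K matrix of mean
#'   signatures), `prey_types` (ordered type names) and `fa` (fatty acid
#'   names).
#' @export
prey_library <- function(signatures, prey_type, specimen_id = NULL,
                         prepare = FALSE, replacement = 0.005) {
  sig <- as.matrix(signatures)
  storage.mode(sig) <- "double"
  if (prepare) sig <- prepare_signatures(sig, replacement = replacement)
  if (nrow(sig) != length(prey_type)) {
    stop("one prey type label is required per signature")
  }
  prey_type <- factor(prey_type, levels = unique(as.character(prey_type)))
  if (nlevels(prey_type) < 2L) stop("a prey library needs at least 2 prey types")
  if (is.null(specimen_id)) {
    specimen_id <- rownames(sig)
    if (is.null(specimen_id)) {
      specimen_id <- sprintf("spec_%d", seq_len(nrow(sig)))
    }
  }
  rownames(sig) <- specimen_id
  if (is.null(colnames(sig))) {
    colnames(sig) <- sprintf("fa_%02d", seq_len(ncol(sig)))
  }
  validate_signature_matrix(sig, "prey signature")
  means <- rowsum(sig, prey_type) / as.vector(table(prey_type))
  means <- close_rows(means)
  structure(
    list(sig = sig, prey_type = prey_type, means = means,
         prey_types = levels(prey_type), fa = colnames(sig)),
    class = "prey_library"
  )
}

#' @export
print.prey_library <- function(x, ...) {
  cat(sprintf("Prey library: %d signatures, %d prey types, %d fatty acids\n",
              nrow(x$sig), length(x$prey_types), ncol(x$sig)))
  counts <- table(x$prey_type)
  cat("  specimens per type: ",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

#' Build a predator sample
#'
#' @param signatures Numeric matrix of predator signatures (one per row),
#'   fatty acid columns in the same order as the associated prey library.
#' @param id Optional predator identifiers.
#' @param class Optional class label per predator (e.g. an age--sex class)
#'   used by [summarize_by_class()].
#' @inheritParams prey_library
#' @return An object of class `predator_sample` with elements `sig` (J x K
#'   matrix), `id`, `class` and `fa`.
#' @export
predator_sample <- function(signatures, id = NULL, class = NULL,
                            prepare = FALSE, replacement = 0.005) {
  sig <- as.matrix(signatures)
  storage.mode(sig) <- "double"
  if (prepare) sig <- prepare_signatures(sig, replacement = replacement)
  if (is.null(id)) {
    id <- rownames(sig)
    if (is.null(id)) id <- sprintf("pred_%d", seq_len(nrow(sig)))
  }
  rownames(sig) <- id
  if (is.null(colnames(sig))) {
    colnames(sig) <- sprintf("fa_%02d", seq_len(ncol(sig)))
  }
  if (!is.null(class) && length(class) != nrow(sig)) {
    stop("one class label is required per predator")
  }
  validate_signature_matrix(sig, "predator signature")
  structure(
    list(sig = sig, id = id, class = class, fa = colnames(sig)),
    class = "predator_sample"
  )
}

#' @export
print.predator_sample <- function(x, ...) {
  cat(sprintf("Predator sample: %d signatures, %d fatty acids\n",
              nrow(x$sig), ncol(x$sig)))
  if (!is.null(x$class)) {
    counts <- table(x$class)
    cat("  classes: ",
        paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

validate_signature_matrix <- function(sig, what, tol = 1e-9) {
  if (any(is.na(sig)) || any(sig <= 0)) {
    stop(sprintf("every %s must be strictly positive after preprocessing; %s",
                 what, "run with prepare = TRUE on raw data"))
  }
  bad <- abs(rowSums(sig) - 1) > tol
  if (any(bad)) {
    stop(sprintf("%s rows do not sum to 1 (max deviation %.3g): %s",
                 what, max(abs(rowSums(sig) - 1)),
                 paste(utils::head(which(bad)), collapse = ", ")))
  }
  invisible(sig)
}

as_mean_matrix <- function(library) {
  if (inherits(library, "prey_library")) return(library$means)
  m <- as.matrix(library)
  validate_signature_matrix(m, "mean prey signature")
  m
}

as_predator_matrix <- function(predators) {
  if (inherits(predators, "predator_sample")) return(predators$sig)
  m <- as.matrix(predators)
  validate_signature_matrix(m, "predator signature")
  m
}
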