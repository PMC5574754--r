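# CSV interfaces.  Doubles are written at 17 significant digits and parsed
# back with strtod (base read.csv), which reproduces every value exactly;
# this keeps all CSV artifacts round-trip safe at full double precision.
#
# Layouts:
#   prey:      prey_type, specimen_id, <fa_1>, ..., [aug]
#   predators: predator_id, [class], <fa_1>, ..., [aug]
#   cc:        fatty_acid, coefficient
#   diets:     predator_id, <prey type 1>, ..., <prey type I>
#
# Signature files written by this package include the augmentation column
# ("aug") and are read back as-is; raw signature files without it hold the
# dietary subset only and are preprocessed (zero replacement, augmentation)
# on read.

# Write a data frame with doubles rendered at 17 significant digits, the
# precision at which text -> double parsing is guaranteed to reproduce the
# original value exactly.
write_csv_full <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_plain <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

read_signature_table <- function(path, id_cols, replacement = 0.005) {
  df <- read_csv_plain(path)
  missing_cols <- setdiff(id_cols$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  meta_cols <- intersect(c(id_cols$required, id_cols$optional), names(df))
  fa_cols <- setdiff(names(df), meta_cols)
  if (!length(fa_cols)) stop(sprintf("%s: no fatty acid columns found", path))
  sig <- as.matrix(df[fa_cols])
  if (!is.numeric(sig)) {
    stop(sprintf("%s: fatty acid columns must be numeric", path))
  }
  prepared <- "aug" %in% fa_cols
  if (!prepared) {
    sig <- prepare_signatures(sig, replacement = replacement)
  }
  list(meta = df[meta_cols], sig = sig, prepared = prepared)
}

#' Read a prey signature CSV
#'
#' Requires columns `prey_type` and `specimen_id`; every remaining column is
#' a fatty acid proportion.  Files without an `aug` column are treated as
#' raw dietary-subset signatures and preprocessed (zeros and missing values
#' replaced by `replacement`, augmentation component appended, closure).
#'
#' @param path CSV file path.
#' @param replacement Zero-replacement constant (default 0.005).
#' @return A [prey_library()].
#' @export
read_prey_csv <- function(path, replacement = 0.005) {
  tab <- read_signature_table(path, list(required = c("prey_type", "specimen_id"),
                                         optional = character()),
                              replacement)
  prey_library(tab$sig, prey_type = tab$meta$prey_type,
               specimen_id = tab$meta$specimen_id)
}

#' Write a prey library to CSV
#'
#' @param library A [prey_library()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prey_csv <- function(library, path) {
  df <- data.frame(prey_type = as.character(library$prey_type),
                   specimen_id = rownames(library$sig),
                   library$sig, check.names = FALSE)
  write_csv_full(df, path)
  invisible(path)
}

#' Read a predator signature CSV
#'
#' Requires a `predator_id` column; an optional `class` column carries
#' age--sex (or other) class labels.  Fatty acid columns as in
#' [read_prey_csv()].
#'
#' @inheritParams read_prey_csv
#' @param fa Optional fatty acid names to check against (e.g. from the prey
#'   library); an error is raised unless the file's fatty acid columns match
#'   in the same order.
#' @return A [predator_sample()].
#' @export
read_predator_csv <- function(path, replacement = 0.005, fa = NULL) {
  tab <- read_signature_table(path, list(required = "predator_id",
                                         optional = "class"),
                              replacement)
  if (!is.null(fa)) check_fa_labels(colnames(tab$sig), fa)
  predator_sample(tab$sig, id = tab$meta$predator_id,
                  class = tab$meta$class)
}

#' Write a predator sample to CSV
#'
#' @param predators A [predator_sample()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predator_csv <- function(predators, path) {
  df <- data.frame(predator_id = rownames(predators$sig))
  if (!is.null(predators$class)) df$class <- predators$class
  df <- cbind(df, as.data.frame(predators$sig, check.names = FALSE))
  write_csv_full(df, path)
  invisible(path)
}

#' Read and write calibration coefficient CSVs
#'
#' Two columns: `fatty_acid` and `coefficient`.  Values round-trip at full
#' double precision.
#'
#' @param path CSV file path.
#' @return `read_cc_csv`: named numeric vector of coefficients.
#' @export
read_cc_csv <- function(path) {
  df <- read_csv_plain(path)
  if (!all(c("fatty_acid", "coefficient") %in% names(df))) {
    stop(sprintf("%s: expected columns fatty_acid, coefficient", path))
  }
  stats::setNames(as.numeric(df$coefficient), df$fatty_acid)
}

#' @rdname read_cc_csv
#' @param cc Named (or unnamed) positive coefficient vector.
#' @export
write_cc_csv <- function(cc, path) {
  nm <- names(cc)
  if (is.null(nm)) nm <- sprintf("fa_%02d", seq_along(cc))
  write_csv_full(data.frame(fatty_acid = nm, coefficient = as.numeric(cc)),
                 path)
  invisible(path)
}

#' Read and write diet matrix CSVs
#'
#' A `predator_id` column followed by one column per prey type.
#'
#' @param path CSV file path.
#' @return `read_diets_csv`: numeric matrix with predator ids as row names.
#' @export
read_diets_csv <- function(path) {
  df <- read_csv_plain(path)
  if (!"predator_id" %in% names(df)) {
    stop(sprintf("%s: expected a predator_id column", path))
  }
  m <- as.matrix(df[setdiff(names(df), "predator_id")])
  rownames(m) <- df$predator_id
  m
}

#' @rdname read_diets_csv
#' @param diet J x I diet matrix (row names taken as predator ids).
#' @export
write_diets_csv <- function(diet, path) {
  diet <- as.matrix(diet)
  ids <- rownames(diet)
  if (is.null(ids)) ids <- sprintf("pred_%d", seq_len(nrow(diet)))
  df <- data.frame(predator_id = ids, diet, check.names = FALSE)
  write_csv_full(df, path)
  invisible(path)
}

#' Compare estimated parameters against known truth
#'
#' Computes signed errors (estimate minus truth) for the diet and
#' calibration-coefficient blocks of a fit, with the maximum absolute error
#' per block and overall -- the error summaries used to validate parameter
#' recovery on generated data.
#'
#' @param estimates,truth Lists with elements `diet` (J x I matrix) and/or
#'   `cc` (length-K vector); blocks present in both are compared.
#' @return An object of class `qfasa_eval`: per-block `errors`, `max_abs`,
#'   `bias` (mean signed error), and the overall `max_abs`.
#' @export
evaluate_against_truth <- function(estimates, truth) {
  blocks <- intersect(intersect(names(estimates), names(truth)),
                      c("diet", "cc"))
  if (!length(blocks)) stop("no comparable blocks (diet, cc) in inputs")
  out <- lapply(blocks, function(b) {
    est <- estimates[[b]]; tru <- truth[[b]]
    if (!identical(dim(est), dim(tru)) || length(est) != length(tru)) {
      stop(sprintf("dimension mismatch in block '%s'", b))
    }
    err <- unname(est - tru)
    list(errors = err, max_abs = max(abs(err)), bias = mean(err))
  })
  names(out) <- blocks
  structure(c(out, list(max_abs = max(vapply(out, `[[`, numeric(1),
                                             "max_abs")))),
            class = "qfasa_eval")
}

#' @export
print.qfasa_eval <- function(x, ...) {
  cat("Parameter recovery versus truth:\n")
  for (b in intersect(c("diet", "cc"), names(x))) {
    cat(sprintf("  %s: max |error| = %.3g, mean signed error = %.3g\n",
                b, x[[b]]$max_abs, x[[b]]$bias))
  }
  cat(sprintf("  overall max |error| = %.3g\n", x$max_abs))
  invisible(x)
}
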