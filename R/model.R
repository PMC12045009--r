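#' deconsize: cell-size-aware reference-based deconvolution
#'
#' Bulk RNA-seq deconvolution estimates the cell-type composition of a
#' heterogeneous tissue sample from cell-type-specific expression profiles.
#' When cell types differ in size (mRNA content), the standard linear model
#' \eqn{Y = Z P} recovers the fraction of RNA attributable to each type, not
#' the fraction of cells.  This package implements the corrected model
#' \eqn{Y = Z S P}, where \eqn{S = diag(s)} holds per-type size factors, so
#' that solving against the rescaled signature \eqn{Z' = Z S} yields cell
#' fractions.  See \code{vignette("size-aware-deconvolution")}.
#'
#' @name deconsize-package
#' @aliases deconsize
#' @keywords internal
"_PACKAGE"

# ---- constructors & validators ---------------------------------------------

#' Construct a bulk expression matrix
#'
#' A bulk matrix holds nonnegative expression values for G genes (rows) by
#' J samples (columns).  Gene and sample identifiers must be unique; all
#' downstream operations align by these labels, never by position.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @return the validated matrix with class \code{"bulk_matrix"}.
#' @export
bulk_matrix <- function(values) {
  values <- as.matrix(values)
  .check_labelled(values, "bulk_matrix", "gene", "sample")
  if (any(values < 0)) stop("bulk_matrix: negative entries are not allowed")
  structure(values, class = c("bulk_matrix", class(values)))
}

#' Construct a cell-type signature (reference) matrix
#'
#' The signature matrix Z holds per-type mean expression for G genes (rows)
#' by K cell types (columns).  The \code{scaled} attribute records whether
#' cell-size rescaling (Z' = Z S) has already been applied, so it cannot
#' happen twice silently.
#'
#' @param values numeric matrix, genes x cell types, labelled on both
#'   dimensions.
#' @param scaled logical; has size rescaling been applied?
#' @return matrix with class \code{"cell_type_reference"} and attribute
#'   \code{scaled}.
#' @export
cell_type_reference <- function(values, scaled = FALSE) {
  values <- as.matrix(values)
  .check_labelled(values, "cell_type_reference", "gene", "cell type")
  if (ncol(values) < 2L)
    stop("cell_type_reference: need at least 2 cell types, got ", ncol(values))
  if (any(values < 0))
    stop("cell_type_reference: negative entries are not allowed")
  zero_cols <- colSums(values > 0) == 0L
  if (any(zero_cols))
    stop("cell_type_reference: all-zero column(s): ",
         paste(colnames(values)[zero_cols], collapse = ", "))
  structure(values, scaled = isTRUE(scaled),
            class = c("cell_type_reference", class(values)))
}

#' Construct a set of per-cell-type size scale factors
#'
#' The vector s of relative cell sizes, one strictly positive factor per
#' cell-type label.  Applied to a reference as the diagonal matrix
#' S = diag(s), i.e. Z' = Z S.
#'
#' @param x named numeric vector (names = cell-type labels) or a
#'   \code{scale_factor_table} from the estimation functions.
#' @return named numeric vector with class \code{"cell_scale_factors"}.
#' @export
cell_scale_factors <- function(x) {
  if (inherits(x, "scale_factor_table"))
    x <- stats::setNames(x$factor, x$cell_type)
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x)))
    stop("cell_scale_factors: factors must have unique non-empty cell-type names")
  x <- stats::setNames(as.numeric(x), names(x))
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("cell_scale_factors: non-positive or non-finite factor for: ",
         paste(names(x)[bad], collapse = ", "))
  structure(x, class = "cell_scale_factors")
}

#' Construct a cell-type proportion matrix
#'
#' P holds proportions for K cell types (rows) by J samples (columns).
#' Every column must lie on the probability simplex (entries >= 0, summing
#' to 1 within \code{tol}); renormalization is never implicit.
#'
#' @param values numeric matrix, cell types x samples, labelled.
#' @param tol simplex tolerance on column sums (default 1e-9).
#' @return matrix with class \code{"proportion_matrix"}.
#' @export
proportion_matrix <- function(values, tol = 1e-9) {
  values <- as.matrix(values)
  .check_labelled(values, "proportion_matrix", "cell type", "sample")
  if (any(values < 0))
    stop("proportion_matrix: negative proportions are not allowed")
  cs <- colSums(values)
  off <- abs(cs - 1) > tol
  if (any(off))
    stop("proportion_matrix: column(s) not on the simplex (|sum-1| > ", tol,
         "): ", paste(colnames(values)[off], collapse = ", "))
  structure(values, class = c("proportion_matrix", class(values)))
}

#' Construct a single-cell dataset
#'
#' Counts (genes x cells, nonnegative integers) plus per-cell annotations.
#' Annotation rows correspond one-to-one, in order, with count columns.
#'
#' @param counts integer matrix or Matrix sparse matrix, genes x cells,
#'   with gene rownames.
#' @param cell_type character vector of cell-type labels, one per cell.
#' @param sample_id character vector of sample/donor ids, one per cell
#'   (optional; defaults to a single pseudo-sample).
#' @param cell_id cell identifiers; default taken from counts colnames or
#'   generated.
#' @return list with elements \code{counts} and \code{cells} (a data.frame
#'   of cell_id, cell_type, sample_id), class \code{"single_cell_dataset"}.
#' @export
single_cell_dataset <- function(counts, cell_type, sample_id = NULL,
                                cell_id = NULL) {
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stop("single_cell_dataset: counts need unique gene rownames")
  n <- ncol(counts)
  if (is.null(cell_id)) {
    cell_id <- colnames(counts)
    if (is.null(cell_id)) cell_id <- sprintf("cell%d", seq_len(n))
  }
  cell_type <- as.character(cell_type)
  if (length(cell_type) != n)
    stop("single_cell_dataset: ", length(cell_type), " cell_type labels for ",
         n, " cells")
  if (any(is.na(cell_type) | !nzchar(cell_type)))
    stop("single_cell_dataset: every cell needs a non-empty cell_type label")
  if (is.null(sample_id)) sample_id <- rep("sample1", n)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != n)
    stop("single_cell_dataset: sample_id length mismatch")
  vals <- if (inherits(counts, "Matrix")) counts@x else counts
  if (length(vals) && (any(vals < 0) || any(vals != round(vals))))
    stop("single_cell_dataset: counts must be nonnegative integers")
  structure(list(
    counts = counts,
    cells  = data.frame(cell_id = as.character(cell_id),
                        cell_type = cell_type,
                        sample_id = sample_id,
                        stringsAsFactors = FALSE)
  ), class = "single_cell_dataset")
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat("single_cell_dataset:", nrow(x$counts), "genes x", ncol(x$counts),
      "cells;", length(unique(x$cells$cell_type)), "cell types;",
      length(unique(x$cells$sample_id)), "sample(s)\n")
  invisible(x)
}

.check_labelled <- function(m, what, rowlab, collab) {
  if (!is.numeric(m)) stop(what, ": values must be numeric")
  if (nrow(m) < 1L || ncol(m) < 1L) stop(what, ": empty matrix")
  if (is.null(rownames(m)) || any(!nzchar(rownames(m))))
    stop(what, ": missing ", rowlab, " identifiers (rownames)")
  if (is.null(colnames(m)) || any(!nzchar(colnames(m))))
    stop(what, ": missing ", collab, " identifiers (colnames)")
  if (anyDuplicated(rownames(m)))
    stop(what, ": duplicated ", rowlab, " identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop(what, ": duplicated ", collab, " identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  invisible(TRUE)
}

is_scaled <- function(reference) isTRUE(attr(reference, "scaled"))

# ---- operations -------------------------------------------------------------

#' Rescale a signature matrix by cell-size factors (Z' = Z S)
#'
#' Multiplies column k of the reference by the size factor of cell type k.
#' This is the core size correction: deconvolving against Z' yields cell
#' fractions instead of RNA fractions.  Rescaling an already-scaled
#' reference is refused unless \code{force = TRUE}, because the correction
#' is applied exactly once per experiment arm.
#'
#' @param reference a \code{\link{cell_type_reference}}.
#' @param factors a \code{\link{cell_scale_factors}} (or named vector /
#'   \code{scale_factor_table}) covering every cell type in the reference.
#' @param force allow rescaling a reference whose \code{scaled} flag is
#'   already set.
#' @return a \code{cell_type_reference} with \code{scaled = TRUE}; gene and
#'   type ordering preserved.
#' @examples
#' z <- cell_type_reference(matrix(c(2, 4, 1, 3), 2,
#'        dimnames = list(c("g1", "g2"), c("A", "B"))))
#' rescale_reference(z, cell_scale_factors(c(A = 3, B = 1)))
#' @export
rescale_reference <- function(reference, factors, force = FALSE) {
  stopifnot(inherits(reference, "cell_type_reference"))
  factors <- cell_scale_factors(factors)
  if (is_scaled(reference) && !force)
    stop("rescale_reference: reference is already scaled; ",
         "pass force = TRUE to rescale deliberately")
  types <- colnames(reference)
  missing <- setdiff(types, names(factors))
  if (length(missing))
    stop("rescale_reference: no scale factor for cell type(s): ",
         paste(missing, collapse = ", "))
  s <- as.numeric(factors[types])
  out <- unclass(reference)
  attr(out, "scaled") <- NULL
  out <- sweep(out, 2L, s, `*`)
  cell_type_reference(out, scaled = TRUE)
}

#' Collapse fine cell-type labels to broad labels
#'
#' Relabels cells according to \code{label_map} (fine label -> broad label),
#' e.g. collapsing excitatory/inhibitory neurons and the glial subtypes to
#' a k = 2 neuron/glial scheme.  Counts are untouched; only annotations
#' change.  Fine labels absent from the map are an error unless
#' \code{drop_unmapped = TRUE}, in which case those cells are removed.
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param label_map named character vector: names are fine labels, values
#'   broad labels.
#' @param drop_unmapped drop cells whose label is not in the map instead of
#'   erroring.
#' @return a \code{single_cell_dataset} with broad labels.
#' @export
aggregate_cell_types <- function(dataset, label_map, drop_unmapped = FALSE) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  label_map <- unlist(label_map)
  fine <- dataset$cells$cell_type
  unmapped <- setdiff(unique(fine), names(label_map))
  keep <- rep(TRUE, length(fine))
  if (length(unmapped)) {
    if (!drop_unmapped)
      stop("aggregate_cell_types: unmapped label(s): ",
           paste(unmapped, collapse = ", "),
           " (set drop_unmapped = TRUE to drop these cells)")
    keep <- fine %in% names(label_map)
  }
  counts <- dataset$counts[, keep, drop = FALSE]
  cells <- dataset$cells[keep, , drop = FALSE]
  single_cell_dataset(counts,
                      cell_type = unname(label_map[cells$cell_type]),
                      sample_id = cells$sample_id,
                      cell_id   = cells$cell_id)
}

#' Known cell-type proportions from single-cell annotations
#'
#' The "ground truth" composition: entry (k, j) is the fraction of cells in
#' sample j annotated as type k.  With \code{by_sample = FALSE} all cells
#' are pooled into one column.
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param by_sample compute one column per sample id (default) or pool.
#' @return a \code{\link{proportion_matrix}} (cell types x samples).
#' @export
compute_known_proportions <- function(dataset, by_sample = TRUE) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  cells <- dataset$cells
  samp <- if (by_sample) cells$sample_id else rep("all", nrow(cells))
  tab <- table(factor(cells$cell_type), factor(samp))
  totals <- colSums(tab)
  if (any(totals == 0))
    stop("compute_known_proportions: sample(s) with zero cells: ",
         paste(colnames(tab)[totals == 0], collapse = ", "))
  p <- sweep(unclass(tab), 2L, totals, `/`)
  proportion_matrix(matrix(p, nrow = nrow(tab),
                           dimnames = list(rownames(tab), colnames(tab))))
}
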