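# Signature-matrix construction from single-cell data, and cell-size
# scale-factor estimation from expression or imaging evidence.

#' Build a cell-type signature matrix from single-cell data
#'
#' Column k is the per-gene arithmetic mean of counts over the cells of
#' type k, optionally restricted to a marker gene set.  Means of raw
#' counts are the default; pass pre-normalized expression in the dataset
#' if a normalized reference is wanted (both count- and TPM-based
#' references are used in practice).
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param markers a \code{marker_set}, character vector of genes, or NULL
#'   for all genes.
#' @return a \code{\link{cell_type_reference}} (unscaled).
#' @export
build_reference <- function(dataset, markers = NULL) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  means <- type_means(dataset)
  if (!is.null(markers)) {
    genes <- if (inherits(markers, "marker_set")) marker_genes(markers)
             else as.character(markers)
    missing <- setdiff(genes, rownames(means))
    if (length(missing))
      stop("build_reference: marker gene(s) absent from dataset: ",
           paste(missing, collapse = ", "))
    means <- means[genes, , drop = FALSE]
  }
  cell_type_reference(means, scaled = FALSE)
}

.new_sft <- function(cell_type, factor, method, n_cells, source = method) {
  structure(data.frame(cell_type = cell_type, factor = as.numeric(factor),
                       source = source, method = method,
                       n_cells = as.integer(n_cells),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("scale_factor_table", "data.frame"))
}

#' Estimate cell-size factors from per-cell library sizes
#'
#' A cell type's mRNA content is proxied by the total counts its cells
#' carry over a gene set (all genes or a marker panel).  The per-type
#' summary is the median per-cell total (robust; mean available).  With
#' \code{normalize_min_to_one} the factors are divided by their minimum so
#' the smallest type has factor 1; pairwise ratios are unchanged.
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param markers marker set / gene vector / NULL for all genes.
#' @param normalize_min_to_one rescale so min factor is exactly 1.
#' @param statistic per-type summary of per-cell totals.
#' @return a \code{scale_factor_table} with method "library_sum".
#' @export
estimate_scale_factors_from_library_sizes <- function(dataset, markers = NULL,
    normalize_min_to_one = FALSE, statistic = c("median", "mean")) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  statistic <- match.arg(statistic)
  counts <- dataset$counts
  if (!is.null(markers)) {
    genes <- if (inherits(markers, "marker_set")) marker_genes(markers)
             else as.character(markers)
    missing <- setdiff(genes, rownames(counts))
    if (length(missing))
      stop("estimate_scale_factors_from_library_sizes: gene(s) absent: ",
           paste(missing, collapse = ", "))
    counts <- counts[genes, , drop = FALSE]
  }
  totals <- as.numeric(Matrix::colSums(counts))
  types <- sort(unique(dataset$cells$cell_type))
  stat_fun <- if (statistic == "median") stats::median else mean
  est <- vapply(types, function(k) {
    tk <- totals[dataset$cells$cell_type == k]
    if (all(tk == 0))
      stop("estimate_scale_factors_from_library_sizes: all-zero totals for ",
           "type '", k, "'")
    stat_fun(tk)
  }, numeric(1L))
  n <- vapply(types, function(k) sum(dataset$cells$cell_type == k),
              integer(1L))
  if (normalize_min_to_one) est <- est / min(est)
  .new_sft(types, est, "library_sum", n)
}

#' Estimate cell-size factors from imaging measurements
#'
#' Per-cell imaging rows (nucleus area, marker puncta copies) are filtered
#' to remove out-of-focus cells (nucleus area above
#' \code{max_nucleus_area}, default 78 in the micron-based units of the
#' input), then summarized per cell type by the median of the chosen size
#' variable.
#'
#' @param table a \code{measurement_table} (see
#'   \code{\link{read_measurements}}) or data.frame with cell_type,
#'   nucleus_area and optionally marker_copies columns.
#' @param max_nucleus_area exclusion threshold on nucleus_area.
#' @param variable size proxy: "nucleus_area" or "marker_copies".
#' @param statistic per-type summary (median default).
#' @return a \code{scale_factor_table} with method "nucleus_area" or
#'   "marker_copies"; attribute \code{filter_log} records removed rows per
#'   type.
#' @export
estimate_scale_factors_from_measurements <- function(table,
    max_nucleus_area = 78, variable = c("nucleus_area", "marker_copies"),
    statistic = c("median", "mean")) {
  variable <- match.arg(variable)
  statistic <- match.arg(statistic)
  stopifnot(nrow(table) > 0L, max_nucleus_area > 0)
  if (!variable %in% names(table))
    stop("estimate_scale_factors_from_measurements: column '", variable,
         "' absent")
  keep <- table$nucleus_area <= max_nucleus_area
  types <- sort(unique(table$cell_type))
  log <- data.frame(cell_type = types,
                    n_total = vapply(types, function(k)
                      sum(table$cell_type == k), integer(1L)),
                    n_removed = vapply(types, function(k)
                      sum(!keep & table$cell_type == k), integer(1L)),
                    row.names = NULL)
  gone <- log$cell_type[log$n_total == log$n_removed]
  if (length(gone))
    stop("estimate_scale_factors_from_measurements: no rows survive the ",
         "nucleus-area filter for type(s): ", paste(gone, collapse = ", "))
  kept <- table[keep, , drop = FALSE]
  stat_fun <- if (statistic == "median") stats::median else mean
  est <- vapply(types, function(k)
    stat_fun(kept[[variable]][kept$cell_type == k]), numeric(1L))
  if (any(est <= 0))
    stop("estimate_scale_factors_from_measurements: non-positive size ",
         "estimate for type(s): ", paste(types[est <= 0], collapse = ", "))
  out <- .new_sft(types, est, variable,
                  log$n_total - log$n_removed)
  attr(out, "filter_log") <- log
  out
}

#' Manually specified cell-size factors
#'
#' Wraps user-chosen factors (e.g. 10 for neurons and 3 for glia, a ratio
#' of about 3.33 that sits between expression-derived and previously
#' published estimates for cortex) into a scale-factor table.
#'
#' @param mapping named numeric vector or list, cell type -> positive
#'   factor.
#' @return a \code{scale_factor_table} with method "manual".
#' @export
manual_scale_factors <- function(mapping) {
  x <- unlist(mapping)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("manual_scale_factors: factors must be named by cell type")
  x <- as.numeric(stats::setNames(x, names(unlist(mapping))))
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("manual_scale_factors: non-positive factor for: ",
         paste(names(unlist(mapping))[bad], collapse = ", "))
  .new_sft(names(unlist(mapping)), x, "manual", NA_integer_)
}
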