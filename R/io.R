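# Readers/writers for the on-disk formats the toolkit touches:
# MatrixMarket sparse counts + TSV annotations, dense TSV matrices,
# scale-factor TSV tables, and JSON evaluation reports.

#' Read a sparse single-cell count matrix (MatrixMarket + annotations)
#'
#' Reads the common single-cell export triplet: a MatrixMarket coordinate
#' file with genes as rows and cells as columns, a gene table and a cell
#' table (TSV, identifier in column 1).  The cell table must carry
#' cell-type and sample columns.
#'
#' @param matrix_path path to the .mtx file.
#' @param genes_path path to the gene annotation TSV (id in column 1).
#' @param cells_path path to the cell annotation TSV (id in column 1).
#' @param cell_type_col,sample_col column names (headered file) or indices
#'   (header-less) holding cell-type and sample labels in the cell table.
#' @param header do the annotation files carry a header row?
#' @param transpose set TRUE for the cells-as-rows MatrixMarket dialect.
#' @return a \code{\link{single_cell_dataset}}.
#' @export
read_sparse_counts <- function(matrix_path, genes_path, cells_path,
                               cell_type_col = "cell_type",
                               sample_col = "sample_id",
                               header = TRUE, transpose = FALSE) {
  m <- Matrix::readMM(matrix_path)
  if (transpose) m <- Matrix::t(m)
  genes <- utils::read.delim(genes_path, header = header,
                             stringsAsFactors = FALSE)
  cells <- utils::read.delim(cells_path, header = header,
                             stringsAsFactors = FALSE)
  if (nrow(genes) != nrow(m))
    stop("read_sparse_counts: gene annotation rows (", nrow(genes),
         ") do not match matrix rows (", nrow(m), ")")
  if (nrow(cells) != ncol(m))
    stop("read_sparse_counts: cell annotation rows (", nrow(cells),
         ") do not match matrix columns (", ncol(m), ")")
  if (length(m@x) && any(m@x < 0))
    stop("read_sparse_counts: negative entries in count matrix")
  pick <- function(df, col, what) {
    if (is.numeric(col)) {
      if (col > ncol(df)) stop("read_sparse_counts: no column ", col,
                               " for ", what)
      df[[col]]
    } else {
      if (!col %in% names(df))
        stop("read_sparse_counts: column '", col, "' (", what,
             ") absent from cell annotations")
      df[[col]]
    }
  }
  rownames(m) <- as.character(genes[[1L]])
  colnames(m) <- as.character(cells[[1L]])
  single_cell_dataset(m,
                      cell_type = pick(cells, cell_type_col, "cell type"),
                      sample_id = pick(cells, sample_col, "sample"),
                      cell_id   = as.character(cells[[1L]]))
}

#' Write a single-cell dataset as MatrixMarket + annotation TSVs
#'
#' Inverse of \code{\link{read_sparse_counts}}; genes as rows.
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param matrix_path,genes_path,cells_path output paths.
#' @export
write_sparse_counts <- function(dataset, matrix_path, genes_path, cells_path) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  m <- methods::as(methods::as(Matrix::Matrix(as.matrix(dataset$counts),
                                              sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  Matrix::writeMM(m, matrix_path)
  utils::write.table(data.frame(gene_id = rownames(dataset$counts)),
                     genes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$cells, cells_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a dense labelled matrix from TSV
#'
#' First column = gene identifier, header row = sample or cell-type labels.
#' Parsing is locale-independent (dot decimal separator).
#'
#' @param path input TSV path.
#' @param as one of "bulk" (returns a \code{\link{bulk_matrix}}),
#'   "reference" (a \code{\link{cell_type_reference}}) or "matrix".
#' @param scaled for \code{as = "reference"}: value of the scaled flag.
#' @return labelled matrix of the requested class.
#' @export
read_dense_matrix <- function(path, as = c("bulk", "reference", "matrix"),
                              scaled = FALSE) {
  as <- match.arg(as)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("read_dense_matrix: need id column plus data columns")
  ids <- df[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("read_dense_matrix: duplicated gene row(s): ",
         paste(dup, collapse = ", "))
  num <- as.matrix(df[, -1L, drop = FALSE])
  parsed <- suppressWarnings(array(as.numeric(num), dim = dim(num)))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed), arr.ind = TRUE)[1L, ]
    stop("read_dense_matrix: non-numeric value '", num[bad[1L], bad[2L]],
         "' at gene ", ids[bad[1L]], ", column ",
         colnames(num)[bad[2L]])
  }
  dimnames(parsed) <- list(ids, colnames(num))
  switch(as,
         bulk      = bulk_matrix(parsed),
         reference = cell_type_reference(parsed, scaled = scaled),
         matrix    = parsed)
}

#' Write a dense labelled matrix as TSV
#'
#' Values serialized with 17 significant digits, so read/write round trips
#' are exact at double precision.
#'
#' @param matrix labelled numeric matrix (bulk, reference or plain).
#' @param path output path.
#' @param id_col name of the identifier column (default "gene_id").
#' @export
write_dense_matrix <- function(matrix, path, id_col = "gene_id") {
  m <- as.matrix(matrix)
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a cell-size scale-factor table from TSV
#'
#' Expected columns: \code{cell_type}, \code{factor}, optional free-text
#' \code{source} (and any extra columns, which are preserved).
#'
#' @param path input TSV path.
#' @return data.frame with class \code{"scale_factor_table"}; ordering as
#'   on disk.
#' @export
read_scale_factors <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("cell_type", "factor")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("read_scale_factors: required column(s) missing: ",
         paste(missing, collapse = ", "))
  df$factor <- suppressWarnings(as.numeric(df$factor))
  bad <- is.na(df$factor) | !is.finite(df$factor) | df$factor <= 0
  if (any(bad))
    stop("read_scale_factors: non-positive or non-numeric factor for: ",
         paste(df$cell_type[bad], collapse = ", "))
  if (anyDuplicated(df$cell_type))
    stop("read_scale_factors: duplicated cell_type rows")
  if (is.null(df$source)) df$source <- ""
  structure(df, class = c("scale_factor_table", "data.frame"))
}

#' Write a scale-factor table as TSV
#'
#' @param table a \code{scale_factor_table} (or data.frame with cell_type
#'   and factor columns).
#' @param path output path.
#' @export
write_scale_factors <- function(table, path) {
  stopifnot(all(c("cell_type", "factor") %in% names(table)))
  tab <- as.data.frame(table)
  tab$factor <- format(tab$factor, digits = 17, trim = TRUE, scientific = NA)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a per-cell imaging measurement table
#'
#' TSV with columns \code{cell_id}, \code{cell_type}, \code{nucleus_area}
#' (micron-based units, >= 0) and \code{marker_copies} (integer puncta
#' counts), as produced by image segmentation software.
#'
#' @param path input TSV path.
#' @return data.frame with class \code{"measurement_table"}.
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("cell_type", "nucleus_area")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("read_measurements: required column(s) missing: ",
         paste(missing, collapse = ", "))
  if (any(!nzchar(df$cell_type)))
    stop("read_measurements: empty cell_type label(s)")
  if (any(!is.finite(df$nucleus_area) | df$nucleus_area < 0))
    stop("read_measurements: nucleus_area must be finite and >= 0")
  structure(df, class = c("measurement_table", "data.frame"))
}

#' Write an evaluation report as JSON
#'
#' Deterministic field ordering; numbers kept at full double precision so
#' a read-back equals the in-memory report.
#'
#' @param report an \code{evaluation_report} from
#'   \code{\link{evaluate_predictions}}.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  if (is.null(report$per_sample) || nrow(report$per_sample) == 0L)
    stop("write_report: report has an empty per-sample section")
  payload <- list(
    per_sample = report$per_sample,
    summary = report$summary,
    correlations = report$correlations,
    metadata = report$metadata
  )
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stop("write_report: cannot write '",
                                           path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              dataframe = "columns", null = "null",
                              na = "null", pretty = TRUE), con)
  invisible(NULL)
}

#' Read back a JSON evaluation report
#'
#' @param path path written by \code{\link{write_report}}.
#' @return an \code{evaluation_report}.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  structure(list(per_sample = as.data.frame(x$per_sample),
                 summary = as.data.frame(x$summary),
                 correlations = if (is.null(x$correlations)) NULL
                                else as.data.frame(x$correlations),
                 metadata = x$metadata),
            class = "evaluation_report")
}
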