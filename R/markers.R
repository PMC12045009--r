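# Marker-gene scoring/selection (mean-ratio) and count-level preprocessing
# applied before signature construction.

#' Per-cell-type mean expression
#'
#' Arithmetic mean of each gene over the cells of each type.  Accepts a
#' dataset or a precomputed genes x types mean matrix (e.g. batch-adjusted
#' expression), which is passed through unchanged.
#'
#' @param x a \code{\link{single_cell_dataset}} or genes x cell-types
#'   numeric matrix.
#' @return genes x cell-types matrix of means.
#' @export
type_means <- function(x) {
  if (is.matrix(x) || inherits(x, "Matrix")) return(as.matrix(x))
  stopifnot(inherits(x, "single_cell_dataset"))
  types <- sort(unique(x$cells$cell_type))
  counts <- x$counts
  out <- vapply(types, function(k) {
    idx <- which(x$cells$cell_type == k)
    as.numeric(Matrix::rowMeans(counts[, idx, drop = FALSE]))
  }, numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Mean-ratio marker scores for one cell type
#'
#' For each gene, the score is the mean expression in the target type
#' divided by the highest mean among all other types.  Scores above 1 mark
#' genes more expressed in the target than in any other type.  A zero
#' denominator with positive target mean yields \code{Inf} (maximally
#' specific gene); zero target mean yields score 0.
#'
#' @param x a \code{\link{single_cell_dataset}} or genes x types mean
#'   matrix (use the latter to score on batch-adjusted or log expression).
#' @param target_type the cell type to score markers for.
#' @return named numeric vector of scores, one per gene, in input gene
#'   order; attribute \code{target_mean} carries the target means (used to
#'   order infinite-score ties).
#' @export
mean_ratio_scores <- function(x, target_type) {
  means <- type_means(x)
  if (ncol(means) < 2L)
    stop("mean_ratio_scores: need at least 2 cell types")
  if (!target_type %in% colnames(means))
    stop("mean_ratio_scores: target type '", target_type,
         "' not present (types: ", paste(colnames(means), collapse = ", "), ")")
  tgt <- means[, target_type]
  other <- means[, setdiff(colnames(means), target_type), drop = FALSE]
  denom <- apply(other, 1L, max)
  score <- ifelse(denom > 0, tgt / denom, ifelse(tgt > 0, Inf, 0))
  structure(stats::setNames(as.numeric(score), rownames(means)),
            target_mean = stats::setNames(as.numeric(tgt), rownames(means)))
}

#' Select top marker genes per cell type by mean ratio
#'
#' Each gene is first claimed by the cell type where its mean-ratio score
#' is highest (so per-type marker lists are disjoint), then within each
#' type the \code{n_per_type} genes with the highest score exceeding
#' \code{min_ratio} are kept.  Ordering: descending score; infinite scores
#' rank first, ordered by target mean descending; remaining ties broken
#' lexicographically by gene identifier.
#'
#' @param x a \code{\link{single_cell_dataset}} or genes x types mean
#'   matrix.
#' @param n_per_type markers to keep per type (typical choices are 40 or
#'   80).
#' @param min_ratio minimum score to qualify (default 1: target mean must
#'   exceed every other type's mean).
#' @return a \code{marker_set}: list with \code{markers} (data.frame of
#'   cell_type, gene, score, rank) and \code{warnings} (per-type shortfall
#'   notes).
#' @export
select_markers <- function(x, n_per_type = 40L, min_ratio = 1) {
  stopifnot(n_per_type >= 1L)
  means <- type_means(x)
  types <- colnames(means)
  score_mat <- vapply(types, function(k) mean_ratio_scores(means, k),
                      numeric(nrow(means)))
  rownames(score_mat) <- rownames(means)
  # claim each gene for the type with its highest score; break score ties
  # toward the type with the larger mean for that gene
  claimed <- vapply(seq_len(nrow(score_mat)), function(g) {
    sc <- score_mat[g, ]
    best <- which(sc == max(sc))
    if (length(best) > 1L) best <- best[which.max(means[g, best])]
    types[best]
  }, character(1L))
  rows <- list(); warnings <- character(0)
  for (k in types) {
    genes_k <- rownames(score_mat)[claimed == k]
    sc <- score_mat[genes_k, k]
    tm <- means[genes_k, k]
    qual <- sc > min_ratio
    genes_k <- genes_k[qual]; sc <- sc[qual]; tm <- tm[qual]
    ord <- order(-is.infinite(sc), ifelse(is.infinite(sc), -tm, 0),
                 -sc, genes_k)
    take <- utils::head(ord, n_per_type)
    if (length(take) < n_per_type)
      warnings <- c(warnings, sprintf(
        "%s: only %d of %d requested markers qualified", k, length(take),
        n_per_type))
    if (length(take))
      rows[[k]] <- data.frame(cell_type = k, gene = genes_k[take],
                              score = as.numeric(sc[take]),
                              rank = seq_along(take),
                              stringsAsFactors = FALSE)
  }
  structure(list(markers = do.call(rbind, c(rows, list(
                   make.row.names = FALSE))),
                 warnings = warnings),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  tab <- table(x$markers$cell_type)
  cat("marker_set:", nrow(x$markers), "genes over", length(tab),
      "cell types (", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), ")\n")
  if (length(x$warnings)) cat("warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' All genes in a marker set
#' @param markers a \code{marker_set}.
#' @return character vector of gene identifiers.
#' @export
marker_genes <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  markers$markers$gene
}

#' Write/read a marker set as TSV (cell_type, gene, score, rank)
#' @param markers a \code{marker_set}.
#' @param path TSV path.
#' @export
write_markers <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  tab <- markers$markers
  tab$score <- format(tab$score, digits = 17, trim = TRUE, scientific = NA)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("cell_type", "gene", "score", "rank")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("read_markers: required column(s) missing: ",
         paste(missing, collapse = ", "))
  df$score <- as.numeric(df$score)
  structure(list(markers = df, warnings = character(0)),
            class = "marker_set")
}

#' Quality-filter bulk samples on marker coverage
#'
#' Retains samples whose total counts over the marker genes reach
#' \code{min_counts} and whose number of zero-expression marker genes does
#' not exceed \code{max_zero_markers}.  The defaults reproduce typical
#' bulk QC thresholds for a brain marker panel (38,750 minimum marker
#' counts; at most 30 silent markers).
#'
#' @param bulk a \code{\link{bulk_matrix}}.
#' @param markers a \code{marker_set} (or character vector of genes).
#' @param min_counts minimum summed marker counts per sample.
#' @param max_zero_markers maximum number of markers with zero counts.
#' @return the filtered \code{bulk_matrix}, with attribute
#'   \code{filter_log}: a data.frame of per-sample marker_counts,
#'   zero_markers and pass.
#' @export
sample_qc_filter <- function(bulk, markers, min_counts = 38750,
                             max_zero_markers = 30) {
  genes <- if (inherits(markers, "marker_set")) marker_genes(markers)
           else as.character(markers)
  if (!length(genes)) stop("sample_qc_filter: empty marker set")
  genes <- intersect(genes, rownames(bulk))
  if (!length(genes))
    stop("sample_qc_filter: no marker genes present in bulk matrix")
  sub <- unclass(bulk)[genes, , drop = FALSE]
  log <- data.frame(sample = colnames(sub),
                    marker_counts = colSums(sub),
                    zero_markers = colSums(sub == 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  log$pass <- log$marker_counts >= min_counts &
    log$zero_markers <= max_zero_markers
  if (!any(log$pass))
    stop("sample_qc_filter: all ", nrow(log), " samples removed by QC")
  out <- bulk_matrix(unclass(bulk)[, log$pass, drop = FALSE])
  attr(out, "filter_log") <- log
  out
}

#' Downsample cell libraries to the per-type minimum
#'
#' Within each group (cell type by default), every cell's counts are
#' subsampled without replacement (multivariate hypergeometric) to the
#' minimum library size observed in that group, so output library sizes
#' are exactly equal within a group.  Exact subsampling — rather than
#' binomial thinning — guarantees the per-cell totals.
#'
#' @param dataset a \code{\link{single_cell_dataset}}.
#' @param grouping annotation column defining the groups (default
#'   "cell_type").
#' @param seed integer seed; the operation is reproducible given it.
#' @return a \code{single_cell_dataset} with downsampled counts.
#' @export
downsample_counts <- function(dataset, grouping = "cell_type", seed = 1L) {
  stopifnot(inherits(dataset, "single_cell_dataset"))
  if (!grouping %in% names(dataset$cells))
    stop("downsample_counts: unknown grouping column '", grouping, "'")
  counts <- as.matrix(dataset$counts)
  groups <- dataset$cells[[grouping]]
  lib <- colSums(counts)
  out <- counts
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    target <- min(lib[idx])
    if (target <= 0)
      stop("downsample_counts: zero minimum library size in group '", g, "'")
    for (i in idx) {
      if (lib[i] > target)
        out[, i] <- .hyper_subsample(counts[, i], target)
    }
  }
  single_cell_dataset(out, cell_type = dataset$cells$cell_type,
                      sample_id = dataset$cells$sample_id,
                      cell_id = dataset$cells$cell_id)
}

# Draw a multivariate hypergeometric sample: pick `target` reads without
# replacement from a count vector. Sequential conditional rhyper() draws.
.hyper_subsample <- function(counts, target) {
  remaining <- sum(counts)
  draw <- integer(length(counts))
  left <- target
  for (g in seq_along(counts)) {
    if (left == 0L) break
    cg <- counts[g]
    remaining <- remaining - cg
    if (remaining <= 0L) { draw[g] <- left; left <- 0L; break }
    x <- stats::rhyper(1L, cg, remaining, left)
    draw[g] <- x
    left <- left - x
  }
  draw
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
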