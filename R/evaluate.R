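# Error, RMSE, bias, and correlation metrics comparing known and predicted
# cell-type proportions.

.check_comparable <- function(known, predicted) {
  if (!setequal(rownames(known), rownames(predicted)))
    stop("evaluate: cell-type labels differ (known: ",
         paste(rownames(known), collapse = ", "), "; predicted: ",
         paste(rownames(predicted), collapse = ", "), ")")
  if (!setequal(colnames(known), colnames(predicted)))
    stop("evaluate: sample labels differ")
  unclass(predicted)[rownames(known), colnames(known), drop = FALSE]
}

#' Per-entry absolute error between known and predicted proportions
#'
#' Error = |P_known - P_pred|, aligned by cell type and sample label.
#'
#' @param known,predicted proportion matrices (types x samples) with
#'   matching label sets.
#' @return matrix of absolute errors in known's ordering.
#' @export
per_type_error <- function(known, predicted) {
  pred <- .check_comparable(known, predicted)
  abs(unclass(known) - pred)
}

#' Root mean squared error over cell types
#'
#' Per sample j, \eqn{RMSE_j = \sqrt{\sum_k (P_{known,kj} -
#' P_{pred,kj})^2 / K}}.  The pooled variant averages squared errors over
#' all (type, sample) pairs before the square root, so pooled RMSE^2 is
#' the count-weighted mean of per-sample RMSE^2.  An optional
#' \code{combine} map derives summed entries before comparison (e.g. a
#' "neuron" entry as excitatory + inhibitory predictions for k = 3
#' summaries).
#'
#' @param known,predicted proportion matrices (types x samples).
#' @param over "sample" (vector of per-sample RMSEs, default) or "pooled"
#'   (single number).
#' @param combine optional named list: new label -> character vector of
#'   labels to sum in both matrices before comparison.
#' @return numeric vector (per sample) or single value (pooled).
#' @export
rmse <- function(known, predicted, over = c("sample", "pooled"),
                 combine = NULL) {
  over <- match.arg(over)
  pred <- .check_comparable(known, predicted)
  kn <- unclass(known)
  if (!is.null(combine)) {
    add <- function(m) {
      extra <- do.call(rbind, lapply(combine, function(parts) {
        miss <- setdiff(parts, rownames(m))
        if (length(miss)) stop("rmse: combine refers to absent label(s): ",
                               paste(miss, collapse = ", "))
        colSums(m[parts, , drop = FALSE])
      }))
      rownames(extra) <- names(combine)
      rbind(m, extra)
    }
    kn <- add(kn); pred <- add(pred)
  }
  if (nrow(kn) == 0L) stop("rmse: no cell types")
  sq <- (kn - pred)^2
  if (over == "sample") {
    out <- sqrt(colMeans(sq))
    stats::setNames(out, colnames(kn))
  } else sqrt(mean(sq))
}

#' Evaluate one or more deconvolution results against known proportions
#'
#' Assembles the long-format comparison table behind benchmark summaries:
#' one row per (condition, sample, cell type) with known, predicted,
#' absolute error and signed bias (predicted - known); per-condition RMSE
#' (both the mean of per-sample RMSEs and the pooled form), mean signed
#' bias per cell type, and — when at least 3 samples are present —
#' Pearson correlation between known and predicted across samples per
#' cell type.
#'
#' @param known a \code{\link{proportion_matrix}} of true proportions.
#' @param results named list of \code{deconvolution_result} objects (or
#'   bare proportion matrices); names label the conditions.
#' @return list with class \code{"evaluation_report"}: \code{per_sample}
#'   (long table), \code{summary} (per condition), \code{correlations}
#'   (per condition x type, NULL when J < 3 or degenerate), and
#'   \code{metadata}.
#' @export
evaluate_predictions <- function(known, results) {
  stopifnot(inherits(known, "proportion_matrix"))
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- sprintf("condition%d", seq_along(results))
  per_sample <- list(); summaries <- list(); cors <- list()
  for (cond in names(results)) {
    r <- results[[cond]]
    props <- if (inherits(r, "deconvolution_result")) r$proportions else r
    pred <- .check_comparable(known, props)
    kn <- unclass(known)
    err <- abs(kn - pred)
    long <- data.frame(
      condition = cond,
      sample = rep(colnames(kn), each = nrow(kn)),
      cell_type = rep(rownames(kn), times = ncol(kn)),
      known = as.numeric(kn),
      predicted = as.numeric(pred),
      error = as.numeric(err),
      signed_bias = as.numeric(pred - kn),
      stringsAsFactors = FALSE)
    per_sample[[cond]] <- long
    per_samp_rmse <- sqrt(colMeans((kn - pred)^2))
    summaries[[cond]] <- data.frame(
      condition = cond,
      rmse_mean_per_sample = mean(per_samp_rmse),
      rmse_pooled = sqrt(mean((kn - pred)^2)),
      mean_signed_bias = mean(pred - kn),
      algorithm = if (inherits(r, "deconvolution_result")) r$algorithm
                  else NA_character_,
      scaled = if (inherits(r, "deconvolution_result")) r$scaled else NA,
      stringsAsFactors = FALSE)
    if (ncol(kn) >= 3L) {
      cc <- vapply(rownames(kn), function(k) {
        x <- kn[k, ]; y <- pred[k, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(x, y)
      }, numeric(1L))
      cors[[cond]] <- data.frame(condition = cond,
                                 cell_type = rownames(kn),
                                 pearson_r = as.numeric(cc),
                                 stringsAsFactors = FALSE)
    }
  }
  note <- if (ncol(unclass(known)) < 3L)
    "correlation omitted: fewer than 3 samples" else NULL
  structure(list(
    per_sample = do.call(rbind, c(per_sample, list(make.row.names = FALSE))),
    summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    correlations = if (length(cors))
      do.call(rbind, c(cors, list(make.row.names = FALSE))) else NULL,
    metadata = list(n_samples = ncol(unclass(known)),
                    n_types = nrow(unclass(known)),
                    note = note)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", x$metadata$n_types, "cell types x",
      x$metadata$n_samples, "samples\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("per-type Pearson correlations:\n")
    print(x$correlations, row.names = FALSE)
  } else if (!is.null(x$metadata$note)) cat(x$metadata$note, "\n")
  invisible(x)
}
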