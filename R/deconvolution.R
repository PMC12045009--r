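# Solvers estimating P from Y and Z (optionally size-rescaled) and the
# name-keyed algorithm registry they plug into.

# ---- NNLS core --------------------------------------------------------------

# Lawson-Hanson active-set non-negative least squares:
#   min ||A x - b||_2  s.t.  x >= 0.
# K (ncol) is small here (2-30 cell types) so a plain R implementation is
# fast; the passive-set subproblem is solved by qr.solve.
.nnls <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * nrow(A)
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter * 10L) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(z[passive] > tol)) { x <- z; break }
      viol <- passive & z <= tol
      alpha <- min(x[viol] / (x[viol] - z[viol]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x[x < 0] <- 0
  x
}

# ---- alignment --------------------------------------------------------------

#' Align a bulk matrix and a reference on their common genes
#'
#' Restricts both matrices to the gene intersection, in reference gene
#' order, and logs how many genes each side lost.  Deconvolution always
#' runs on aligned inputs.
#'
#' @param bulk a \code{\link{bulk_matrix}}.
#' @param reference a \code{\link{cell_type_reference}}.
#' @return list(bulk, reference, dropped_bulk, dropped_reference).
#' @export
align_markers <- function(bulk, reference) {
  common <- intersect(rownames(reference), rownames(bulk))
  if (!length(common))
    stop("align_markers: bulk and reference share no genes")
  list(bulk = bulk_matrix(unclass(bulk)[common, , drop = FALSE]),
       reference = cell_type_reference(
         unclass(reference)[common, , drop = FALSE],
         scaled = is_scaled(reference)),
       dropped_bulk = nrow(bulk) - length(common),
       dropped_reference = nrow(reference) - length(common))
}

.finish_result <- function(raw, resid, bulk, reference, algorithm,
                           factors = NULL) {
  if (any(colSums(raw) <= 0))
    stop("deconvolution: all-zero solution for sample(s) ",
         paste(colnames(bulk)[colSums(raw) <= 0], collapse = ", "),
         " (degenerate reference?)")
  props <- sweep(raw, 2L, colSums(raw), `/`)
  dimnames(props) <- list(colnames(reference), colnames(bulk))
  structure(list(
    proportions = proportion_matrix(props),
    algorithm = algorithm,
    scaled = is_scaled(reference),
    factors_used = factors,
    residual_norm = stats::setNames(resid, colnames(bulk)),
    genes_used = rownames(reference)
  ), class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("deconvolution_result (", x$algorithm,
      if (x$scaled) ", size-scaled" else ", unscaled", "): ",
      nrow(x$proportions), " cell types x ", ncol(x$proportions),
      " samples over ", length(x$genes_used), " genes\n", sep = "")
  print(round(unclass(x$proportions), 4))
  invisible(x)
}

# ---- solvers ----------------------------------------------------------------

#' Deconvolute bulk samples by NNLS on the probability simplex
#'
#' For each sample j, solves \eqn{min ||Z p - y_j||_2, p >= 0} and then
#' divides by the coefficient sum so each column lies on the simplex.  The
#' residual norm recorded per sample comes from the unnormalized fit.
#' When the reference is unscaled and cell sizes differ, the result is the
#' per-type RNA fraction \eqn{s \circ p / \sum s \circ p}, not the cell
#' fraction — rescale the reference first to recover cell fractions.
#'
#' @param bulk a \code{\link{bulk_matrix}}, genes aligned with the
#'   reference (see \code{\link{align_markers}}).
#' @param reference a \code{\link{cell_type_reference}}.
#' @param options unused; present for registry signature compatibility.
#' @return a \code{deconvolution_result}.
#' @export
deconvolute_nnls <- function(bulk, reference, options = list()) {
  .check_aligned(bulk, reference)
  A <- unclass(reference); attr(A, "scaled") <- NULL
  raw <- matrix(0, ncol(reference), ncol(bulk))
  resid <- numeric(ncol(bulk))
  for (j in seq_len(ncol(bulk))) {
    y <- unclass(bulk)[, j]
    if (all(y == 0))
      stop("deconvolute_nnls: sample '", colnames(bulk)[j],
           "' is all zeros")
    p <- .nnls(A, y)
    raw[, j] <- p
    resid[j] <- sqrt(sum((A %*% p - y)^2))
  }
  .finish_result(raw, resid, bulk, reference, "nnls")
}

#' Weighted NNLS deconvolution
#'
#' Solves \eqn{min ||W^{1/2}(Z p - y)||_2, p >= 0} per sample, then
#' simplex-normalizes.  With uniform weights this is exactly
#' \code{\link{deconvolute_nnls}}.  Weights may be supplied per gene or
#' derived from per-gene variance across bulk samples as
#' \eqn{w_g = 1/(\sigma^2_g + \nu)}, with ridge constant \eqn{\nu}
#' defaulting to the mean per-gene variance times 1e-3 (keeps weights
#' finite for zero-variance genes).
#'
#' @param bulk,reference aligned inputs as in
#'   \code{\link{deconvolute_nnls}}.
#' @param options list with either \code{weights} (positive numeric, one
#'   per gene) or \code{weight_mode = "variance"}; optional \code{nu}
#'   overrides the ridge constant.
#' @return a \code{deconvolution_result}.
#' @export
deconvolute_weighted_nnls <- function(bulk, reference, options = list()) {
  .check_aligned(bulk, reference)
  G <- nrow(reference)
  w <- options$weights
  if (is.null(w)) {
    if (identical(options$weight_mode, "variance")) {
      v <- apply(unclass(bulk), 1L, stats::var)
      if (ncol(bulk) < 2L) v <- rep(0, G)
      nu <- options$nu
      if (is.null(nu)) nu <- max(mean(v) * 1e-3, .Machine$double.eps)
      w <- 1 / (v + nu)
    } else w <- rep(1, G)
  }
  if (length(w) != G)
    stop("deconvolute_weighted_nnls: need one weight per gene (", G, ")")
  if (any(!is.finite(w) | w <= 0))
    stop("deconvolute_weighted_nnls: weights must be positive and finite")
  sw <- sqrt(w)
  A <- unclass(reference); attr(A, "scaled") <- NULL
  Aw <- A * sw
  raw <- matrix(0, ncol(reference), ncol(bulk))
  resid <- numeric(ncol(bulk))
  for (j in seq_len(ncol(bulk))) {
    y <- unclass(bulk)[, j]
    if (all(y == 0))
      stop("deconvolute_weighted_nnls: sample '", colnames(bulk)[j],
           "' is all zeros")
    p <- .nnls(Aw, y * sw)
    raw[, j] <- p
    resid[j] <- sqrt(sum((A %*% p - y)^2))
  }
  .finish_result(raw, resid, bulk, reference, "wnnls")
}

.check_aligned <- function(bulk, reference) {
  if (!identical(rownames(bulk), rownames(reference)))
    stop("deconvolution: bulk and reference genes are not aligned; ",
         "run align_markers() first")
  if (ncol(reference) < 2L)
    stop("deconvolution: need at least 2 cell types")
  invisible(TRUE)
}

# ---- registry ---------------------------------------------------------------

#' Create an algorithm registry
#'
#' A registry maps algorithm names to solver functions with the common
#' signature \code{function(bulk, reference, options)} returning a
#' \code{deconvolution_result}.  A fresh registry has the built-ins
#' "nnls" (default) and "wnnls" pre-registered; external algorithm
#' wrappers (e.g. around multi-sample or assay-bias-correcting methods)
#' plug in via \code{\link{register_algorithm}}.
#'
#' @return an environment with class \code{"algorithm_registry"}.
#' @export
algorithm_registry <- function() {
  reg <- new.env(parent = emptyenv())
  class(reg) <- "algorithm_registry"
  register_algorithm(reg, "nnls", deconvolute_nnls,
                     requires_reference = TRUE)
  register_algorithm(reg, "wnnls", deconvolute_weighted_nnls,
                     requires_reference = TRUE)
  reg
}

#' Register a deconvolution algorithm
#'
#' @param registry an \code{\link{algorithm_registry}}.
#' @param name unique algorithm name.
#' @param solver function(bulk, reference, options) ->
#'   \code{deconvolution_result}; must be deterministic given its inputs.
#' @param requires_reference does the solver need a signature matrix?
#' @return the registry, invisibly.
#' @export
register_algorithm <- function(registry, name, solver,
                               requires_reference = TRUE) {
  stopifnot(inherits(registry, "algorithm_registry"), is.function(solver))
  if (name %in% ls(registry))
    stop("register_algorithm: '", name, "' is already registered")
  assign(name, list(name = name, solver = solver,
                    requires_reference = requires_reference),
         envir = registry)
  invisible(registry)
}

#' List registered algorithm names
#' @param registry an \code{\link{algorithm_registry}}.
#' @return character vector of names, sorted.
#' @export
list_algorithms <- function(registry) sort(ls(registry))

.default_registry_env <- new.env(parent = emptyenv())

default_registry <- function() {
  if (is.null(.default_registry_env$reg))
    .default_registry_env$reg <- algorithm_registry()
  .default_registry_env$reg
}

#' Run the full deconvolution pipeline
#'
#' Pipeline: align genes, rescale the reference by cell-size factors if
#' given (Z' = Z S), then apply the requested solver.  Passing no factors
#' — or all-ones factors — reproduces the unscaled run bit for bit.
#'
#' @param bulk a \code{\link{bulk_matrix}}.
#' @param reference a \code{\link{cell_type_reference}} (unscaled).
#' @param factors cell-size factors (\code{cell_scale_factors}, named
#'   vector or \code{scale_factor_table}), or NULL for no scaling.
#' @param algorithm registered algorithm name (default "nnls").
#' @param options solver-specific options list.
#' @param registry algorithm registry (package default if omitted).
#' @return a \code{deconvolution_result}; \code{$scaled} and
#'   \code{$factors_used} record whether/which factors were applied.
#' @examples
#' z <- cell_type_reference(matrix(c(10, 1, 1, 8), 2,
#'        dimnames = list(c("g1", "g2"), c("neuron", "glial"))))
#' y <- bulk_matrix(matrix(c(5.5, 4.5), 2,
#'        dimnames = list(c("g1", "g2"), "s1")))
#' run_deconvolution(y, z)$proportions
#' @export
run_deconvolution <- function(bulk, reference, factors = NULL,
                              algorithm = "nnls", options = list(),
                              registry = default_registry()) {
  if (!algorithm %in% ls(registry))
    stop("run_deconvolution: unknown algorithm '", algorithm,
         "' (registered: ", paste(list_algorithms(registry), collapse = ", "),
         ")")
  aligned <- align_markers(bulk, reference)
  ref <- aligned$reference
  fac <- NULL
  if (!is.null(factors)) {
    fac <- cell_scale_factors(factors)
    ref <- rescale_reference(ref, fac)
  }
  spec <- get(algorithm, envir = registry)
  res <- spec$solver(aligned$bulk, ref, options)
  res$algorithm <- algorithm
  res$factors_used <- fac
  res
}
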