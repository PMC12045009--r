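# Pseudobulk construction (Y = Z S P), synthetic single-cell generation,
# and the five-term shuffle experiments.

#' Generate pseudobulk samples as Y = Z S P
#'
#' The noiseless pseudobulk is the exact matrix product of the (optionally
#' size-rescaled) reference and the known proportions; this makes exact
#' recovery achievable by a matched deconvolution and isolates the effect
#' of mismatched cell sizes.  Count noise (Poisson or negative binomial
#' with mean equal to the noiseless value) is opt-in.
#'
#' @param reference a \code{\link{cell_type_reference}}.
#' @param factors cell-size factors applied as Z' = Z S, or NULL for no
#'   scaling (all types treated as equal-sized).
#' @param proportions a \code{\link{proportion_matrix}} (types x samples).
#' @param noise "none" (default), "poisson", or "negative_binomial".
#' @param dispersion NB dispersion theta (> 0): variance = mu + mu^2/theta.
#' @param seed integer seed used for the noise draws.
#' @return a \code{\link{bulk_matrix}} (genes x samples).
#' @examples
#' z <- cell_type_reference(matrix(c(2, 4, 1, 3), 2,
#'        dimnames = list(c("g1", "g2"), c("A", "B"))))
#' p <- proportion_matrix(matrix(c(0.5, 0.5), 2,
#'        dimnames = list(c("A", "B"), "s1")))
#' generate_pseudobulk(z, c(A = 3, B = 1), p)   # (3.5, 7.5)
#' @export
generate_pseudobulk <- function(reference, factors = NULL, proportions,
                                noise = c("none", "poisson",
                                          "negative_binomial"),
                                dispersion = NULL, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(inherits(reference, "cell_type_reference"),
            inherits(proportions, "proportion_matrix"))
  z <- reference
  if (!is.null(factors)) z <- rescale_reference(z, factors)
  types_z <- colnames(z); types_p <- rownames(proportions)
  if (!setequal(types_z, types_p))
    stop("generate_pseudobulk: cell-type mismatch between reference (",
         paste(types_z, collapse = ", "), ") and proportions (",
         paste(types_p, collapse = ", "), ")")
  y <- unclass(z) %*% unclass(proportions)[types_z, , drop = FALSE]
  if (noise != "none") {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    mu <- as.numeric(y)
    drawn <- if (noise == "poisson") {
      stats::rpois(length(mu), mu)
    } else {
      if (is.null(dispersion) || dispersion <= 0)
        stop("generate_pseudobulk: negative_binomial noise needs ",
             "dispersion > 0")
      stats::rnbinom(length(mu), size = dispersion, mu = mu)
    }
    y <- matrix(as.numeric(drawn), nrow(y), ncol(y), dimnames = dimnames(y))
  }
  bulk_matrix(y)
}

#' Generate a synthetic single-cell dataset with planted markers and sizes
#'
#' Emulates the structure of an snRNA-seq input: each cell type has M
#' planted marker genes whose mean is \code{fold_change} times the base
#' mean, every cell's expected counts are multiplied by its type's size
#' multiplier (so types differ in library size the way large neurons and
#' smaller glia do), counts are negative binomial
#' (variance = mu + mu^2/theta), and cells are spread over samples.
#'
#' @param n_types K (>= 2).
#' @param n_genes total genes G (must be >= K * markers_per_type).
#' @param markers_per_type planted markers per type (M).
#' @param fold_change marker enrichment f (> 1).
#' @param base_mean baseline NB mean per gene (mu).
#' @param dispersion NB dispersion theta (> 0).
#' @param size_multipliers per-type relative cell size; recycled named or
#'   unnamed vector of length K (default all 1).
#' @param cells_per_type cells per type per the whole dataset.
#' @param n_samples cells are assigned round-robin to this many samples.
#' @param seed integer seed; the dataset is reproducible given it.
#' @param type_names optional type labels (default type1..K).
#' @return a \code{\link{single_cell_dataset}}; attribute
#'   \code{planted_markers} maps each type to its marker genes.
#' @export
generate_synthetic_sc <- function(n_types = 2L, n_genes = 200L,
                                  markers_per_type = 40L, fold_change = 8,
                                  base_mean = 2, dispersion = 10,
                                  size_multipliers = NULL,
                                  cells_per_type = 100L, n_samples = 1L,
                                  seed = 1L, type_names = NULL) {
  if (n_types < 2L) stop("generate_synthetic_sc: n_types must be >= 2")
  if (markers_per_type < 1L)
    stop("generate_synthetic_sc: markers_per_type must be >= 1")
  if (fold_change <= 1)
    stop("generate_synthetic_sc: fold_change must be > 1")
  if (base_mean <= 0 || dispersion <= 0)
    stop("generate_synthetic_sc: base_mean and dispersion must be positive")
  if (n_genes < n_types * markers_per_type)
    stop("generate_synthetic_sc: n_genes (", n_genes, ") < n_types * ",
         "markers_per_type (", n_types * markers_per_type, ")")
  if (is.null(type_names)) type_names <- sprintf("type%d", seq_len(n_types))
  if (is.null(size_multipliers)) size_multipliers <- rep(1, n_types)
  if (length(size_multipliers) != n_types)
    stop("generate_synthetic_sc: need one size multiplier per type")
  if (any(size_multipliers <= 0))
    stop("generate_synthetic_sc: size multipliers must be positive")
  size_multipliers <- stats::setNames(as.numeric(size_multipliers),
                                      type_names)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  # planted marker blocks: type k owns genes [(k-1)M+1, kM]
  planted <- stats::setNames(lapply(seq_len(n_types), function(k)
    genes[((k - 1L) * markers_per_type + 1L):(k * markers_per_type)]),
    type_names)
  mu_mat <- matrix(base_mean, n_genes, n_types,
                   dimnames = list(genes, type_names))
  for (k in seq_len(n_types))
    mu_mat[planted[[k]], k] <- base_mean * fold_change

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n_cells <- n_types * cells_per_type
  cell_type <- rep(type_names, each = cells_per_type)
  sample_id <- sprintf("sample%d",
                       rep_len(seq_len(n_samples), n_cells))
  counts <- matrix(0L, n_genes, n_cells, dimnames = list(
    genes, sprintf("cell%05d", seq_len(n_cells))))
  for (i in seq_len(n_cells)) {
    mu_i <- mu_mat[, cell_type[i]] * size_multipliers[cell_type[i]]
    counts[, i] <- stats::rnbinom(n_genes, size = dispersion, mu = mu_i)
  }
  ds <- single_cell_dataset(counts, cell_type = cell_type,
                            sample_id = sample_id)
  attr(ds, "planted_markers") <- planted
  attr(ds, "size_multipliers") <- size_multipliers
  ds
}

#' Construct a shuffle-experiment design
#'
#' The pseudobulk/deconvolution identity
#' \deqn{P_{dec} \Leftarrow \{ Z_{dec} S_{dec},\; Z_{pb} S_{pb} P_{pb} \}}
#' has five terms; shuffle experiments vary one while matching the rest,
#' probing how robust composition estimates are to, e.g., cell sizes
#' measured on a different tissue block.  Deconvolution-side terms left
#' NULL default to the matched pseudobulk-side term.
#'
#' @param z_pseudobulk reference used to build the pseudobulk.
#' @param s_pseudobulk cell-size factors used to build the pseudobulk
#'   (NULL = all ones).
#' @param p_pseudobulk known proportions (types x samples).
#' @param z_deconvolution reference handed to the solver (NULL = matched).
#' @param s_deconvolution factors handed to the solver (NULL = matched;
#'   use \code{ones} for explicitly unscaled deconvolution).
#' @return list with class \code{"shuffle_design"}; \code{$matched} flags
#'   which terms are matched.
#' @export
shuffle_design <- function(z_pseudobulk, s_pseudobulk = NULL, p_pseudobulk,
                           z_deconvolution = NULL, s_deconvolution = NULL) {
  stopifnot(inherits(z_pseudobulk, "cell_type_reference"),
            inherits(p_pseudobulk, "proportion_matrix"))
  matched <- c(
    z = is.null(z_deconvolution),
    s = is.null(s_deconvolution)
  )
  structure(list(z_pb = z_pseudobulk, s_pb = s_pseudobulk,
                 p_pb = p_pseudobulk,
                 z_dec = if (is.null(z_deconvolution)) z_pseudobulk
                         else z_deconvolution,
                 s_dec = if (is.null(s_deconvolution)) s_pseudobulk
                         else s_deconvolution,
                 matched = matched),
            class = "shuffle_design")
}

#' Run a shuffle experiment
#'
#' Builds Y from the pseudobulk-side terms of the design, deconvolves with
#' the deconvolution-side terms, and evaluates against the known
#' proportions.  With all terms matched (and no noise) recovery is exact
#' to machine precision; with mismatched sizes the closed-form bias
#' \eqn{\hat p \propto (s_{pb}/s_{dec}) \circ p} applies.
#'
#' @param design a \code{\link{shuffle_design}}.
#' @param algorithm registered algorithm name.
#' @param registry algorithm registry.
#' @param noise,dispersion,seed passed to
#'   \code{\link{generate_pseudobulk}}.
#' @return an \code{evaluation_report} (see
#'   \code{\link{evaluate_predictions}}); its metadata records which terms
#'   were matched.
#' @export
run_shuffle_experiment <- function(design, algorithm = "nnls",
                                   registry = default_registry(),
                                   noise = "none", dispersion = NULL,
                                   seed = 1L) {
  stopifnot(inherits(design, "shuffle_design"))
  if (!setequal(colnames(design$z_pb), colnames(design$z_dec)))
    stop("run_shuffle_experiment: pseudobulk and deconvolution references ",
         "carry different cell types")
  y <- generate_pseudobulk(design$z_pb, design$s_pb, design$p_pb,
                           noise = noise, dispersion = dispersion,
                           seed = seed)
  res <- run_deconvolution(y, design$z_dec, factors = design$s_dec,
                           algorithm = algorithm, registry = registry)
  report <- evaluate_predictions(design$p_pb, list(deconvolution = res))
  report$metadata$matched_terms <- design$matched
  report$metadata$seed <- seed
  report$metadata$noise <- noise
  report
}
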