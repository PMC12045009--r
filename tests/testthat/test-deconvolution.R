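test_that("align_markers restricts to the gene intersection", {
  z <- toy_reference(genes = c("g2", "g3", "g4"),
                     values = c(1, 2, 3, 4, 5, 6))
  y <- bulk_matrix(matrix(1:3, 3, dimnames = list(c("g1", "g2", "g3"),
                                                  "s1")))
  out <- align_markers(y, z)
  expect_identical(rownames(out$bulk), c("g2", "g3"))
  expect_identical(rownames(out$reference), c("g2", "g3"))
  expect_equal(out$dropped_bulk, 1)
  expect_equal(out$dropped_reference, 1)
  # identical gene sets pass through unchanged
  same <- align_markers(bulk_matrix(matrix(1:3, 3,
            dimnames = list(rownames(z), "s1"))), z)
  expect_equal(unclass(same$reference), unclass(z), ignore_attr = TRUE)
  # disjoint sets error
  y2 <- bulk_matrix(matrix(1, 1, dimnames = list("gX", "s1")))
  expect_error(align_markers(y2, z), "no genes")
})

test_that("NNLS recovers an exact column match and the worked 3-gene case", {
  z <- rank_reference(K = 3, G = 30)
  yA <- bulk_matrix(matrix(unclass(z)[, 1], nrow(z),
                           dimnames = list(rownames(z), "s1")))
  p <- deconvolute_nnls(yA, z)$proportions
  expect_equal(unclass(p)[, 1], c(type1 = 1, type2 = 0, type3 = 0),
               tolerance = 1e-10)

  z2 <- cell_type_reference(matrix(c(1, 0, 1, 0, 1, 1), 3,
          dimnames = list(c("g1", "g2", "g3"), c("A", "B"))))
  y2 <- bulk_matrix(matrix(c(0.6, 0.4, 1.0), 3,
          dimnames = list(c("g1", "g2", "g3"), "s1")))
  p2 <- deconvolute_nnls(y2, z2)$proportions
  expect_equal(unclass(p2)[, 1], c(A = 0.6, B = 0.4), tolerance = 1e-10)
})

test_that("NNLS-then-normalize matches the K=2 grid-search oracle", {
  set.seed(99)
  for (i in 1:50) {
    Z <- matrix(stats::runif(8 * 2, 0, 5), 8)
    dimnames(Z) <- list(sprintf("g%d", 1:8), c("A", "B"))
    p_true <- stats::runif(1)
    y <- Z %*% c(p_true, 1 - p_true) + stats::rnorm(8, sd = 0.05)
    y <- pmax(y, 0)
    fit <- deconvolute_nnls(
      bulk_matrix(matrix(y, 8, dimnames = list(rownames(Z), "s1"))),
      cell_type_reference(Z))
    # oracle searches the simplex directly, step 1e-4
    p_grid <- grid_search_k2(Z, y)
    expect_lt(abs(unclass(fit$proportions)["A", 1] - p_grid), 2e-4)
  }
})

test_that("unscaled deconvolution returns the RNA fraction", {
  z <- rank_reference(K = 2, G = 40)
  s <- c(type1 = 10, type2 = 3)
  p <- unit_props(c(0.5, 0.5), colnames(z))
  y <- generate_pseudobulk(z, s, p)
  # unscaled: q = s*p / sum(s*p) = (10, 3)/13
  q <- run_deconvolution(y, z)$proportions
  expect_equal(unclass(q)[, 1], c(type1 = 10 / 13, type2 = 3 / 13),
               tolerance = 1e-8)
  # scaled: exact recovery
  phat <- run_deconvolution(y, z, factors = s)$proportions
  expect_equal(unclass(phat)[, 1], c(type1 = 0.5, type2 = 0.5),
               tolerance = 1e-10)
})

test_that("solver errors are labelled", {
  z <- toy_reference()
  y0 <- bulk_matrix(matrix(c(0, 0), 2, dimnames = list(c("g1", "g2"),
                                                       "dead")))
  expect_error(deconvolute_nnls(y0, z), "'dead' is all zeros")
  ymis <- bulk_matrix(matrix(1:2, 2, dimnames = list(c("g2", "g1"), "s1")))
  expect_error(deconvolute_nnls(ymis, z), "not aligned")
})

test_that("weighted NNLS equals NNLS under uniform weights", {
  z <- rank_reference(K = 3, G = 24, seed = 5)
  p <- unit_props(c(0.2, 0.3, 0.5), colnames(z))
  y <- generate_pseudobulk(z, NULL, p, noise = "poisson", seed = 11)
  plain <- deconvolute_nnls(y, z)
  w_unif <- deconvolute_weighted_nnls(y, z,
                                      list(weights = rep(1, nrow(z))))
  expect_equal(unclass(w_unif$proportions), unclass(plain$proportions),
               tolerance = 1e-12)
  expect_error(deconvolute_weighted_nnls(y, z,
                                         list(weights = rep(-1, nrow(z)))),
               "positive")
})

test_that("near-zero weight on a contaminated gene removes its influence", {
  z <- rank_reference(K = 2, G = 12, seed = 6)
  p <- unit_props(c(0.4, 0.6), colnames(z))
  y <- generate_pseudobulk(z, NULL, p)
  ycont <- unclass(y); ycont[1, 1] <- ycont[1, 1] + 50
  ycont <- bulk_matrix(ycont)
  w <- rep(1, nrow(z)); w[1] <- 1e-12
  down <- deconvolute_weighted_nnls(ycont, z, list(weights = w))
  # oracle: plain NNLS with the gene dropped outright
  keep <- rownames(z)[-1]
  ref_sub <- cell_type_reference(unclass(z)[keep, ])
  removed <- deconvolute_nnls(
    bulk_matrix(unclass(ycont)[keep, , drop = FALSE]), ref_sub)
  expect_equal(unclass(down$proportions), unclass(removed$proportions),
               tolerance = 1e-6)
})

test_that("variance-derived weights help on noisy pseudobulk (soft property)", {
  # replicate samples at a fixed composition, with a handful of genes
  # carrying much larger noise: cross-sample variance identifies them and
  # 1/(var + nu) downweighting should beat uniform weights most of the time
  zbig <- rank_reference(K = 2, G = 30, seed = 12)
  zbig <- cell_type_reference(unclass(zbig) * 20)
  J <- 6L
  p <- proportion_matrix(matrix(rep(c(0.35, 0.65), J), 2,
         dimnames = list(colnames(zbig), sprintf("s%d", 1:J))))
  wins <- 0L
  n_rep <- 50L
  for (seed in seq_len(n_rep)) {
    y <- generate_pseudobulk(zbig, NULL, p, noise = "poisson", seed = seed)
    set.seed(seed + 1000)
    noisy_genes <- 1:5
    ym <- unclass(y)
    ym[noisy_genes, ] <- ym[noisy_genes, ] +
      matrix(stats::rpois(length(noisy_genes) * J, 300),
             length(noisy_genes))
    ym <- bulk_matrix(ym)
    plain <- rmse(p, deconvolute_nnls(ym, zbig)$proportions,
                  over = "pooled")
    wtd <- rmse(p, deconvolute_weighted_nnls(ym, zbig,
      list(weight_mode = "variance"))$proportions, over = "pooled")
    if (wtd <= plain) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.6)
})

test_that("the registry dispatches, lists, and rejects duplicates", {
  reg <- algorithm_registry()
  expect_identical(list_algorithms(reg), c("nnls", "wnnls"))
  expect_error(register_algorithm(reg, "nnls", function(...) NULL),
               "already registered")
  # user plugin: uniform proportions
  register_algorithm(reg, "uniform", function(bulk, reference, options) {
    K <- ncol(reference)
    props <- matrix(1 / K, K, ncol(bulk),
                    dimnames = list(colnames(reference), colnames(bulk)))
    structure(list(proportions = proportion_matrix(props),
                   algorithm = "uniform", scaled = FALSE,
                   factors_used = NULL,
                   residual_norm = rep(NA_real_, ncol(bulk)),
                   genes_used = rownames(reference)),
              class = "deconvolution_result")
  })
  z <- toy_reference()
  y <- bulk_matrix(matrix(c(2, 4), 2, dimnames = list(c("g1", "g2"), "s1")))
  out <- run_deconvolution(y, z, algorithm = "uniform", registry = reg)
  expect_equal(as.numeric(out$proportions), c(0.5, 0.5))
  expect_error(run_deconvolution(y, z, algorithm = "missing",
                                 registry = reg), "registered: nnls")
})

test_that("factors none vs all-ones give identical results", {
  z <- rank_reference(K = 3, G = 18, seed = 8)
  p <- unit_props(c(0.1, 0.4, 0.5), colnames(z))
  y <- generate_pseudobulk(z, NULL, p, noise = "poisson", seed = 2)
  a <- run_deconvolution(y, z)
  b <- run_deconvolution(y, z,
                         factors = stats::setNames(rep(1, 3), colnames(z)))
  expect_identical(unclass(a$proportions), unclass(b$proportions))
  expect_false(a$scaled); expect_true(b$scaled)
})

test_that("proportions stay on the simplex and ignore bulk scale", {
  for (seed in 1:10) {
    z <- rank_reference(K = 3, G = 21, seed = seed)
    p <- proportion_sweep(colnames(z), n = 4)
    y <- generate_pseudobulk(z, NULL, p, noise = "poisson", seed = seed)
    fit <- run_deconvolution(y, z)
    expect_true(all(abs(colSums(fit$proportions) - 1) < 1e-9))
    expect_true(all(unclass(fit$proportions) >= 0))
    # scale invariance: multiply one bulk column by c > 0
    y2 <- unclass(y); y2[, 2] <- y2[, 2] * 37.5
    fit2 <- run_deconvolution(bulk_matrix(y2), z)
    expect_equal(unclass(fit2$proportions)[, 2],
                 unclass(fit$proportions)[, 2], tolerance = 1e-10)
  }
})
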