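test_that("mean_ratio_scores matches the definition on hand examples", {
  means <- matrix(c(10, 4,   # type A
                    2, 8,    # type B
                    1, 1),   # type C
                  nrow = 2,
                  dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  sc <- mean_ratio_scores(means, "A")
  expect_equal(unname(sc["g1"]), 5)    # 10 / max(2, 1)
  expect_equal(unname(sc["g2"]), 0.5)  # 4 / max(8, 1)
  expect_error(mean_ratio_scores(means, "D"), "not present")
})

test_that("mean_ratio_scores equals brute force on random toy matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    means <- matrix(stats::rexp(20 * 3), 20,
                    dimnames = list(sprintf("g%02d", 1:20), c("A", "B", "C")))
    means[sample(length(means), 5)] <- 0
    tgt <- sample(c("A", "B", "C"), 1)
    expect_identical(as.numeric(mean_ratio_scores(means, tgt)),
                     as.numeric(brute_force_mean_ratio(means, tgt)))
  }
})

test_that("select_markers keeps top-N disjoint sorted lists", {
  set.seed(5)
  means <- matrix(stats::runif(60 * 3, 0.1, 1), 60,
                  dimnames = list(sprintf("g%02d", 1:60), c("A", "B", "C")))
  means[1:10, "A"] <- means[1:10, "A"] + 5
  means[11:20, "B"] <- means[11:20, "B"] + 5
  means[21:30, "C"] <- means[21:30, "C"] + 5
  mk <- select_markers(means, n_per_type = 5)
  tab <- mk$markers
  expect_equal(unname(table(tab$cell_type)[c("A", "B", "C")]),
               rep(5L, 3), ignore_attr = TRUE)
  expect_false(anyDuplicated(tab$gene) > 0)
  for (k in c("A", "B", "C")) {
    s <- tab$score[tab$cell_type == k]
    expect_true(all(diff(s) <= 0))
  }
  # monotonicity: growing n keeps earlier picks
  mk10 <- select_markers(means, n_per_type = 10)
  for (k in c("A", "B", "C"))
    expect_true(all(tab$gene[tab$cell_type == k] %in%
                    mk10$markers$gene[mk10$markers$cell_type == k]))
})

test_that("exclusive genes get the infinite-score sentinel and rank first", {
  means <- matrix(c(5, 1, 9,
                    0, 3, 0,
                    0, 1, 0), nrow = 3,
                  dimnames = list(c("gx", "gy", "gz"), c("A", "B", "C")))
  sc <- mean_ratio_scores(means, "A")
  expect_identical(unname(sc["gx"]), Inf)
  mk <- select_markers(means, n_per_type = 3)
  a <- mk$markers[mk$markers$cell_type == "A", ]
  expect_identical(a$gene[1], "gz")  # Inf ties ordered by target mean desc
  expect_identical(a$gene[2], "gx")
})

test_that("shortfall records a warning in metadata, not an error", {
  means <- matrix(c(5, 1, 1, 5), 2,
                  dimnames = list(c("g1", "g2"), c("A", "B")))
  mk <- select_markers(means, n_per_type = 10)
  expect_length(mk$warnings, 2)
  expect_match(mk$warnings[1], "only 1 of 10")
})

test_that("marker sets round-trip as TSV", {
  ds <- generate_synthetic_sc(n_types = 3, n_genes = 60,
                              markers_per_type = 10, cells_per_type = 20,
                              seed = 9)
  mk <- select_markers(ds, n_per_type = 5)
  d <- withr::local_tempdir()
  p <- file.path(d, "markers.tsv")
  write_markers(mk, p)
  back <- read_markers(p)
  expect_equal(back$markers$gene, mk$markers$gene)
  expect_equal(back$markers$score, mk$markers$score, tolerance = 1e-15)
})

test_that("sample_qc_filter applies both marker-count thresholds", {
  genes <- sprintf("g%02d", 1:40)
  y <- matrix(1000, 40, 3, dimnames = list(genes, c("keep", "low", "zeros")))
  y[, "low"] <- 750                      # 30,000 marker counts: below floor
  y[, "zeros"] <- 2000; y[1:31, "zeros"] <- 0  # 31 silent markers
  y["g01", "keep"] <- 0                  # 40,000 - wait, adjust below
  y[, "keep"] <- 1000; y[1:10, "keep"] <- 0; y[11:40, "keep"] <- 1340
  # keep: 30 * 1340 = 40,200 counts, 10 zero markers -> retained
  bulk <- bulk_matrix(y)
  out <- sample_qc_filter(bulk, genes, min_counts = 38750,
                          max_zero_markers = 30)
  expect_identical(colnames(out), "keep")
  log <- attr(out, "filter_log")
  expect_equal(log$pass, c(TRUE, FALSE, FALSE))
  expect_equal(log$marker_counts[log$sample == "low"], 30000)
  expect_equal(log$zero_markers[log$sample == "zeros"], 31)
  expect_error(sample_qc_filter(bulk, genes, min_counts = 1e9,
                                max_zero_markers = 0), "all .* samples")
})

test_that("downsample_counts hits the per-type minimum exactly", {
  counts <- matrix(c(60, 40, 30, 20, 5, 5), nrow = 2,
                   dimnames = list(c("g1", "g2"), sprintf("c%d", 1:3)))
  ds <- single_cell_dataset(counts, cell_type = rep("A", 3))
  out <- downsample_counts(ds, seed = 42)
  expect_equal(unname(colSums(as.matrix(out$counts))), rep(10, 3))
  # integrality and no entry grows
  expect_true(all(as.matrix(out$counts) == round(as.matrix(out$counts))))
  expect_true(all(as.matrix(out$counts) <= counts))
  # determinism
  out2 <- downsample_counts(ds, seed = 42)
  expect_identical(as.matrix(out$counts), as.matrix(out2$counts))
  # zero minimum library errors with the group name
  ds0 <- single_cell_dataset(matrix(c(5, 0), 1, 2,
                                    dimnames = list("g1", NULL)),
                             cell_type = c("B", "B"))
  expect_error(downsample_counts(ds0), "group 'B'")
})

test_that("downsampling matches the hypergeometric expectation", {
  # one type, many cells: per-gene expected counts after exact
  # subsampling are proportional to the original composition; chi-square
  # goodness of fit over pooled draws should not reject at alpha = 0.01
  set.seed(1)
  G <- 10
  base <- c(400, 200, 100, 80, 60, 50, 40, 30, 25, 15)
  # 200 double-depth cells plus one cell at the target depth
  counts <- cbind(matrix(rep(base * 2, 200), G), base)
  rownames(counts) <- sprintf("g%02d", 1:G)
  ds <- single_cell_dataset(counts, cell_type = rep("A", ncol(counts)))
  out <- downsample_counts(ds, seed = 7)
  tot <- colSums(as.matrix(out$counts))
  expect_true(all(tot == sum(base)))
  pooled <- rowSums(as.matrix(out$counts)[, 1:200])
  expected <- base / sum(base) * sum(pooled)
  chisq <- sum((pooled - expected)^2 / expected)
  pval <- stats::pchisq(chisq, df = G - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})
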