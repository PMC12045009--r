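# Shared fixtures, built in code at test time.

toy_reference <- function(genes = c("g1", "g2"), types = c("A", "B"),
                          values = c(2, 4, 1, 3), scaled = FALSE) {
  cell_type_reference(matrix(values, length(genes),
                             dimnames = list(genes, types)),
                      scaled = scaled)
}

# full-column-rank K-type reference with distinct marker blocks
rank_reference <- function(K = 2L, G = 40L, seed = 42L) {
  set.seed(seed)
  types <- sprintf("type%d", seq_len(K))
  genes <- sprintf("g%03d", seq_len(G))
  m <- matrix(stats::runif(G * K, 0.5, 2), G, K,
              dimnames = list(genes, types))
  block <- split(seq_len(G), rep_len(seq_len(K), G))
  for (k in seq_len(K)) m[block[[k]], k] <- m[block[[k]], k] + 10
  cell_type_reference(m)
}

unit_props <- function(p, types, sample = "s1") {
  proportion_matrix(matrix(p, length(types),
                           dimnames = list(types, sample)))
}

# proportion sweep: `n` samples moving type1 over [lo, hi], remainder
# split evenly over the other types
proportion_sweep <- function(types, n = 17L, lo = 0.25, hi = 0.80) {
  p1 <- seq(lo, hi, length.out = n)
  K <- length(types)
  m <- rbind(p1, matrix(rep((1 - p1) / (K - 1), each = K - 1), K - 1))
  dimnames(m) <- list(types, sprintf("s%02d", seq_len(n)))
  proportion_matrix(m)
}

# tiny deterministic single-cell dataset: 4 genes, 2 types x 3 cells,
# 2 samples
toy_dataset <- function() {
  counts <- matrix(c(5, 0, 2, 1,
                     6, 1, 3, 0,
                     4, 0, 1, 1,
                     0, 7, 0, 3,
                     1, 8, 1, 2,
                     0, 9, 0, 4), nrow = 4,
                   dimnames = list(c("g1", "g2", "g3", "g4"),
                                   sprintf("c%d", 1:6)))
  single_cell_dataset(counts,
                      cell_type = rep(c("A", "B"), each = 3),
                      sample_id = rep(c("s1", "s2"), times = 3))
}
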