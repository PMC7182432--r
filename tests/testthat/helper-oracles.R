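# Independent oracles and fixture builders. The oracles implement the
# definitions literally (double loops, exhaustive enumeration) and share no
# code with the package implementation they check.

# percent rank by the definition: rank(c) = 1 + #{c': x(c') < x(c)},
# PR = (rank - 1) / (N - 1), gene by gene, cell by cell
oracle_percent_rank <- function(M) {
  M <- as.matrix(M)
  n <- ncol(M)
  out <- M
  for (g in seq_len(nrow(M))) {
    for (c in seq_len(n)) {
      out[g, c] <- sum(M[g, ] < M[g, c]) / (n - 1)
    }
  }
  out
}

# mean percent rank over a gene set: literal loop over the oracle PR rows
oracle_scgps <- function(M, genes) {
  pr <- oracle_percent_rank(M)
  vapply(seq_len(ncol(M)), function(c) {
    s <- 0
    for (g in genes) s <- s + pr[g, c]
    s / length(genes)
  }, 0)
}

# exact two-sided rank-sum p by exhaustive enumeration of all C(n, n_a)
# group labelings of the pooled sample (tie-free inputs only)
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  ud <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(ud <= u_obs), mean(ud >= u_obs)))
}

# random sparse log-normalized fixture with engineered tie blocks:
# integer-valued rows tie heavily, a few rows are constant or all-zero,
# a few are tie-free reals
random_lognorm_fixture <- function(n_genes, n_cells) {
  M <- matrix(0, n_genes, n_cells)
  for (g in seq_len(n_genes)) {
    kind <- sample(c("sparse_int", "real", "constant", "zero"), 1,
                   prob = c(0.6, 0.25, 0.1, 0.05))
    M[g, ] <- switch(kind,
      sparse_int = rpois(n_cells, lambda = runif(1, 0.2, 2)),
      real = stats::rexp(n_cells),
      constant = rep(round(stats::rexp(1), 2), n_cells),
      zero = 0)
  }
  expression_matrix(M, gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    cell_ids = sprintf("c%03d", seq_len(n_cells)),
                    layer = "lognorm")
}

random_counts_fixture <- function(n_genes, n_cells, lambda = 1.5) {
  M <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
  # guarantee nonzero totals so normalization is defined
  zero_cells <- which(colSums(M) == 0)
  M[1, zero_cells] <- 1L
  expression_matrix(M, gene_ids = sprintf("g%03d", seq_len(n_genes)),
                    cell_ids = sprintf("c%03d", seq_len(n_cells)),
                    layer = "raw_counts")
}

dense_values <- function(x) as.matrix(x$values)
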