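# Shared fixtures: all built in code at test time.

# Count container from a bare matrix, metadata parsed from column names.
mk_counts <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  meristem_counts(m, parse_sample_ids(colnames(m)))
}

# Small deterministic count matrix: 2 stages x 2 replicates.
toy_counts <- function(seed = 42, n_genes = 6, n_stages = 2) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * 2 * n_stages, 50), nrow = n_genes)
    colnames(m) <- as.vector(outer(1:2, seq_len(n_stages),
                                   function(r, s) sprintf("M%d_R%d", s, r)))
    mk_counts(m)
  })
}

# Five well-separated archetypes from the package defaults (the flat and
# M5-dip shapes are omitted: each is close to the other's complement).
arch5 <- function(n_genes_each = 100, base_mean_range = c(200, 1000)) {
  default_archetypes(n_genes_each, base_mean_range)[
    c("spike_m5", "m4_m6_up", "mono_up", "mono_down", "late_burst")]
}

# Brute-force median-of-ratios oracle, straight from the definition.
oracle_size_factors <- function(m) {
  usable <- apply(m > 0, 1, all)
  geo <- apply(m[usable, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  apply(m[usable, , drop = FALSE] / geo, 2, median)
}

# Brute-force co-occurrence oracle: O(R * n^2) triple loop.
oracle_cooccurrence <- function(labels) {
  R <- nrow(labels)
  n <- ncol(labels)
  N <- matrix(0L, n, n)
  for (r in seq_len(R))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (labels[r, i] == labels[r, j]) N[i, j] <- N[i, j] + 1L
  N
}
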