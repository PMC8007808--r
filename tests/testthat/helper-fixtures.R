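# Shared fixtures: everything is generated in code at test time.

# Small planted dataset: one dual-disease driver module (module 1) and one
# osteoporosis-only module (module 2), strong loadings for fast recovery.
small_config <- function(seed = 1, n_samples = 200, sizes = c(25, 15),
                         n_background = 60, ...) {
  simulation_config(n_samples = n_samples, module_sizes = sizes,
                    n_background = n_background,
                    trait_effects = default_trait_effects(length(sizes)),
                    seed = seed, ...)
}

# Eigengenes computed from the planted truth labels (bypasses network
# detection when a test targets a downstream stage only).
truth_eigengenes <- function(dataset) {
  module_eigengenes(dataset$expression, dataset$truth$gene_module_labels)
}

# Random symmetric adjacency with unit diagonal, entries in [0, 1].
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Brute-force TOM by the defining triple loop; the oracle for the matrix
# implementation.
tom_brute_force <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj) - 1
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l_ij <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l_ij <- l_ij + adj[i, u] * adj[u, j]
      }
      tom[i, j] <- (l_ij + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
    }
  }
  tom
}

# Random positive-definite 2x2 SSCP matrix.
random_sscp <- function(seed, scale = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(20), 10, 2)
  crossprod(m) * scale
}
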