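test_that("UPGMA clustering reproduces hand-computed merge heights", {
  # 4-leaf instance: (1,2) at 0.1, (3,4) at 0.2,
  # then mean(0.9, 0.8, 0.7, 0.6) = 0.75
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["c", "d"] <- d["d", "c"] <- 0.2
  d["a", "c"] <- d["c", "a"] <- 0.9
  d["a", "d"] <- d["d", "a"] <- 0.8
  d["b", "c"] <- d["c", "b"] <- 0.7
  d["b", "d"] <- d["d", "b"] <- 0.6
  dend <- average_linkage_cluster(d)
  expect_equal(dend$height, c(0.1, 0.2, 0.75))

  # two zero-distance blocks with unit separation
  b <- matrix(1, 6, 6)
  b[1:3, 1:3] <- 0
  b[4:6, 4:6] <- 0
  dimnames(b) <- list(paste0("g", 1:6), paste0("g", 1:6))
  dend_b <- average_linkage_cluster(b)
  expect_equal(max(dend_b$height), 1)
  expect_equal(sort(dend_b$height), c(0, 0, 0, 0, 1))

  expect_error(average_linkage_cluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  dd <- d; diag(dd) <- 0.5
  expect_error(average_linkage_cluster(dd), "diagonal")
})

test_that("UPGMA is invariant to leaf input order", {
  a <- random_adjacency(30, seed = 12)
  diss <- tom_dissimilarity(topological_overlap(a))
  dimnames(diss) <- list(paste0("g", 1:30), paste0("g", 1:30))
  dend1 <- average_linkage_cluster(diss)
  set.seed(1)
  perm <- sample(30)
  dend2 <- average_linkage_cluster(diss[perm, perm])
  expect_equal(sort(dend1$height), sort(dend2$height), tolerance = 1e-12)
  c1 <- stats::cutree(dend1, k = 4)
  c2 <- stats::cutree(dend2, k = 4)[names(c1)]
  expect_equal(adjusted_rand_index(c1, c2), 1)
})

test_that("tree cut recovers two planted blocks and demotes small clusters", {
  d <- generate_dataset(simulation_config(
    n_samples = 300, module_sizes = c(50, 40), n_background = 100,
    loading_range = c(0.6, 0.9), trait_effects = matrix(0, 10, 2), seed = 5))
  cm <- correlation_matrix(d$expression)
  tom <- topological_overlap(signed_adjacency(cm, 10))
  dend <- average_linkage_cluster(tom_dissimilarity(tom))
  asg <- dynamic_tree_cut(dend, min_module_size = 10)
  truth <- d$truth$gene_module_labels
  keep <- truth > 0
  expect_equal(adjusted_rand_index(truth[keep], asg$labels[names(truth)[keep]]), 1)

  # a planted block of 5 genes with min size 10 ends up unassigned
  d5 <- generate_dataset(simulation_config(
    n_samples = 300, module_sizes = c(40, 5), n_background = 60,
    loading_range = c(0.7, 0.9), trait_effects = matrix(0, 10, 2), seed = 6))
  cm5 <- correlation_matrix(d5$expression)
  dend5 <- average_linkage_cluster(
    tom_dissimilarity(topological_overlap(signed_adjacency(cm5, 10))))
  asg5 <- dynamic_tree_cut(dend5, min_module_size = 10)
  block5 <- names(d5$truth$gene_module_labels)[d5$truth$gene_module_labels == 2]
  expect_true(all(asg5$labels[block5] == 0))

  expect_error(dynamic_tree_cut(dend, min_module_size = 1), "min_module_size")
  expect_error(dynamic_tree_cut(dend, cut_height = 2), "cut_height")
})

test_that("module count is non-increasing in min_module_size", {
  d <- generate_dataset(small_config(seed = 8))
  cm <- correlation_matrix(d$expression)
  dend <- average_linkage_cluster(
    tom_dissimilarity(topological_overlap(signed_adjacency(cm, 10))))
  counts <- vapply(c(5, 10, 30), function(ms) {
    length(dynamic_tree_cut(dend, min_module_size = ms)$module_sizes)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pure-noise expression leaves most genes unassigned", {
  frac_grey <- vapply(1:20, function(s) {
    d <- generate_dataset(simulation_config(
      n_samples = 100, module_sizes = 1, n_background = 499,
      trait_effects = matrix(0, 10, 1), seed = s))
    cm <- correlation_matrix(d$expression)
    dend <- average_linkage_cluster(
      tom_dissimilarity(topological_overlap(signed_adjacency(cm, 10))))
    asg <- dynamic_tree_cut(dend, min_module_size = 10,
                            cor = cm, n_samples = 100)
    mean(asg$labels == 0)
  }, numeric(1))
  expect_true(all(frac_grey >= 0.8))
})

test_that("the cohesion filter keeps real modules and rejects chance clusters", {
  d <- generate_dataset(small_config(seed = 24, n_samples = 300))
  cm <- correlation_matrix(d$expression)
  dend <- average_linkage_cluster(
    tom_dissimilarity(topological_overlap(signed_adjacency(cm, 10))))
  with_filter <- dynamic_tree_cut(dend, 10, cor = cm, n_samples = 300)
  truth <- d$truth$gene_module_labels
  keep <- truth > 0
  expect_equal(adjusted_rand_index(truth[keep],
                                   with_filter$labels[names(truth)[keep]]), 1)
  expect_error(dynamic_tree_cut(dend, 10, cor = cm), "n_samples")
})

test_that("eigengene degenerate and oracle cases", {
  set.seed(31)
  expr <- matrix(stats::rnorm(50 * 21), 50, 21,
                 dimnames = list(sprintf("s%02d", 1:50), sprintf("g%02d", 1:21)))
  # single-gene module: eigengene equals the z-scored profile, varexp 1
  labels <- stats::setNames(c(1L, rep(2L, 20)), colnames(expr))
  eig <- module_eigengenes(expr, labels)
  z1 <- as.numeric(scale(expr[, 1]))
  expect_equal(unname(eig$scores[, 1]), z1, tolerance = 1e-10)
  expect_equal(unname(eig$variance_explained[1]), 1)

  # variance explained equals the top-eigenvalue ratio of the member
  # correlation matrix (independent eigen-decomposition oracle)
  members <- names(labels)[labels == 2]
  ev <- eigen(stats::cor(expr[, members]), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(eig$variance_explained[2]), ev[1] / sum(ev),
               tolerance = 1e-8)

  # k identical duplicated genes: eigengene is the common z-profile
  dup <- expr[, c(1, 1, 1)]
  colnames(dup) <- c("d1", "d2", "d3")
  eig_dup <- module_eigengenes(dup, stats::setNames(rep(1L, 3), colnames(dup)))
  expect_equal(unname(eig_dup$scores[, 1]), z1, tolerance = 1e-10)
  expect_equal(unname(eig_dup$variance_explained[1]), 1, tolerance = 1e-12)

  # duplicating every member gene leaves the eigengene unchanged
  both <- cbind(expr[, members], expr[, members])
  colnames(both) <- paste0("h", seq_len(ncol(both)))
  eig_two <- module_eigengenes(both, stats::setNames(rep(1L, ncol(both)), colnames(both)))
  expect_equal(unname(eig_two$scores[, 1]), unname(eig$scores[, 2]),
               tolerance = 1e-8)

  # every eigengene column is centred
  expect_lt(max(abs(colMeans(eig$scores))), 1e-10)
})

test_that("module membership is gene-eigengene correlation", {
  set.seed(32)
  expr <- matrix(stats::rnorm(40 * 10), 40, 10,
                 dimnames = list(paste0("s", 1:40), paste0("g", 1:10)))
  labels <- stats::setNames(c(1L, rep(2L, 9)), colnames(expr))
  eig <- module_eigengenes(expr, labels)
  mm <- module_membership(expr, eig)
  # sole member of its module: MM = 1
  expect_equal(unname(mm["g1", 1]), 1, tolerance = 1e-12)
  # gene equal to the negated eigengene: MM = -1
  expr2 <- cbind(expr, neg = -eig$scores[, 2])
  mm2 <- module_membership(expr2, eig)
  expect_equal(unname(mm2["neg", 2]), -1, tolerance = 1e-12)
  # spot-check against direct correlation on 5 genes
  for (g in paste0("g", 2:6)) {
    expect_equal(unname(mm[g, 2]), stats::cor(expr[, g], eig$scores[, 2]),
                 tolerance = 1e-12)
  }
})

test_that("gene significance joins on sample ids", {
  d <- generate_dataset(small_config(seed = 13, n_samples = 100))
  gs <- gene_significance(d$expression, d$traits)
  expect_equal(dim(gs), c(100, 10))
  # trait equal to a gene's expression gives GS = 1
  tt <- d$traits
  tt$traits[, "CIMTavg"] <- d$expression[tt$sample_ids, 1]
  gs1 <- gene_significance(d$expression, tt)
  expect_equal(unname(gs1[1, "CIMTavg"]), 1, tolerance = 1e-12)
  # permuting trait row order leaves GS unchanged (id-based join)
  perm <- sample(nrow(tt$traits))
  tt_perm <- trait_table(tt$traits[perm, ], tt$covariates[perm, ], tt$groups)
  expect_equal(gene_significance(d$expression, tt_perm), gs1)
  # an independent noise trait has small |GS| for nearly all genes
  set.seed(14)
  big <- generate_dataset(simulation_config(
    n_samples = 1000, module_sizes = 10, n_background = 190,
    trait_effects = matrix(0, 10, 1), seed = 14))
  gs_null <- gene_significance(big$expression, big$traits)
  expect_gte(mean(abs(gs_null[, 1]) < 0.1), 0.99)
})

test_that("GS-MM quality check has the documented boundaries", {
  gs <- stats::setNames(c(0.5, 0.3, 0.1, 0.8), paste0("g", 1:4))
  mm <- gs
  q <- gs_mm_quality(gs, mm, paste0("g", 1:4))
  expect_equal(q$r_gs_mm, 1)
  expect_equal(q$p, 0)
  # |GS| is used: sign-flipped GS gives the same r
  q2 <- gs_mm_quality(-gs, mm, paste0("g", 1:4))
  expect_equal(q2$r_gs_mm, 1)
  # 3-gene module: p computed with 1 df, r = 1 gives the p = 0 bound
  q3 <- gs_mm_quality(gs[1:3], mm[1:3], paste0("g", 1:3))
  expect_equal(q3$n, 3)
  expect_equal(q3$p, 0)
  expect_error(gs_mm_quality(gs[1:2], mm[1:2], paste0("g", 1:2)), ">= 3")
})

test_that("planted driver modules pass the GS-MM quality bar", {
  # trait wired to the module factor at the generator's default scale:
  # cor(|GS|, MM) over member genes exceeds the conventional 0.34 bar
  hits <- vapply(1:100, function(s) {
    d <- generate_dataset(simulation_config(seed = s))
    m1 <- names(d$truth$gene_module_labels)[d$truth$gene_module_labels == 1]
    sub <- d$expression[, m1]
    eig <- module_eigengenes(sub, stats::setNames(rep(1L, length(m1)), m1))
    gs <- gene_significance(sub, d$traits)
    mm <- module_membership(sub, eig)
    gs_mm_quality(gs[, "DRToBMC"], mm[, 1], m1)$r_gs_mm > 0.34
  }, logical(1))
  expect_gte(sum(hits), 95)
})
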