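#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' Thin, validated wrapper around [stats::hclust()] with
#' `method = "average"`, which implements unweighted pair-group average
#' linkage; merges and heights are deterministic for a given input.
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal (typically
#'   `1 - TOM`).
#' @return an `hclust` object.
#' @export
average_linkage_cluster <- function(diss) {
  diss <- as.matrix(diss)
  if (!isSymmetric(unname(diss), tol = 1e-8)) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(diss)) > 1e-12)) stop("dissimilarity diagonal must be zero")
  if (any(diss < 0)) stop("dissimilarities must be non-negative")
  stats::hclust(stats::as.dist(diss), method = "average")
}

# Conventional module colour vocabulary, in assignment order; modules past
# the palette fall back to "module_<k>".
module_palette <- function() {
  c("turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta", "honeydew",
    "lightcoral", "darkseagreen", "sienna")
}

#' Cut a dendrogram into modules (static-height tree variant)
#'
#' Removes merges above `cut_height`, takes the remaining branches as
#' clusters, demotes clusters smaller than `min_module_size` to the
#' unassigned label 0 ("grey"), and relabels surviving modules by decreasing
#' size, mapping them onto a conventional colour vocabulary.
#'
#' When the gene-gene correlation matrix and the sample count are supplied,
#' a cohesion filter is applied as well: a cluster is kept only if the
#' leading eigenvalue of its member correlation matrix exceeds `cohesion`
#' times the Marchenko-Pastur bulk edge `(1 + sqrt(m/n))^2`, the largest
#' eigenvalue expected from an m-gene cluster of pure noise at n samples.
#' This rejects chance clusters that a static height cut cannot distinguish
#' from real co-expression on tree geometry alone.
#'
#' @param dend an `hclust` tree from [average_linkage_cluster()].
#' @param min_module_size minimum genes per module (>= 2, default 10).
#' @param cut_height static cut height; the default is 0.99 of the way up
#'   the merge-height range, `h_min + 0.99 (h_max - h_min)`. TOM
#'   dissimilarity trees concentrate their merges in a narrow band just
#'   below 1, so the cut must be placed relative to the observed height
#'   range, not as a fraction of the maximum height.
#' @param cor optional genes x genes correlation matrix (gene ids matching
#'   the dendrogram labels), enabling the cohesion filter.
#' @param n_samples number of samples behind `cor`; required with `cor`.
#' @param cohesion multiple of the Marchenko-Pastur edge a cluster's leading
#'   correlation eigenvalue must exceed (default 2).
#' @return a `module_assignment`: list with `labels` (named integer vector,
#'   0 = unassigned), `colors` (named character vector, "grey" = unassigned),
#'   `module_sizes`, `cut_height`, `min_module_size`.
#' @export
dynamic_tree_cut <- function(dend, min_module_size = 10, cut_height = NULL,
                             cor = NULL, n_samples = NULL, cohesion = 2) {
  stopifnot(inherits(dend, "hclust"))
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  if (!is.null(cor) && is.null(n_samples)) {
    stop("n_samples is required when cor is supplied")
  }
  if (is.null(cut_height)) {
    cut_height <- min(dend$height) + 0.99 * diff(range(dend$height))
  }
  if (cut_height <= 0 || cut_height > max(dend$height)) {
    stop("cut_height must be in (0, max merge height]")
  }
  raw <- stats::cutree(dend, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  if (!is.null(cor) && length(keep) > 0) {
    cohesive <- vapply(keep, function(cl) {
      members <- names(raw)[raw == as.integer(cl)]
      m <- length(members)
      lam1 <- eigen(cor[members, members], symmetric = TRUE,
                    only.values = TRUE)$values[1]
      lam1 > cohesion * (1 + sqrt(m / n_samples))^2
    }, logical(1))
    keep <- keep[cohesive]
  }
  labels <- integer(length(raw))
  names(labels) <- names(raw)
  if (length(keep) > 0) {
    keep <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- i
  }
  palette <- module_palette()
  color_of <- function(k) {
    ifelse(k == 0, "grey",
           ifelse(k <= length(palette), palette[pmax(k, 1)],
                  paste0("module_", k)))
  }
  structure(list(
    labels = labels,
    colors = stats::setNames(color_of(labels), names(labels)),
    module_sizes = if (any(labels > 0)) table(labels[labels > 0]) else table(integer(0)),
    cut_height = cut_height,
    min_module_size = min_module_size
  ), class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  n_mod <- length(x$module_sizes)
  cat(sprintf("module_assignment: %d modules over %d genes (%d unassigned)\n",
              n_mod, length(x$labels), sum(x$labels == 0)))
  if (n_mod > 0) {
    sz <- as.integer(x$module_sizes)
    cat("  sizes:", paste(sz, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Module labels for a set of genes
#' @param assign a `module_assignment`.
#' @param module integer label or colour name.
#' @return character vector of member gene ids.
#' @export
module_members <- function(assign, module) {
  if (is.character(module)) {
    names(assign$colors)[assign$colors == module]
  } else {
    names(assign$labels)[assign$labels == module]
  }
}

#' Module eigengenes (first principal components)
#'
#' Summarises each module by the first principal component of its member
#' genes' z-scored expression across samples. The sign is oriented so the
#' eigengene correlates non-negatively with the mean member z-profile, and
#' variance explained is the top eigenvalue over the trace of the member
#' correlation matrix.
#'
#' @param expr samples x genes matrix.
#' @param assign a `module_assignment` (or a named integer/character label
#'   vector; 0/"grey" = unassigned).
#' @return an `eigengene_matrix`: list with `scores` (samples x modules,
#'   zero-mean columns named by module colour), `variance_explained`,
#'   `orientation_sign`, `module_colors`.
#' @export
module_eigengenes <- function(expr, assign) {
  labels <- if (inherits(assign, "module_assignment")) assign$labels else assign
  colors <- if (inherits(assign, "module_assignment")) {
    assign$colors
  } else {
    stats::setNames(ifelse(labels == 0, "grey", paste0("module_", labels)),
                    names(labels))
  }
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stop("no modules to summarise")
  scores <- matrix(NA_real_, nrow(expr), length(mods))
  varexp <- numeric(length(mods))
  osign <- integer(length(mods))
  mod_colors <- character(length(mods))
  for (i in seq_along(mods)) {
    members <- names(labels)[labels == mods[i]]
    members <- intersect(members, colnames(expr))
    if (length(members) < 1) stop(sprintf("module %s has no member in expr", mods[i]))
    sub <- expr[, members, drop = FALSE]
    sds <- apply(sub, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("excluding %d constant member gene(s) from module %s",
                      sum(sds == 0), mods[i]))
      sub <- sub[, sds > 0, drop = FALSE]
      if (ncol(sub) == 0) stop(sprintf("module %s has only constant members", mods[i]))
    }
    z <- scale(sub)
    sv <- svd(z, nu = 1, nv = 0)
    # scale by 1/sqrt(m) so a module of identical genes has eigengene equal
    # to the common z-profile, and duplicating members leaves it unchanged
    pc <- sv$u[, 1] * sv$d[1] / sqrt(ncol(z))
    s <- sign(stats::cor(pc, rowMeans(z)))
    if (is.na(s) || s == 0) s <- 1
    scores[, i] <- s * pc
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
    osign[i] <- as.integer(s)
    mod_colors[i] <- colors[names(labels)[labels == mods[i]][1]]
  }
  dimnames(scores) <- list(rownames(expr), mod_colors)
  structure(list(
    scores = scores,
    variance_explained = stats::setNames(varexp, mod_colors),
    orientation_sign = stats::setNames(osign, mod_colors),
    module_colors = stats::setNames(mod_colors, mods)
  ), class = "eigengene_matrix")
}

#' Module membership (kME)
#'
#' Pearson correlation of every gene with every module eigengene.
#'
#' @param expr samples x genes matrix.
#' @param eig an `eigengene_matrix`.
#' @return genes x modules correlation matrix; constant genes give NA with a
#'   warning.
#' @export
module_membership <- function(expr, eig) {
  stopifnot(inherits(eig, "eigengene_matrix"))
  mm <- suppressWarnings(stats::cor(expr, eig$scores))
  if (anyNA(mm)) warning("constant gene(s) produced undefined module membership")
  mm
}

#' Gene significance (gene-trait correlation)
#'
#' Pearson correlation of each gene's expression with each trait over
#' samples shared (by id) between the expression matrix and the trait table.
#'
#' @param expr samples x genes matrix with sample-id rownames.
#' @param traits a [trait_table()].
#' @return genes x traits correlation matrix.
#' @export
gene_significance <- function(expr, traits) {
  stopifnot(inherits(traits, "trait_table"))
  shared <- intersect(rownames(expr), traits$sample_ids)
  if (length(shared) < 3) stop("fewer than 3 shared samples between expression and traits")
  suppressWarnings(stats::cor(expr[shared, , drop = FALSE],
                              traits$traits[shared, , drop = FALSE],
                              use = "pairwise.complete.obs"))
}

#' GS-MM module quality check
#'
#' Correlates the magnitude of gene significance (|GS|) with module
#' membership (MM) over a module's member genes; high positive correlation
#' indicates that the genes most related to the trait are also the most
#' central module members.
#'
#' @param gs_col per-gene GS values (named by gene).
#' @param mm_col per-gene MM values for the module (named by gene).
#' @param member_genes member gene ids (>= 3).
#' @return list with `r_gs_mm`, `p`, `n`, and the aligned `gs`/`mm` vectors.
#' @export
gs_mm_quality <- function(gs_col, mm_col, member_genes) {
  if (length(member_genes) < 3) stop("need >= 3 member genes")
  gs <- abs(gs_col[member_genes])
  mm <- mm_col[member_genes]
  if (anyNA(gs) || anyNA(mm)) stop("GS/MM missing for some member genes")
  r <- stats::cor(gs, mm)
  m <- length(member_genes)
  p <- cor_test_p(r, m)
  list(r_gs_mm = r, p = p, n = m, gs = gs, mm = mm)
}

# Two-sided p for a Pearson correlation via the t distribution (df = n - 2);
# |r| = 1 maps to p = 0. Vectorized over r, with n recycled alongside.
cor_test_p <- function(r, n) {
  n <- rep_len(n, length(r))
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  rr <- pmin(1, pmax(-1, r[ok]))
  nn <- n[ok]
  pe <- numeric(length(rr))
  exact <- abs(rr) >= 1
  t_stat <- rr[!exact] * sqrt((nn[!exact] - 2) / (1 - rr[!exact]^2))
  pe[!exact] <- 2 * stats::pt(abs(t_stat), df = nn[!exact] - 2, lower.tail = FALSE)
  p[ok] <- pe
  p
}

#' Export a dendrogram as Newick
#'
#' @param dend an `hclust` object.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
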