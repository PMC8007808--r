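#' Gene-gene Pearson correlation matrix
#'
#' Pairwise Pearson correlations over pairwise-complete observations for all
#' gene pairs; the first network-construction step. Zero-variance genes yield
#' undefined correlations, which are set to 0 with a warning (such genes
#' should normally be dropped with [drop_constant_genes()] beforehand).
#'
#' @param expr samples x genes numeric matrix with sample/gene dimnames.
#' @return genes x genes correlation matrix, unit diagonal.
#' @export
correlation_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop("need >= 3 samples for correlations")
  if (anyNA(expr)) {
    obs <- crossprod(!is.na(expr))
    off <- obs[upper.tri(obs)]
    if (any(off < 3)) stop("some gene pairs have fewer than 3 shared observations")
    r <- suppressWarnings(stats::cor(expr, use = "pairwise.complete.obs"))
  } else {
    r <- suppressWarnings(stats::cor(expr))
  }
  if (anyNA(r)) {
    warning(sprintf("%d genes have zero variance; their correlations set to 0",
                    sum(is.na(diag(r)))))
    r[is.na(r)] <- 0
  }
  diag(r) <- 1
  r
}

#' Drop zero-variance genes before network construction
#'
#' @param expr samples x genes matrix.
#' @return the matrix without constant genes; reports how many were dropped.
#' @export
drop_constant_genes <- function(expr) {
  v <- apply(expr, 2, stats::var, na.rm = TRUE)
  bad <- !is.finite(v) | v == 0
  if (any(bad)) {
    message(sprintf("dropping %d zero-variance gene(s): %s", sum(bad),
                    paste(utils::head(colnames(expr)[bad], 5), collapse = ", ")))
    expr <- expr[, !bad, drop = FALSE]
  }
  expr
}

#' Soft-thresholded adjacency matrix
#'
#' Raises correlations to a soft power to de-emphasise weak co-expression.
#' The signed transform `((1 + r) / 2)^beta` maps negative correlations to
#' near-zero adjacency; the unsigned-absolute variant `|r|^beta` is available
#' for comparison. Default `beta = 10`.
#'
#' @param cor genes x genes correlation matrix.
#' @param beta soft-threshold power, integer >= 1.
#' @param mode `"signed"` (default) or `"unsigned"`.
#' @return adjacency matrix in \[0, 1\] with unit diagonal and attributes
#'   `beta` and `mode`.
#' @export
signed_adjacency <- function(cor, beta = 10, mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1) {
    stop("beta must be a single number >= 1")
  }
  a <- if (mode == "signed") ((1 + cor) / 2)^beta else abs(cor)^beta
  diag(a) <- 1
  attr(a, "beta") <- beta
  attr(a, "mode") <- mode
  a
}

#' Signed scale-free topology fit statistic
#'
#' Bins the connectivity distribution into equal-width bins, regresses
#' log10(frequency) on log10(mean bin connectivity) over non-empty bins, and
#' returns the regression R^2 multiplied by the negated sign of the slope, so
#' the statistic is positive only for decaying (scale-free-like) degree
#' distributions.
#'
#' @param connectivity vector of non-negative node connectivities.
#' @param n_bins number of equal-width bins (default 10).
#' @return a single number in \[-1, 1\], or `NA` when undefined (all
#'   connectivities equal, or < 2 usable bins).
#' @export
scale_free_fit <- function(connectivity, n_bins = 10) {
  k <- connectivity[is.finite(connectivity) & connectivity > 0]
  if (length(unique(k)) < 2) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 2) return(NA_real_)
  x <- log10(mean_k[keep])
  y <- log10(freq[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  unname(-sign(slope) * r2)
}

#' Choose a soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes node
#' connectivities `k_i = sum_{j != i} a_ij` and the signed scale-free fit
#' statistic; the chosen power is the smallest one whose fit reaches
#' `r2_cut`. If none qualifies the report falls back to power 10 with
#' `fallback = TRUE`.
#'
#' @param cor correlation matrix.
#' @param powers candidate integer powers (default 1:20).
#' @param r2_cut required fit (default 0.80).
#' @param mode adjacency mode, see [signed_adjacency()].
#' @param n_bins bins for [scale_free_fit()].
#' @return a `soft_threshold_report`: data.frame (`power`, `fit`,
#'   `mean_connectivity`) with attributes `chosen` and `fallback`.
#' @export
pick_soft_threshold <- function(cor, powers = 1:20, r2_cut = 0.80,
                                mode = "signed", n_bins = 10) {
  if (length(powers) == 0) stop("powers must be non-empty")
  rows <- lapply(powers, function(b) {
    a <- signed_adjacency(cor, beta = b, mode = mode)
    k <- rowSums(a) - 1
    data.frame(power = b, fit = scale_free_fit(k, n_bins = n_bins),
               mean_connectivity = mean(k))
  })
  report <- do.call(rbind, rows)
  passing <- which(!is.na(report$fit) & report$fit >= r2_cut)
  if (length(passing) > 0) {
    chosen <- report$power[min(passing)]
    fallback <- FALSE
  } else {
    chosen <- 10L
    fallback <- TRUE
  }
  structure(report, chosen = chosen, fallback = fallback,
            class = c("soft_threshold_report", "data.frame"))
}

#' Topological overlap matrix
#'
#' Similarity combining direct adjacency with shared-neighbour structure:
#' for i != j, `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k_i = sum_{u != i} a_iu`;
#' `TOM_ii = 1`.
#'
#' @param adj adjacency matrix with entries in \[0, 1\], unit diagonal.
#' @return genes x genes TOM in \[0, 1\].
#' @export
topological_overlap <- function(adj) {
  adj <- as.matrix(adj)
  if (any(adj < 0) || any(adj > 1)) stop("adjacency entries must be in [0, 1]")
  # With unit diagonal, (A %*% A)_ij includes the u = i and u = j terms,
  # each equal to a_ij, so L = A^2 - 2A off-diagonal.
  l <- adj %*% adj - 2 * adj
  k <- rowSums(adj) - 1
  denom <- outer(k, k, pmin) + 1 - adj
  tom <- (l + adj) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' TOM dissimilarity
#'
#' @param tom a topological overlap matrix.
#' @return `1 - tom`, with zero diagonal; the clustering input.
#' @export
tom_dissimilarity <- function(tom) {
  d <- 1 - tom
  diag(d) <- 0
  d
}
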