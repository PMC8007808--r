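#' Module-trait correlation screening
#'
#' Pearson correlation of every module eigengene with every trait, with
#' two-sided p from the t distribution (df = n - 2) and Bonferroni-adjusted
#' p. The default adjustment family is the full screen, modules x traits.
#'
#' @param eig an `eigengene_matrix`.
#' @param traits a [trait_table()].
#' @param family Bonferroni family size; default `modules * traits`.
#' @return a `module_trait_result`: list with matrices `r`, `p`, `p_adj`
#'   (modules x traits), `n` (pairwise-complete sample counts), `groups`,
#'   `family_size`.
#' @export
module_trait_correlations <- function(eig, traits, family = NULL) {
  stopifnot(inherits(eig, "eigengene_matrix"), inherits(traits, "trait_table"))
  shared <- intersect(rownames(eig$scores), traits$sample_ids)
  if (length(shared) < 4) stop("fewer than 4 shared samples")
  me <- eig$scores[shared, , drop = FALSE]
  tr <- traits$traits[shared, , drop = FALSE]
  r <- t(suppressWarnings(stats::cor(me, tr, use = "pairwise.complete.obs")))
  n_obs <- t(crossprod(!is.na(me), !is.na(tr)))
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  for (j in seq_len(ncol(r))) p[, j] <- cor_test_p(r[, j], n_obs[, j])
  r <- t(r); p <- t(p) # modules x traits
  if (is.null(family)) family <- length(r)
  structure(list(
    r = r, p = p, p_adj = pmin(p * family, 1),
    n = t(n_obs), groups = traits$groups, family_size = family
  ), class = "module_trait_result")
}

#' @export
print.module_trait_result <- function(x, ...) {
  cat(sprintf("module_trait_result: %d modules x %d traits (Bonferroni family %d)\n",
              nrow(x$r), ncol(x$r), x$family_size))
  invisible(x)
}

#' Select candidate dual-disease modules
#'
#' A module is a candidate when it has at least one significantly correlated
#' trait (Bonferroni-adjusted p < alpha) in each disease group, i.e. at
#' least one osteoporosis trait and at least one atherosclerosis trait.
#'
#' @param res a `module_trait_result`.
#' @param alpha significance level (default 0.05).
#' @return a `candidate_selection`: list with `selected` (module names),
#'   `trait_pairs` (data.frame module/osteo/athero), `alpha`, `rule`.
#' @export
select_candidate_modules <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "module_trait_result"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  groups <- res$groups[colnames(res$p_adj)]
  if (anyNA(groups)) stop("trait group map is missing some traits")
  osteo <- groups == "osteo"
  sig <- res$p_adj < alpha
  selected <- rownames(res$p_adj)[
    rowSums(sig[, osteo, drop = FALSE], na.rm = TRUE) > 0 &
    rowSums(sig[, !osteo, drop = FALSE], na.rm = TRUE) > 0
  ]
  pairs <- do.call(rbind, lapply(selected, function(m) {
    pr <- select_trait_pair(m, res)
    data.frame(module = m, osteo = pr[["osteo"]], athero = pr[["athero"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(
    selected = selected,
    trait_pairs = pairs,
    alpha = alpha,
    rule = ">=1 Bonferroni-significant trait in each disease group"
  ), class = "candidate_selection")
}

#' Pick a module's most significant trait per disease group
#'
#' Returns, for each disease group, the trait with the smallest adjusted p
#' for the given module; ties are broken by smaller raw p, then by trait
#' column order.
#'
#' @param module module name (rowname of the result matrices).
#' @param res a `module_trait_result`.
#' @return named character vector `c(osteo = ..., athero = ...)`.
#' @export
select_trait_pair <- function(module, res) {
  stopifnot(inherits(res, "module_trait_result"))
  if (!module %in% rownames(res$p_adj)) stop(sprintf("unknown module '%s'", module))
  groups <- res$groups[colnames(res$p_adj)]
  pick <- function(group) {
    idx <- which(groups == group)
    pa <- res$p_adj[module, idx]
    pr <- res$p[module, idx]
    if (all(is.na(pa))) stop(sprintf("module '%s' has no usable %s cells", module, group))
    ord <- order(pa, pr, seq_along(idx))
    colnames(res$p_adj)[idx[ord[1]]]
  }
  c(osteo = pick("osteo"), athero = pick("athero"))
}

#' Long-format export of a module-trait screen
#'
#' @param res a `module_trait_result`.
#' @return data.frame with columns module, trait, group, r, p, p_adj, n.
#' @export
module_trait_long <- function(res) {
  stopifnot(inherits(res, "module_trait_result"))
  grid <- expand.grid(module = rownames(res$r), trait = colnames(res$r),
                      stringsAsFactors = FALSE)
  grid$group <- unname(res$groups[grid$trait])
  grid$r <- res$r[cbind(grid$module, grid$trait)]
  grid$p <- res$p[cbind(grid$module, grid$trait)]
  grid$p_adj <- res$p_adj[cbind(grid$module, grid$trait)]
  grid$n <- res$n[cbind(grid$module, grid$trait)]
  grid[order(grid$module, grid$trait), ]
}
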