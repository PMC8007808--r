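#' Hypothesis and error SSCP matrices for a single predictor term
#'
#' Least-squares multivariate fit of a bivariate (or p-variate) outcome on a
#' design containing intercept, covariates and the predictor of interest.
#' The error SSCP `E` is the residual cross-product of the full model; the
#' hypothesis SSCP `H` is the Type-II extra SSCP of adding the predictor to
#' the covariate-only model (for a single added column this is
#' order-independent and equals the Type-III SSCP).
#'
#' @param Y n x p outcome matrix (complete cases only).
#' @param X_full full design matrix including an intercept column.
#' @param predictor_col column index (or name) of the predictor in `X_full`.
#' @return list with `H`, `E` (p x p), `v` (error df = n - rank(X_full)),
#'   `df_h` (hypothesis df, 1 per predictor column).
#' @export
fit_mlm_sscp <- function(Y, X_full, predictor_col) {
  Y <- as.matrix(Y)
  X_full <- as.matrix(X_full)
  n <- nrow(Y)
  if (nrow(X_full) != n) stop("Y and X_full must have the same rows")
  if (is.character(predictor_col)) {
    predictor_col <- match(predictor_col, colnames(X_full))
  }
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    bad <- qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]
    nm <- colnames(X_full)
    if (is.null(nm)) nm <- paste0("X", seq_len(ncol(X_full)))
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(nm[bad], collapse = ", ")))
  }
  if (n <= qr_full$rank + ncol(Y)) stop("too few complete cases for the design")
  res_full <- qr.resid(qr_full, Y)
  E <- crossprod(res_full)
  X0 <- X_full[, -predictor_col, drop = FALSE]
  res_red <- qr.resid(qr(X0), Y)
  H <- crossprod(res_red) - E
  list(H = H, E = E, v = n - qr_full$rank,
       df_h = length(predictor_col))
}

#' Pillai's trace
#'
#' `V = trace(H (H + E)^-1)` for hypothesis and error SSCP matrices; ranges
#' from 0 to `min(p, df_h)`, larger values meaning a stronger multivariate
#' effect.
#'
#' @param H,E symmetric SSCP matrices; `H + E` must be invertible.
#' @return the Pillai-Bartlett trace statistic.
#' @export
pillai_trace <- function(H, E) {
  T_mat <- H + E
  if (abs(det(T_mat)) < .Machine$double.xmin) stop("singular H + E")
  sum(diag(H %*% solve(T_mat)))
}

#' F approximation for Pillai's trace
#'
#' Standard Pillai-Bartlett F transform. With `s = min(p_resp, df_h)`,
#' `m = (|p_resp - df_h| - 1)/2`, `n' = (v - p_resp - 1)/2`:
#' `df1 = s(2m + s + 1)`, `df2 = s(2n' + s + 1)`,
#' `F = (df2/df1) V/(s - V)`. The transform is exact (not approximate) when
#' `s = 1`, which holds for every single-predictor test in this pipeline.
#'
#' @param V Pillai's trace.
#' @param p_resp number of response variables.
#' @param df_h hypothesis degrees of freedom.
#' @param v error degrees of freedom (> p_resp).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
pillai_f_test <- function(V, p_resp, df_h, v) {
  if (v <= p_resp) stop("error df must exceed the number of responses")
  s <- min(p_resp, df_h)
  if (V < 0 || V > s + 1e-12) stop("V must be in [0, s]")
  m <- (abs(p_resp - df_h) - 1) / 2
  n_prime <- (v - p_resp - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n_prime + s + 1)
  if (V >= s) {
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  F_stat <- (df2 / df1) * V / (s - V)
  list(F = F_stat, df1 = df1, df2 = df2,
       p = stats::pf(F_stat, df1, df2, lower.tail = FALSE))
}

# Covariate sets of the three adjustment models.
model_covariates <- function(model) {
  switch(as.character(model),
         "1" = character(0),
         "2" = c("age", "sex", "bmi"),
         "3" = c("age", "sex", "bmi", "smoking", "alcohol", "physical_activity"),
         stop("model must be 1, 2 or 3"))
}

# One Pillai test of `predictor` against the bivariate outcome, on complete
# cases. y2: n x 2 matrix; covars: data.frame or NULL.
pillai_single_test <- function(y2, predictor, covars = NULL) {
  X <- cbind(`(Intercept)` = 1, predictor = predictor)
  if (!is.null(covars) && ncol(covars) > 0) {
    X <- cbind(X, as.matrix(covars))
  }
  cc <- stats::complete.cases(cbind(y2, X))
  Y <- as.matrix(y2)[cc, , drop = FALSE]
  X <- X[cc, , drop = FALSE]
  fit <- fit_mlm_sscp(Y, X, predictor_col = 2)
  V <- pillai_trace(fit$H, fit$E)
  ft <- pillai_f_test(V, p_resp = ncol(Y), df_h = fit$df_h, v = fit$v)
  data.frame(pillai = V, F = ft$F, df1 = ft$df1, df2 = ft$df2, p = ft$p,
             n_used = sum(cc))
}

#' Joint association of candidate modules with a bivariate trait outcome
#'
#' For each candidate module, tests the joint association of its eigengene
#' with the module's selected (osteoporosis, atherosclerosis) trait pair via
#' Pillai's trace, under three adjustment models: model 1 unadjusted; model 2
#' adjusted for age, sex and BMI; model 3 additionally for smoking, alcohol
#' and physical activity. P-values are Bonferroni-adjusted within each model
#' over the candidate modules.
#'
#' @param eig an `eigengene_matrix`.
#' @param sel a `candidate_selection`.
#' @param traits a [trait_table()].
#' @param models subset of 1:3 to run.
#' @param alpha,suggestive_alpha thresholds for the `significance` flag
#'   (default 0.05 significant, 0.25 suggestive).
#' @return data.frame with one row per module x model: module, model,
#'   osteo_trait, athero_trait, pillai, F, df1, df2, p, p_adj, n_used,
#'   family_size, significance.
#' @export
module_joint_association <- function(eig, sel, traits, models = 1:3,
                                     alpha = 0.05, suggestive_alpha = 0.25) {
  stopifnot(inherits(eig, "eigengene_matrix"),
            inherits(sel, "candidate_selection"),
            inherits(traits, "trait_table"))
  if (length(sel$selected) == 0) {
    return(data.frame(module = character(0), model = integer(0),
                      osteo_trait = character(0), athero_trait = character(0),
                      pillai = numeric(0), F = numeric(0), df1 = numeric(0),
                      df2 = numeric(0), p = numeric(0), p_adj = numeric(0),
                      n_used = integer(0), family_size = integer(0),
                      significance = character(0)))
  }
  shared <- intersect(rownames(eig$scores), traits$sample_ids)
  family <- length(sel$selected)
  out <- list()
  for (model in models) {
    cov_names <- model_covariates(model)
    missing_cov <- setdiff(cov_names, colnames(traits$covariates))
    if (length(missing_cov) > 0) {
      stop(sprintf("model %d covariate(s) absent: %s", model,
                   paste(missing_cov, collapse = ", ")))
    }
    covars <- if (length(cov_names)) {
      traits$covariates[shared, cov_names, drop = FALSE]
    } else NULL
    for (mod in sel$selected) {
      pair <- sel$trait_pairs[sel$trait_pairs$module == mod, ]
      y2 <- traits$traits[shared, c(pair$osteo, pair$athero), drop = FALSE]
      row <- pillai_single_test(y2, eig$scores[shared, mod], covars)
      row <- cbind(data.frame(module = mod, model = model,
                              osteo_trait = pair$osteo,
                              athero_trait = pair$athero), row)
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$p_adj <- pmin(1, res$p * family)
  res$family_size <- family
  res$significance <- ifelse(res$p_adj < alpha, "significant",
                             ifelse(res$p_adj < suggestive_alpha,
                                    "suggestive", "ns"))
  rownames(res) <- NULL
  res
}

#' Joint association of a module's member genes with its trait pair
#'
#' Runs the Pillai test with each member gene's expression as the predictor,
#' under the same three adjustment models, Bonferroni-adjusting within each
#' model over the module's size. Output is sorted by adjusted p within each
#' model and carries a rank column, so the top gene per model is row rank 1.
#'
#' @param expr samples x genes matrix.
#' @param module module label or colour.
#' @param assign a `module_assignment`.
#' @param pair named character vector `c(osteo = ..., athero = ...)`.
#' @param traits a [trait_table()].
#' @param models subset of 1:3.
#' @return data.frame: module, model, gene, pillai, F, df1, df2, p, p_adj,
#'   n_used, family_size, rank.
#' @export
gene_joint_association <- function(expr, module, assign, pair, traits,
                                   models = 1:3) {
  stopifnot(inherits(traits, "trait_table"))
  members <- module_members(assign, module)
  if (length(members) == 0) stop("module has no members")
  absent <- setdiff(members, colnames(expr))
  if (length(absent) > 0) {
    warning(sprintf("skipping %d gene(s) absent from expression matrix", length(absent)))
    members <- setdiff(members, absent)
  }
  shared <- intersect(rownames(expr), traits$sample_ids)
  y2 <- traits$traits[shared, c(pair[["osteo"]], pair[["athero"]]), drop = FALSE]
  family <- length(members)
  out <- list()
  for (model in models) {
    cov_names <- model_covariates(model)
    covars <- if (length(cov_names)) {
      traits$covariates[shared, cov_names, drop = FALSE]
    } else NULL
    rows <- lapply(members, function(g) {
      cbind(data.frame(module = as.character(module), model = model, gene = g),
            pillai_single_test(y2, expr[shared, g], covars))
    })
    block <- do.call(rbind, rows)
    block$p_adj <- pmin(1, block$p * family)
    block <- block[order(block$p_adj, block$p), ]
    block$rank <- seq_len(nrow(block))
    out[[length(out) + 1]] <- block
  }
  res <- do.call(rbind, out)
  res$family_size <- family
  rownames(res) <- NULL
  res
}
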