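test_that("SSCP fit matches the projection oracle and flags rank problems", {
  set.seed(41)
  n <- 40
  Y <- matrix(stats::rnorm(2 * n), n, 2)
  x <- stats::rnorm(n)
  X <- cbind(1, x)
  fit <- fit_mlm_sscp(Y, X, predictor_col = 2)
  # no-covariate oracle: H = regression SSCP of Y on the centred predictor,
  # via the explicit projection matrix
  xc <- x - mean(x)
  P <- outer(xc, xc) / sum(xc^2)
  H_oracle <- t(Y) %*% P %*% Y
  expect_equal(fit$H, H_oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$v, n - 2)
  # E + H equals the intercept-only residual SSCP
  Yc <- scale(Y, scale = FALSE)
  expect_equal(fit$E + fit$H, crossprod(Yc), tolerance = 1e-10,
               ignore_attr = TRUE)

  # predictor orthogonal to Y: H ~ 0
  Y_orth <- qr.resid(qr(cbind(1, x)), Y)
  fit_o <- fit_mlm_sscp(Y_orth, X, predictor_col = 2)
  expect_lt(max(abs(fit_o$H)), 1e-10)

  # duplicated covariate column raises a rank error naming the column
  Xd <- cbind(`(Intercept)` = 1, predictor = x, bmi = x)
  expect_error(fit_mlm_sscp(Y, Xd, 2), "collinear")
})

test_that("Pillai's trace matches the eigen-decomposition oracle", {
  expect_equal(pillai_trace(matrix(0, 2, 2), random_sscp(1)), 0)
  for (s in 1:10) {
    H <- random_sscp(s)
    E <- random_sscp(s + 100)
    V <- pillai_trace(H, E)
    ev <- eigen(H %*% solve(H + E), only.values = TRUE)$values
    expect_equal(V, sum(Re(ev)), tolerance = 1e-8)
    expect_gte(V, 0)
    expect_lte(V, 2)
  }
  # E -> 0 with full-rank H: V -> 2
  H <- random_sscp(3)
  expect_equal(pillai_trace(H, H * 1e-12), 2, tolerance = 1e-6)
})

test_that("Pillai F transform has its boundary behaviour and exactness", {
  ft0 <- pillai_f_test(0, p_resp = 2, df_h = 1, v = 30)
  expect_equal(ft0$F, 0)
  expect_equal(ft0$p, 1)
  expect_equal(pillai_f_test(1, 2, 1, 30)$p, 0) # V = s boundary
  expect_error(pillai_f_test(0.5, 2, 1, v = 2), "error df")

  # p_resp = 1 degenerate case: F equals the univariate partial F
  set.seed(43)
  n <- 50
  y <- stats::rnorm(n)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  X <- cbind(`(Intercept)` = 1, predictor = x, z = z)
  fit <- fit_mlm_sscp(matrix(y), X, 2)
  V <- pillai_trace(fit$H, fit$E)
  ft <- pillai_f_test(V, p_resp = 1, df_h = 1, v = fit$v)
  full <- stats::lm(y ~ x + z)
  red <- stats::lm(y ~ z)
  partial_f <- stats::anova(red, full)
  expect_equal(ft$F, partial_f$F[2], tolerance = 1e-8)
  expect_equal(ft$p, partial_f$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("Pillai pipeline agrees with anova.mlm and the Hotelling route", {
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    Y <- matrix(stats::rnorm(2 * n), n, 2)
    x <- stats::rnorm(n)
    z <- stats::rnorm(n)
    fit <- fit_mlm_sscp(Y, cbind(1, x, z), 2)
    V <- pillai_trace(fit$H, fit$E)
    ft <- pillai_f_test(V, 2, 1, fit$v)
    # independent oracle 1: stats::anova.mlm with the predictor fitted last
    ref <- stats::anova(stats::lm(Y ~ z + x), test = "Pillai")
    expect_equal(V, ref["x", "Pillai"], tolerance = 1e-10)
    expect_equal(ft$F, ref["x", "approx F"], tolerance = 1e-8)
    expect_equal(ft$p, ref["x", "Pr(>F)"], tolerance = 1e-8)
    # independent oracle 2: for s = 1 the Hotelling route is equivalent,
    # F = lambda (v - p + 1) / p with lambda = tr(H E^-1)
    lambda <- sum(diag(fit$H %*% solve(fit$E)))
    F_hot <- lambda * (fit$v - 2 + 1) / 2
    p_hot <- stats::pf(F_hot, 2, fit$v - 1, lower.tail = FALSE)
    expect_equal(ft$p, p_hot, tolerance = 1e-8)
  }
})

test_that("a covariate orthogonal to predictor and responses only costs df", {
  set.seed(44)
  n <- 60
  Y <- matrix(stats::rnorm(2 * n), n, 2)
  x <- stats::rnorm(n)
  # build z orthogonal to intercept, x and both Y columns
  z <- qr.resid(qr(cbind(1, x, Y)), stats::rnorm(n))
  f1 <- fit_mlm_sscp(Y, cbind(1, x), 2)
  f2 <- fit_mlm_sscp(Y, cbind(1, x, z), 2)
  expect_equal(f1$H, f2$H, tolerance = 1e-10)
  expect_equal(f1$E, f2$E, tolerance = 1e-10)
  expect_equal(f2$v, f1$v - 1)
  V <- pillai_trace(f1$H, f1$E)
  t1 <- pillai_f_test(V, 2, 1, f1$v)
  t2 <- pillai_f_test(V, 2, 1, f2$v)
  expect_equal(t2$F / t1$F, t2$df2 / t1$df2, tolerance = 1e-12)
})

test_that("module joint association flags the planted dual module", {
  d <- generate_dataset(small_config(seed = 45, n_samples = 300))
  eig <- truth_eigengenes(d)
  mt <- module_trait_correlations(eig, d$traits)
  sel <- select_candidate_modules(mt)
  res <- module_joint_association(eig, sel, d$traits)
  expect_equal(nrow(res), 3 * length(sel$selected))
  m1 <- res[res$module == "module_1", ]
  expect_true(all(m1$significance == "significant"))
  expect_true(all(res$p_adj >= res$p))
  expect_true(all(res$pillai >= 0 & res$pillai <= 1))
  # model 3 must error when covariates are absent
  tt <- d$traits
  tt$covariates <- tt$covariates[, "age", drop = FALSE]
  expect_error(module_joint_association(eig, sel, tt, models = 3), "absent")
})

test_that("empty candidate selection yields an empty table", {
  d <- generate_dataset(small_config(seed = 46, n_samples = 100))
  eig <- truth_eigengenes(d)
  sel <- structure(list(selected = character(0), trait_pairs = NULL,
                        alpha = 0.05, rule = ""), class = "candidate_selection")
  res <- module_joint_association(eig, sel, d$traits)
  expect_equal(nrow(res), 0)
})

test_that("gene-level tests mirror the module test and family adjustment", {
  d <- generate_dataset(small_config(seed = 47, n_samples = 200))
  labels <- d$truth$gene_module_labels
  # single-gene module: gene-level model-1 result equals the module-level
  # result when the eigengene is that gene's z-profile
  one <- stats::setNames(1L, names(labels)[1])
  eig1 <- module_eigengenes(d$expression, one)
  asg1 <- structure(list(
    labels = one,
    colors = stats::setNames("module_1", names(one)),
    module_sizes = table(1L)), class = "module_assignment")
  pair <- c(osteo = "DRToBMC", athero = "CIMTavg")
  sel1 <- structure(list(selected = colnames(eig1$scores)[1],
                         trait_pairs = data.frame(
                           module = colnames(eig1$scores)[1],
                           osteo = "DRToBMC", athero = "CIMTavg")),
                    class = "candidate_selection")
  mod_res <- module_joint_association(eig1, sel1, d$traits, models = 1)
  gene_res <- gene_joint_association(d$expression, 1L, asg1, pair,
                                     d$traits, models = 1)
  expect_equal(gene_res$pillai, mod_res$pillai, tolerance = 1e-10)
  expect_equal(gene_res$F, mod_res$F, tolerance = 1e-10)
  expect_equal(gene_res$p, mod_res$p, tolerance = 1e-10)

  # Bonferroni family = module size; ranking is by adjusted p
  asg <- structure(list(
    labels = labels,
    colors = stats::setNames(ifelse(labels == 0, "grey",
                                    paste0("module_", labels)), names(labels)),
    module_sizes = table(labels[labels > 0])), class = "module_assignment")
  gr <- gene_joint_association(d$expression, "module_1", asg, pair,
                               d$traits, models = 1)
  expect_equal(unique(gr$family_size), 25)
  expect_equal(gr$p_adj, pmin(gr$p * 25, 1))
  expect_false(is.unsorted(gr$p_adj))
  expect_equal(gr$rank, seq_len(25))
})

test_that("a gene driving the traits directly ranks at the top", {
  hits <- vapply(1:50, function(s) {
    cfg <- simulation_config(
      n_samples = 250, module_sizes = 15, n_background = 10,
      trait_effects = default_trait_effects(1), seed = s)
    d <- generate_dataset(cfg)
    labels <- d$truth$gene_module_labels
    # rewire two traits so gene g1 drives them directly
    tt <- d$traits
    set.seed(s + 5000)
    g1 <- d$expression[, names(labels)[1]]
    tt$traits[, "DRToBMC"] <- 0.8 * g1 + stats::rnorm(250)
    tt$traits[, "CIMTavg"] <- 0.8 * g1 + stats::rnorm(250)
    asg <- structure(list(
      labels = labels,
      colors = stats::setNames(ifelse(labels == 0, "grey", "module_1"),
                               names(labels)),
      module_sizes = table(labels[labels > 0])), class = "module_assignment")
    gr <- gene_joint_association(d$expression, "module_1", asg,
                                 c(osteo = "DRToBMC", athero = "CIMTavg"),
                                 tt, models = 1)
    which(gr$gene == names(labels)[1]) <= 3
  }, logical(1))
  expect_gte(sum(hits), 45)
})
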