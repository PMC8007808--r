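#' Default trait layout
#'
#' Ten early-disease traits: four ultrasound intima-media thickness traits
#' (atherosclerosis group) followed by six pQCT bone traits (osteoporosis
#' group). Acronyms follow the field's conventions, e.g. `CIMTavg` = average
#' carotid intima-media thickness, `DRToBMC` = distal radius total bone
#' mineral content.
#'
#' @return `default_trait_names()`: character vector of 10 trait acronyms.
#' @export
default_trait_names <- function() {
  c("CIMTavg", "CIMTmax", "BIMTavg", "BIMTmax",
    "DRTrD", "DTTrD", "DRToBMC", "RSCoBMC", "DTToBMC", "TSCoBMC")
}

#' @rdname default_trait_names
#' @return `default_trait_groups()`: named character vector mapping each trait
#'   to `"athero"` or `"osteo"`.
#' @export
default_trait_groups <- function() {
  stats::setNames(c(rep("athero", 4), rep("osteo", 6)), default_trait_names())
}

covariate_names <- function() {
  c("age", "sex", "bmi", "smoking", "alcohol", "physical_activity")
}

#' Default module-to-trait effect matrix
#'
#' Traits x modules matrix of linear effects of the latent module factors on
#' the traits. The default plants one dual-disease driver module (module 1,
#' wired to two osteoporosis and two atherosclerosis traits), one
#' osteoporosis-only module (module 2) and leaves any further modules
#' trait-null, mirroring the screening problem the pipeline is built for.
#'
#' @param n_modules number of planted modules (columns).
#' @param effect effect size used for the wired entries (default 0.5, a
#'   moderate effect against unit factor and unit trait-noise variance).
#' @return numeric matrix with `length(default_trait_names())` rows.
#' @export
default_trait_effects <- function(n_modules = 3, effect = 0.5) {
  eff <- matrix(0, nrow = 10, ncol = n_modules,
                dimnames = list(default_trait_names(), NULL))
  if (n_modules >= 1) {
    eff[c("CIMTavg", "BIMTmax", "DRToBMC", "TSCoBMC"), 1] <- effect
  }
  if (n_modules >= 2) {
    eff[c("DRTrD", "DTTrD"), 2] <- effect
  }
  eff
}

#' Simulation configuration for planted-module expression data
#'
#' Validates and assembles the parameters of the synthetic-data generator.
#' The generator plants `length(module_sizes)` co-expression modules: each
#' module has one latent factor per sample and each member gene is the factor
#' scaled by a gene-specific loading plus Gaussian noise; background genes are
#' pure noise. Traits are linear combinations of module factors and
#' covariates plus noise.
#'
#' @param n_samples number of simulated participants (>= 10).
#' @param module_sizes integer vector, genes per planted module (all >= 1).
#' @param n_background number of unassigned pure-noise genes (>= 0).
#' @param loading_range interval within (0, 1] that gene loadings are drawn
#'   from uniformly.
#' @param noise_sd residual SD of gene expression (> 0).
#' @param trait_effects traits x modules effect matrix (rows must match
#'   `trait_names`); see [default_trait_effects()].
#' @param covariate_effects traits x covariates effect matrix (age, sex, bmi,
#'   smoking, alcohol, physical_activity), applied to raw covariate values.
#' @param factor_covariate_loadings optional modules x covariates matrix of
#'   loadings of standardized covariates on the module factors; used to build
#'   confounded scenarios where a module-trait association is carried
#'   entirely by a covariate such as BMI.
#' @param trait_noise_sd residual SD of traits (> 0).
#' @param trait_names,trait_groups trait layout; defaults to the 4 + 6
#'   atherosclerosis/osteoporosis layout of [default_trait_names()].
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 500,
                              module_sizes = c(50, 30, 20),
                              n_background = 1400,
                              loading_range = c(0.4, 0.9),
                              noise_sd = 1,
                              trait_effects = default_trait_effects(length(module_sizes)),
                              covariate_effects = NULL,
                              factor_covariate_loadings = NULL,
                              trait_noise_sd = 1,
                              trait_names = default_trait_names(),
                              trait_groups = default_trait_groups(),
                              seed = 1) {
  n_modules <- length(module_sizes)
  if (is.null(covariate_effects)) {
    covariate_effects <- matrix(0, length(trait_names), 6,
                                dimnames = list(trait_names, covariate_names()))
  }
  if (is.null(factor_covariate_loadings)) {
    factor_covariate_loadings <- matrix(0, n_modules, 6,
                                        dimnames = list(NULL, covariate_names()))
  }
  check_that(
    "n_samples must be >= 10" = is.numeric(n_samples) && n_samples >= 10,
    "module_sizes must be a non-empty vector of positive integers" =
      length(module_sizes) >= 1 && all(module_sizes >= 1),
    "n_background must be non-negative" = n_background >= 0,
    "loading_range must be an interval within (0, 1]" =
      length(loading_range) == 2 && loading_range[1] > 0 &&
      loading_range[2] <= 1 && loading_range[1] <= loading_range[2],
    "noise_sd must be positive" = noise_sd > 0,
    "trait_noise_sd must be positive" = trait_noise_sd > 0,
    "trait_effects must have one row per trait" =
      nrow(trait_effects) == length(trait_names),
    "trait_effects must have one column per module" =
      ncol(trait_effects) == n_modules,
    "covariate_effects must be traits x 6 covariates" =
      all(dim(covariate_effects) == c(length(trait_names), 6)),
    "factor_covariate_loadings must be modules x 6 covariates" =
      all(dim(factor_covariate_loadings) == c(n_modules, 6)),
    "every trait needs a group" = all(trait_names %in% names(trait_groups)),
    "trait groups must be 'osteo' or 'athero'" =
      all(trait_groups %in% c("osteo", "athero"))
  )
  rownames(trait_effects) <- trait_names
  structure(list(
    n_samples = as.integer(n_samples),
    module_sizes = as.integer(module_sizes),
    n_background = as.integer(n_background),
    loading_range = loading_range,
    noise_sd = noise_sd,
    trait_effects = trait_effects,
    covariate_effects = covariate_effects,
    factor_covariate_loadings = factor_covariate_loadings,
    trait_noise_sd = trait_noise_sd,
    trait_names = trait_names,
    trait_groups = trait_groups[trait_names],
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Trait table
#'
#' Container pairing per-sample disease traits (with their osteo/athero group
#' map) and adjustment covariates.
#'
#' @param traits samples x traits numeric matrix with rownames = sample ids.
#' @param covariates data.frame of covariates aligned to the same samples.
#' @param groups named character vector mapping traits to "osteo"/"athero".
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(traits, covariates, groups) {
  check_that(
    "traits must be a matrix with sample rownames" =
      is.matrix(traits) && !is.null(rownames(traits)),
    "covariates must align with traits" =
      nrow(covariates) == nrow(traits),
    "every trait column needs a group" =
      all(colnames(traits) %in% names(groups)),
    "groups must be 'osteo' or 'athero'" =
      all(groups %in% c("osteo", "athero"))
  )
  structure(list(
    sample_ids = rownames(traits),
    traits = traits,
    groups = groups[colnames(traits)],
    covariates = covariates
  ), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d samples, %d traits (%d osteo, %d athero), %d covariates\n",
              nrow(x$traits), ncol(x$traits), sum(x$groups == "osteo"),
              sum(x$groups == "athero"), ncol(x$covariates)))
  invisible(x)
}

# Covariate marginals approximate the cohort's descriptives: age uniform on
# 30-45 y, 56% female, BMI ~ N(25.7, 4.4^2) kg/m^2, 14% daily smokers,
# right-skewed alcohol (units/day), physical activity ~ N(19.8, 21^2) MET-h/wk
# truncated at 0.
draw_covariates <- function(n) {
  data.frame(
    age = stats::runif(n, 30, 45),
    sex = stats::rbinom(n, 1, 0.56),
    bmi = stats::rnorm(n, 25.7, 4.4),
    smoking = stats::rbinom(n, 1, 0.14),
    alcohol = stats::rlnorm(n, meanlog = log(0.6), sdlog = 0.8),
    physical_activity = pmax(0, stats::rnorm(n, 19.8, 21))
  )
}

#' Generate a planted-module expression dataset
#'
#' Simulates an expression matrix with planted co-expression modules, a trait
#' table with known module-to-trait effects and covariates, and the planted
#' ground truth. All randomness comes from one RNG stream seeded with
#' `config$seed`; draws are consumed in a fixed order (covariates, factors,
#' loadings, expression noise, trait noise), so equal seeds give bit-identical
#' outputs.
#'
#' Expression model: for gene g in module m(g), `x_sg = beta_g * f_sm + eps`,
#' `beta_g ~ U(loading_range)`, `eps ~ N(0, noise_sd^2)`; background genes are
#' pure noise. Trait model: `y_st = sum_m gamma_tm f_sm + sum_c delta_tc z_sc
#' + eta`, `eta ~ N(0, trait_noise_sd^2)`. Traits are therefore on a
#' standardized (unitless) scale; only their correlation/association
#' structure is meaningful.
#'
#' @param config a [simulation_config()].
#' @return list with components `expression` (samples x genes matrix),
#'   `traits` (a [trait_table()]), and `truth` (class `planted_truth`:
#'   `gene_module_labels`, `factor_scores`, `trait_effects`,
#'   `driver_modules`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sizes <- config$module_sizes
  n_modules <- length(sizes)
  n_genes <- sum(sizes) + config$n_background
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  covariates <- draw_covariates(n)
  z_std <- scale(as.matrix(covariates))

  # Factors: optionally load on standardized covariates (confounding
  # scenarios); residual variance tops the factor variance up to ~1.
  lambda <- config$factor_covariate_loadings
  factor_scores <- matrix(0, n, n_modules)
  for (m in seq_len(n_modules)) {
    lam <- lambda[m, ]
    resid_var <- max(0, 1 - sum(lam^2))
    factor_scores[, m] <- drop(z_std %*% lam) +
      sqrt(resid_var) * stats::rnorm(n)
  }
  colnames(factor_scores) <- paste0("factor_", seq_len(n_modules))
  rownames(factor_scores) <- sample_ids

  labels <- c(rep(seq_len(n_modules), times = sizes),
              rep(0L, config$n_background))
  names(labels) <- gene_ids
  loadings <- stats::runif(sum(sizes), config$loading_range[1],
                           config$loading_range[2])

  signal <- factor_scores[, labels[seq_len(sum(sizes))], drop = FALSE] *
    rep(loadings, each = n)
  expr <- cbind(signal, matrix(0, n, config$n_background)) +
    matrix(stats::rnorm(n * n_genes, sd = config$noise_sd), n, n_genes)
  dimnames(expr) <- list(sample_ids, gene_ids)

  traits <- factor_scores %*% t(config$trait_effects) +
    as.matrix(covariates) %*% t(config$covariate_effects) +
    matrix(stats::rnorm(n * length(config$trait_names),
                        sd = config$trait_noise_sd),
           n, length(config$trait_names))
  colnames(traits) <- config$trait_names
  rownames(traits) <- sample_ids
  rownames(covariates) <- sample_ids

  gamma <- config$trait_effects
  osteo <- config$trait_groups == "osteo"
  driver <- which(colSums(gamma[osteo, , drop = FALSE] != 0) > 0 &
                  colSums(gamma[!osteo, , drop = FALSE] != 0) > 0)

  truth <- structure(list(
    gene_module_labels = labels,
    factor_scores = factor_scores,
    loadings = stats::setNames(loadings, gene_ids[seq_len(sum(sizes))]),
    trait_effects = gamma,
    driver_modules = driver
  ), class = "planted_truth")

  list(expression = expr,
       traits = trait_table(traits, covariates, config$trait_groups),
       truth = truth)
}

#' Bone mineral content from pQCT area and density
#'
#' Mineral content (mg) of a tomographic bone slice, computed as
#' `0.2 * (area / 100) * density` from the cross-sectional area (mm^2) and
#' volumetric density (mg/cm^3); the 0.2 factor reflects the 2 mm slice
#' thickness.
#'
#' @param area cross-sectional bone area in mm^2 (>= 0).
#' @param density volumetric mineral density in mg/cm^3 (>= 0).
#' @return mineral content in mg; vectorized with recycling.
#' @export
compute_mineral_content <- function(area, density) {
  if (any(area < 0, na.rm = TRUE) || any(density < 0, na.rm = TRUE)) {
    stop("area and density must be non-negative")
  }
  0.2 * (area / 100) * density
}

#' Generate a matched gene-set collection for a planted truth
#'
#' Builds a GMT-writable collection with one "true" set per planted module
#' (an `overlap_fraction` sample of the module's genes plus random filler
#' genes, keeping the set size equal to the module size) and `n_decoy_sets`
#' random decoy sets, so enrichment recovery can be tested against known
#' ground truth.
#'
#' @param truth a `planted_truth` from [generate_dataset()].
#' @param n_decoy_sets number of random decoy sets (>= 0).
#' @param overlap_fraction fraction of each module's genes included in its
#'   true set, in \[0, 1\].
#' @param decoy_size_range integer range of decoy set sizes.
#' @param seed integer seed.
#' @return a `gene_set_collection`: list with `sets` (named list of gene-id
#'   vectors), `descriptions`, and `source`.
#' @export
generate_gene_sets <- function(truth, n_decoy_sets = 50,
                               overlap_fraction = 0.8,
                               decoy_size_range = c(10, 50), seed = 1) {
  stopifnot(inherits(truth, "planted_truth"))
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]")
  }
  if (length(truth$gene_module_labels) == 0) stop("empty truth")
  set.seed(seed)
  universe <- names(truth$gene_module_labels)
  modules <- sort(unique(truth$gene_module_labels[truth$gene_module_labels > 0]))
  sets <- list()
  for (m in modules) {
    members <- names(truth$gene_module_labels)[truth$gene_module_labels == m]
    n_true <- round(overlap_fraction * length(members))
    core <- if (n_true > 0) sample(members, n_true) else character(0)
    n_fill <- length(members) - n_true
    pool <- setdiff(universe, members)
    fill <- if (n_fill > 0) sample(pool, min(n_fill, length(pool))) else character(0)
    sets[[sprintf("TRUE_SET_M%d", m)]] <- unique(c(core, fill))
  }
  if (n_decoy_sets > 0) {
    decoy_sizes <- sample(seq(decoy_size_range[1], decoy_size_range[2]),
                          n_decoy_sets, replace = TRUE)
    for (i in seq_len(n_decoy_sets)) {
      sets[[sprintf("DECOY_%03d", i)]] <- sample(universe, decoy_sizes[i])
    }
  }
  gene_set_collection(sets, source = "synthetic")
}
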