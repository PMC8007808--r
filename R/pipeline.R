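#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Inputs may be given as
#' file paths (`expression_file`, `traits_file`, `gene_sets_file`) or as
#' in-memory objects (`expression`, `traits`, `gene_sets`).
#'
#' @param expression,expression_file samples x genes matrix, or TSV path.
#' @param traits,traits_file a [trait_table()], or CSV/TSV path.
#' @param gene_sets,gene_sets_file a [gene_set_collection()], or GMT path;
#'   optional (enrichment is skipped without one).
#' @param out_dir run directory; created if absent.
#' @param orientation expression file orientation, see [read_expression()].
#' @param trait_groups group map used when reading `traits_file`.
#' @param beta soft power; default 10 (the conventional signed-network
#'   power). Pass `NULL` to use the power chosen by [pick_soft_threshold()]
#'   instead; the selection report is written either way.
#' @param mode adjacency mode ("signed"/"unsigned").
#' @param powers,r2_cut soft-threshold candidate grid and fit cutoff.
#' @param min_module_size,cut_height tree-cut parameters.
#' @param screening_alpha candidate-screening significance level.
#' @param screening_family Bonferroni family for the screen (default
#'   modules x traits).
#' @param models MANOVA adjustment models to run (subset of 1:3).
#' @param manova_alpha,suggestive_alpha MANOVA reporting thresholds.
#' @param enrichment_alpha,min_set_size,max_set_size,k_clusters enrichment
#'   and pathway-clustering options.
#' @param seed integer seed recorded in the manifest.
#' @param verbose emit progress messages.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(expression = NULL, expression_file = NULL,
                            traits = NULL, traits_file = NULL,
                            gene_sets = NULL, gene_sets_file = NULL,
                            out_dir = tempfile("comodule_run_"),
                            orientation = "genes-rows",
                            trait_groups = default_trait_groups(),
                            beta = 10, mode = "signed",
                            powers = 1:20, r2_cut = 0.80,
                            min_module_size = 10, cut_height = NULL,
                            screening_alpha = 0.05, screening_family = NULL,
                            models = 1:3, manova_alpha = 0.05,
                            suggestive_alpha = 0.25,
                            enrichment_alpha = 0.05,
                            min_set_size = 10, max_set_size = 500,
                            k_clusters = 4, seed = 1, verbose = TRUE) {
  if (is.null(expression) && is.null(expression_file)) {
    stop("provide expression or expression_file")
  }
  if (is.null(traits) && is.null(traits_file)) {
    stop("provide traits or traits_file")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(state, fmt, ...) {
  msg <- sprintf(fmt, ...)
  state$log <- c(state$log, msg)
  if (state$verbose) message(msg)
  state
}

write_tsv_with_note <- function(df, path, note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(note)) writeLines(paste0("# ", note), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full co-expression / joint-association pipeline
#'
#' Executes the nine analysis stages — expression input, correlation network
#' (with soft-threshold selection, adjacency and TOM), dissimilarity
#' clustering, module detection, eigengenes, module-trait screening (with
#' candidate selection), GS-MM quality check, joint MANOVA (modules then
#' member genes), and pathway enrichment with term clustering — writing
#' every intermediate table, a JSON manifest of all parameters and family
#' sizes, and a plain-text log under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every intermediate object plus
#'   `out_dir` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(log = character(0), verbose = isTRUE(config$verbose))
  stages <- character(0)
  set.seed(config$seed)

  # 1. expression input -------------------------------------------------
  expr <- if (!is.null(config$expression)) config$expression else
    read_expression(config$expression_file, orientation = config$orientation)
  traits <- if (!is.null(config$traits)) config$traits else
    read_traits(config$traits_file, groups = config$trait_groups)
  expr <- drop_constant_genes(expr)
  shared <- intersect(rownames(expr), traits$sample_ids)
  if (length(shared) == 0) stop("stage expression_input: no shared samples")
  state <- log_line(state,
    "expression_input: %d samples x %d genes; %d samples shared with traits",
    nrow(expr), ncol(expr), length(shared))
  expr <- expr[shared, , drop = FALSE]
  stages <- c(stages, "expression_input")

  # 2. correlation network: correlation, power, adjacency, TOM ----------
  cor_mat <- correlation_matrix(expr)
  st_report <- pick_soft_threshold(cor_mat, powers = config$powers,
                                   r2_cut = config$r2_cut, mode = config$mode)
  beta <- if (!is.null(config$beta)) config$beta else attr(st_report, "chosen")
  adj <- signed_adjacency(cor_mat, beta = beta, mode = config$mode)
  tom <- topological_overlap(adj)
  state <- log_line(state,
    "correlation_network: mode=%s, chosen power=%d%s, using beta=%d",
    config$mode, attr(st_report, "chosen"),
    if (attr(st_report, "fallback")) " (fallback)" else "", beta)
  write_tsv_with_note(as.data.frame(st_report),
                      file.path(out_dir, "soft_threshold.tsv"),
                      sprintf("signed scale-free fit per candidate power; chosen=%d fallback=%s",
                              attr(st_report, "chosen"), attr(st_report, "fallback")))
  stages <- c(stages, "correlation_network")

  # 3. dissimilarity clustering -----------------------------------------
  diss <- tom_dissimilarity(tom)
  dend <- average_linkage_cluster(diss)
  write_newick(dend, file.path(out_dir, "gene_dendrogram.nwk"))
  stages <- c(stages, "dissimilarity_clustering")

  # 4. module detection ---------------------------------------------------
  assign <- dynamic_tree_cut(dend, min_module_size = config$min_module_size,
                             cut_height = config$cut_height,
                             cor = cor_mat, n_samples = nrow(expr))
  n_mod <- length(assign$module_sizes)
  state <- log_line(state,
    "module_detection: %d modules (sizes %s), %d genes unassigned; cut_height=%.4f",
    n_mod, paste(as.integer(assign$module_sizes), collapse = "/"),
    sum(assign$labels == 0), assign$cut_height)
  if (n_mod == 0) stop("stage module_detection: no modules found")
  write_tsv_with_note(
    data.frame(gene_id = names(assign$labels), module = unname(assign$labels),
               color = unname(assign$colors)),
    file.path(out_dir, "module_assignment.tsv"),
    sprintf("static tree cut at %.4f, min_module_size=%d",
            assign$cut_height, assign$min_module_size))
  stages <- c(stages, "module_detection")

  # 5. eigengenes ---------------------------------------------------------
  eig <- module_eigengenes(expr, assign)
  write_tsv_with_note(
    data.frame(sample_id = rownames(eig$scores), eig$scores, check.names = FALSE),
    file.path(out_dir, "eigengenes.tsv"),
    "module eigengenes: first PC of z-scored member expression, zero-mean columns")
  stages <- c(stages, "eigengenes")

  # 6. module-trait screening --------------------------------------------
  mt <- module_trait_correlations(eig, traits, family = config$screening_family)
  sel <- select_candidate_modules(mt, alpha = config$screening_alpha)
  state <- log_line(state,
    "module_trait_screening: Bonferroni family=%d, alpha=%.3g, %d candidate module(s): %s",
    mt$family_size, config$screening_alpha, length(sel$selected),
    paste(sel$selected, collapse = ", "))
  write_tsv_with_note(module_trait_long(mt),
                      file.path(out_dir, "module_trait_correlations.tsv"),
                      sprintf("Pearson r (traits standardized/native units); Bonferroni family=%d",
                              mt$family_size))
  stages <- c(stages, "module_trait_screening")

  # 7. GS-MM quality check ------------------------------------------------
  gs <- gene_significance(expr, traits)
  mm <- module_membership(expr, eig)
  qc_rows <- list()
  for (mod in sel$selected) {
    members <- names(assign$colors)[assign$colors == mod]
    if (length(members) < 3) next
    pair <- sel$trait_pairs[sel$trait_pairs$module == mod, ]
    for (tr in c(pair$osteo, pair$athero)) {
      q <- gs_mm_quality(gs[, tr], mm[, mod], members)
      qc_rows[[length(qc_rows) + 1]] <- data.frame(
        module = mod, trait = tr, r_gs_mm = q$r_gs_mm, p = q$p, n_genes = q$n)
    }
  }
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else
    data.frame(module = character(0), trait = character(0),
               r_gs_mm = numeric(0), p = numeric(0), n_genes = integer(0))
  write_tsv_with_note(qc, file.path(out_dir, "gs_mm_quality.tsv"),
                      "cor(|GS|, MM) over member genes per candidate module and paired trait")
  stages <- c(stages, "gs_mm_quality")

  # 8. joint MANOVA: modules, then member genes of candidates -------------
  manova_mod <- module_joint_association(eig, sel, traits,
                                         models = config$models,
                                         alpha = config$manova_alpha,
                                         suggestive_alpha = config$suggestive_alpha)
  write_tsv_with_note(manova_mod, file.path(out_dir, "manova_modules.tsv"),
                      sprintf("Pillai's trace per candidate module and model; Bonferroni family=%d (candidates per model)",
                              length(sel$selected)))
  manova_genes <- list()
  for (mod in sel$selected) {
    pair <- sel$trait_pairs[sel$trait_pairs$module == mod, ]
    gj <- gene_joint_association(expr, mod, assign,
                                 c(osteo = pair$osteo, athero = pair$athero),
                                 traits, models = config$models)
    manova_genes[[mod]] <- gj
  }
  gene_tab <- if (length(manova_genes)) do.call(rbind, manova_genes) else NULL
  if (!is.null(gene_tab)) {
    write_tsv_with_note(gene_tab, file.path(out_dir, "manova_genes.tsv"),
                        "Pillai's trace per member gene and model; Bonferroni family = module size per model")
  }
  state <- log_line(state, "joint_manova: %d module rows, %d gene rows",
                    nrow(manova_mod),
                    if (is.null(gene_tab)) 0L else nrow(gene_tab))
  stages <- c(stages, "joint_manova")

  # 9. pathway enrichment + term clustering -------------------------------
  enr_tab <- NULL
  clusters <- NULL
  coll <- if (!is.null(config$gene_sets)) config$gene_sets else
    if (!is.null(config$gene_sets_file)) read_gmt(config$gene_sets_file) else NULL
  if (!is.null(coll)) {
    in_any_set <- unique(unlist(coll$sets, use.names = FALSE))
    universe <- intersect(colnames(expr), in_any_set)
    enr_list <- list()
    for (mod in sel$selected) {
      members <- names(assign$colors)[assign$colors == mod]
      er <- enrich_module(members, coll, universe,
                          min_size = config$min_set_size,
                          max_size = config$max_set_size)
      if (nrow(er) > 0) er <- cbind(module = mod, er)
      enr_list[[mod]] <- er
    }
    enr_list <- Filter(function(e) nrow(e) > 0, enr_list)
    enr_tab <- if (length(enr_list)) do.call(rbind, enr_list) else NULL
    if (!is.null(enr_tab) && nrow(enr_tab) > 0) {
      rownames(enr_tab) <- NULL
      write_tsv_with_note(enr_tab, file.path(out_dir, "enrichment.tsv"),
                          sprintf("hypergeometric over-representation; Bonferroni per collection after size filter [%d, %d]",
                                  config$min_set_size, config$max_set_size))
      sig <- enr_tab[enr_tab$p_adj < config$enrichment_alpha, , drop = FALSE]
      sig <- sig[!duplicated(sig$term), , drop = FALSE]
      if (nrow(sig) >= 2) {
        clusters <- cluster_enriched_pathways(sig, k_clusters = config$k_clusters)
        write_tsv_with_note(
          data.frame(term = names(clusters$clusters),
                     cluster = unname(clusters$clusters)),
          file.path(out_dir, "pathway_clusters.tsv"),
          sprintf("average-linkage clusters of 1-Jaccard(core genes), k=%d", clusters$k))
        write_newick(clusters$dendrogram, file.path(out_dir, "pathway_dendrogram.nwk"))
      }
      state <- log_line(state, "pathway_enrichment: %d records, %d significant term(s)",
                        nrow(enr_tab), nrow(sig))
    } else {
      state <- log_line(state, "pathway_enrichment: no testable sets")
    }
  } else {
    state <- log_line(state, "pathway_enrichment: no gene-set collection supplied; skipped tests")
  }
  stages <- c(stages, "pathway_enrichment")

  manifest <- list(
    package = "comodule",
    stages = stages,
    seed = config$seed,
    parameters = list(
      mode = config$mode, beta_used = beta,
      chosen_power = attr(st_report, "chosen"),
      power_fallback = attr(st_report, "fallback"),
      r2_cut = config$r2_cut,
      min_module_size = config$min_module_size,
      cut_height = assign$cut_height,
      screening_alpha = config$screening_alpha,
      screening_family = mt$family_size,
      models = config$models,
      manova_family = length(sel$selected),
      manova_alpha = config$manova_alpha,
      suggestive_alpha = config$suggestive_alpha,
      enrichment_alpha = config$enrichment_alpha,
      set_size_filter = c(config$min_set_size, config$max_set_size),
      k_clusters = config$k_clusters
    ),
    n_samples = nrow(expr), n_genes = ncol(expr),
    n_modules = n_mod,
    candidate_modules = sel$selected
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(state$log, file.path(out_dir, "run.log"))

  invisible(list(
    expression = expr, correlation = cor_mat, soft_threshold = st_report,
    adjacency = adj, tom = tom, dendrogram = dend, assignment = assign,
    eigengenes = eig, module_trait = mt, selection = sel,
    gs = gs, mm = mm, gs_mm = qc,
    manova_modules = manova_mod, manova_genes = gene_tab,
    enrichment = enr_tab, pathway_clusters = clusters,
    out_dir = out_dir, manifest = manifest
  ))
}
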