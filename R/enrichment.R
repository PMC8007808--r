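#' Gene-set collection
#'
#' @param sets named list of character vectors of member gene ids; empty
#'   sets are rejected and duplicate genes within a set removed.
#' @param descriptions optional character vector of term descriptions.
#' @param source source tag, e.g. "GO", "KEGG", "DO" or "custom".
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "custom") {
  if (length(sets) == 0) stop("collection must contain at least one set")
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must have unique names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("member lists must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets)),
                 source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection (%s): %d sets, sizes %d-%d\n", x$source,
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line is `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Duplicate genes within a line are removed; a line without members is a
#' parse error reported with its line number.
#'
#' @param path path to a GMT file.
#' @param source source tag stored on the collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, source = "custom") {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene", i))
    }
    sets[[fields[1]]] <- unique(fields[-(1:2)])
    desc <- c(desc, fields[2])
  }
  gene_set_collection(sets, descriptions = desc, source = source)
}

#' Write a gene-set collection as GMT
#'
#' @param coll a [gene_set_collection()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$descriptions[[nm]], coll$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail (inclusive) probability of drawing `k` or more annotated genes
#' when `n` genes are drawn without replacement from a universe of `N` genes
#' of which `K` are annotated:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k observed overlap count.
#' @param n query (module) size.
#' @param K annotated-set size within the universe.
#' @param N universe size.
#' @return the p-value; `k = 0` gives 1 exactly.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || K > N || n > N || k > min(n, K)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation of a gene list against a collection
#'
#' Intersects each set with the universe, drops sets outside
#' `[min_size, max_size]`, tests each remaining set hypergeometrically
#' against the query, and Bonferroni-adjusts over the number of sets tested.
#'
#' @param module_genes query gene ids (intersected with the universe).
#' @param coll a [gene_set_collection()].
#' @param universe background gene ids; by default every universe gene, but
#'   conventionally the expression-matrix genes appearing in >= 1 set.
#' @param min_size,max_size set-size filters after universe intersection
#'   (defaults 10 and 500).
#' @return an `enrichment_result` data.frame sorted by p: term, name, k, n,
#'   K, N, p, p_adj, core_genes (semicolon-joined overlap).
#' @export
enrich_module <- function(module_genes, coll, universe,
                          min_size = 10, max_size = 500) {
  stopifnot(inherits(coll, "gene_set_collection"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- intersect(unique(module_genes), universe)
  sets <- lapply(coll$sets, intersect, universe)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (length(sets) == 0) {
    return(structure(data.frame(term = character(0), name = character(0),
                                k = integer(0), n = integer(0), K = integer(0),
                                N = integer(0), p = numeric(0),
                                p_adj = numeric(0), core_genes = character(0)),
                     family_size = 0L, class = c("enrichment_result", "data.frame")))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    core <- intersect(query, sets[[nm]])
    k <- length(core)
    data.frame(term = nm, name = unname(coll$descriptions[nm]),
               k = k, n = n, K = length(sets[[nm]]), N = N,
               p = hypergeometric_test(k, n, length(sets[[nm]]), N),
               core_genes = paste(core, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- pmin(1, res$p * nrow(res))
  res <- res[order(res$p, res$term),
             c("term", "name", "k", "n", "K", "N", "p", "p_adj", "core_genes")]
  rownames(res) <- NULL
  structure(res, family_size = nrow(res),
            class = c("enrichment_result", "data.frame"))
}

#' Cluster enriched terms by member-gene similarity
#'
#' Pools significant enrichment records, computes pairwise distances
#' `1 - Jaccard` over their core (overlapping) genes — or over full set
#' membership with `use = "full"` — clusters them by average linkage and
#' cuts into `k_clusters` groups.
#'
#' @param results an `enrichment_result` (or rbind of several), typically
#'   pre-filtered to significant terms.
#' @param k_clusters number of pathway groups to report (default 4).
#' @param use `"core"` (default) to measure similarity on the enriched core
#'   genes, `"full"` to use full set membership.
#' @param coll required when `use = "full"`: the original collection.
#' @return a `pathway_cluster_result`: list with `terms`, `distance` matrix,
#'   `dendrogram` (hclust), `clusters` (named integer vector).
#' @export
cluster_enriched_pathways <- function(results, k_clusters = 4,
                                      use = c("core", "full"), coll = NULL) {
  use <- match.arg(use)
  if (nrow(results) < 2) stop("need >= 2 enriched terms to cluster; skip clustering")
  genes <- if (use == "core") {
    strsplit(results$core_genes, ";", fixed = TRUE)
  } else {
    if (is.null(coll)) stop("use = 'full' requires the collection")
    coll$sets[results$term]
  }
  names(genes) <- results$term
  m <- length(genes)
  d <- matrix(0, m, m, dimnames = list(results$term, results$term))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- genes[[i]]; b <- genes[[j]]
      u <- length(union(a, b))
      jac <- if (u == 0) 0 else length(intersect(a, b)) / u
      d[i, j] <- d[j, i] <- 1 - jac
    }
  }
  dend <- average_linkage_cluster(d)
  k_clusters <- min(k_clusters, m)
  clusters <- stats::cutree(dend, k = k_clusters)
  structure(list(terms = results$term, distance = d, dendrogram = dend,
                 clusters = clusters, k = k_clusters),
            class = "pathway_cluster_result")
}
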