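#' Read an expression matrix from TSV
#'
#' The file default is the transcriptomics convention (genes in rows, first
#' column gene ids, remaining columns sample ids); the internal orientation
#' is always samples x genes. Pass `orientation = "samples-rows"` for
#' already-transposed files. Duplicate ids, ragged rows and non-numeric
#' cells are rejected with their location.
#'
#' @param path TSV file with a header row.
#' @param orientation `"genes-rows"` (default) or `"samples-rows"`.
#' @return samples x genes numeric matrix.
#' @export
read_expression <- function(path, orientation = c("genes-rows", "samples-rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate row id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate column id(s)")
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell at row %d ('%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(df)[-1])
  if (orientation == "genes-rows") t(num) else num
}

#' Write an expression matrix as TSV (genes in rows)
#'
#' @param expr samples x genes matrix.
#' @param path output path.
#' @param id_column name of the first (gene id) column.
#' @return the path, invisibly.
#' @export
write_expression <- function(expr, path, id_column = "gene_id") {
  df <- data.frame(colnames(expr), t(expr), check.names = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait table
#'
#' Reads a delimited file (comma or tab, sniffed from the header line) whose
#' first column is the sample id. Columns named like the six standard
#' covariates (age, sex, bmi, smoking, alcohol, physical_activity) become
#' covariates; every remaining column must appear in `groups`.
#'
#' @param path CSV/TSV file.
#' @param groups named character vector mapping trait columns to
#'   "osteo"/"athero"; defaults to [default_trait_groups()].
#' @return a [trait_table()].
#' @export
read_traits <- function(path, groups = default_trait_groups()) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  header <- readLines(path, n = 1)
  sep <- if (lengths(regmatches(header, gregexpr(",", header))) >=
             lengths(regmatches(header, gregexpr("\t", header)))) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample id(s) in trait table")
  df <- df[, -1, drop = FALSE]
  cov_cols <- intersect(covariate_names(), colnames(df))
  trait_cols <- setdiff(colnames(df), cov_cols)
  unmapped <- setdiff(trait_cols, names(groups))
  if (length(unmapped) > 0) {
    stop(sprintf("trait column(s) not in group map: %s",
                 paste(unmapped, collapse = ", ")))
  }
  traits <- as.matrix(df[, trait_cols, drop = FALSE])
  if (!is.numeric(traits)) stop("trait columns must be numeric")
  rownames(traits) <- ids
  covariates <- df[, cov_cols, drop = FALSE]
  rownames(covariates) <- ids
  trait_table(traits, covariates, groups)
}

#' Write a trait table as CSV
#'
#' @param traits a [trait_table()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  stopifnot(inherits(traits, "trait_table"))
  df <- data.frame(sample_id = traits$sample_ids, traits$traits,
                   traits$covariates, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the planted-truth gene-module map as two-column TSV
#'
#' @param truth a `planted_truth`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  utils::write.table(
    data.frame(gene_id = names(truth$gene_module_labels),
               module = unname(truth$gene_module_labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
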