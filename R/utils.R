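#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' used mainly to score planted-module recovery. Labels may be any atomic
#' type; only the induced partitions matter.
#'
#' @param a,b vectors of equal length giving the two partitions.
#' @return A single number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ij - expected) / (max_index - expected)
}

#' Bonferroni adjustment
#'
#' @param p raw p-values.
#' @param family family size (defaults to `length(p)`).
#' @return `pmin(1, p * family)`.
#' @keywords internal
bonferroni <- function(p, family = length(p)) pmin(1, p * family)

# Stop unless all conditions hold; `...` are named `cond = "message"` pairs.
check_that <- function(...) {
  conds <- list(...)
  for (msg in names(conds)) {
    if (!isTRUE(conds[[msg]])) stop(msg, call. = FALSE)
  }
  invisible(TRUE)
}
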