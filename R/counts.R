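# 3x3 two-locus genotype count tables and allele-counting estimators.

.MARKER_GT <- c("MM", "Mm", "mm")
.DISEASE_GT <- c("AA", "Aa", "aa")

#' Two-locus genotype count table
#'
#' A 3x3 table of counts `n_ij` with rows indexing the marker genotype
#' (MM, Mm, mm) and columns the disease genotype (AA, Aa, aa). Counts must be
#' non-negative and finite; fractional counts are permitted so that
#' expectation tables (n times a probability table) can flow through the
#' likelihood machinery unchanged.
#'
#' @param x A 3x3 numeric matrix (or object coercible to one), rows
#'   MM/Mm/mm, columns AA/Aa/aa.
#' @return An object of class `genotype_counts` (a 3x3 matrix).
#' @export
genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  x <- as.matrix(x)
  if (!is.numeric(x) || !identical(dim(x), c(3L, 3L)))
    stop("genotype counts must be a 3x3 numeric matrix", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("genotype counts must be finite and non-negative", call. = FALSE)
  dimnames(x) <- list(marker = .MARKER_GT, disease = .DISEASE_GT)
  class(x) <- c("genotype_counts", class(matrix()))
  x
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts (n = %g)\n", sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Allele frequencies by allele counting
#'
#' Estimates the marker (`p`) and disease (`q`) allele frequencies from a
#' genotype count table by counting allele copies:
#' `p_hat = (2 n_1. + n_2.) / (2n)`, `q_hat = (2 n_.1 + n_.2) / (2n)`.
#'
#' @param counts A [genotype_counts()] table.
#' @return Named vector `c(p, q)`.
#' @export
allele_freqs <- function(counts) {
  counts <- genotype_counts(counts)
  n <- sum(counts)
  if (n <= 0) stop("empty count table: n must be positive", call. = FALSE)
  rm <- rowSums(counts)
  cm <- colSums(counts)
  c(p = unname((2 * rm[1] + rm[2]) / (2 * n)),
    q = unname((2 * cm[1] + cm[2]) / (2 * n)))
}
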