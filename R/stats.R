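# Auxiliary statistics: r^2, Hardy-Weinberg chi-square, allelic case-control
# chi-square.

#' Squared correlation measure of LD
#'
#' `r^2 = D^2 / (p (1-p) q (1-q))`. Requires both loci polymorphic.
#'
#' @inheritParams d_bounds
#' @param D LD coefficient.
#' @return `r^2` in `[0, 1]` whenever `D` lies within [d_bounds()].
#' @export
r_squared <- function(D, p, q) {
  .check_freq(p, "p", interior = TRUE)
  .check_freq(q, "q", interior = TRUE)
  stopifnot(is.numeric(D), is.finite(D))
  D^2 / (p * (1 - p) * q * (1 - q))
}

#' Hardy-Weinberg equilibrium chi-square test for one biallelic locus
#'
#' Pearson goodness-of-fit of the three genotype counts against HWE
#' proportions computed from the sample allele frequency; 1 degree of
#' freedom, no continuity correction.
#'
#' @param g0,g1,g2 Genotype counts with 2, 1 and 0 copies of the reference
#'   allele (e.g. AA, Aa, aa).
#' @return List with `chi2`, `p_value`, `df = 1` and `degenerate` (TRUE for a
#'   monomorphic locus, where `chi2 = 0` and `p_value = 1` by convention).
#' @export
hwe_chisq <- function(g0, g1, g2) {
  obs <- c(g0, g1, g2)
  if (any(!is.finite(obs)) || any(obs < 0) || sum(obs) <= 0)
    stop("genotype counts must be non-negative with positive total",
         call. = FALSE)
  n <- sum(obs)
  f <- (2 * g0 + g1) / (2 * n)
  if (f <= 0 || f >= 1)
    return(list(chi2 = 0, p_value = 1, df = 1L, degenerate = TRUE))
  expd <- n * c(f^2, 2 * f * (1 - f), (1 - f)^2)
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, degenerate = FALSE)
}

#' Allelic chi-square test for marker frequency difference (case vs control)
#'
#' 2x2 Pearson chi-square on allele counts (2 x genotype counts folded to
#' allele copies), 1 df, no continuity correction: the conventional test of
#' marker allele-frequency difference between cases and controls.
#'
#' @param case_counts,control_counts Length-3 genotype counts (2, 1, 0
#'   copies of the marker allele) for cases and controls.
#' @return List with `chi2`, `p_value`, `df = 1` and the 2x2 allele table.
#' @export
allelic_chisq <- function(case_counts, control_counts) {
  chk <- function(x, nm) {
    if (length(x) != 3L || any(!is.finite(x)) || any(x < 0) || sum(x) <= 0)
      stop(sprintf("`%s` must be 3 non-negative counts with positive total", nm),
           call. = FALSE)
  }
  chk(case_counts, "case_counts")
  chk(control_counts, "control_counts")
  tab <- rbind(case    = c(2 * case_counts[1] + case_counts[2],
                           2 * case_counts[3] + case_counts[2]),
               control = c(2 * control_counts[1] + control_counts[2],
                           2 * control_counts[3] + control_counts[2]))
  colnames(tab) <- c("M", "m")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd == 0)) {
    chi2 <- 0  # one allele absent from both groups: no information
  } else {
    chi2 <- sum((tab - expd)^2 / expd)
  }
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L, table = tab)
}
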