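# Joint-likelihood estimator of D ("Method H"): Hill's two-locus genotype
# distribution under random union of gametes, haplotype frequency g11
# estimated by EM chromosome counting, cross-checked against the cubic score
# equation (Weir-Cockerham form), with D_hat = g11_hat - p q. Valid for
# randomly collected samples; exposed here both as a safe ("strict")
# estimator and in a "replication" mode that reproduces its failure on
# ascertained samples.

#' Joint two-locus genotype distribution (Hill)
#'
#' Probabilities of the nine marker x disease genotype combinations under
#' random union of gametes with frequencies from [haplotype_freqs()]. The
#' double heterozygote pools the cis and trans configurations:
#' `P(MmAa) = 2 (g11 g22 + g12 g21)`.
#'
#' @param params An [ld_params()] object.
#' @return A 3x3 matrix of class `joint_prob_table` summing to 1, with
#'   attribute `g` holding the gamete frequencies.
#' @export
joint_probs <- function(params) {
  g <- haplotype_freqs(params)
  P <- rbind(MM = c(g[["g11"]]^2, 2 * g[["g11"]] * g[["g12"]], g[["g12"]]^2),
             Mm = c(2 * g[["g11"]] * g[["g21"]],
                    2 * (g[["g11"]] * g[["g22"]] + g[["g12"]] * g[["g21"]]),
                    2 * g[["g12"]] * g[["g22"]]),
             mm = c(g[["g21"]]^2, 2 * g[["g21"]] * g[["g22"]], g[["g22"]]^2))
  colnames(P) <- .DISEASE_GT
  structure(P, g = g, class = c("joint_prob_table", class(matrix())))
}

# Grouped coefficients of the joint log-likelihood in g11 with p, q fixed
# (g12 = p - g11, g21 = q - g11, g22 = 1 - p - q + g11):
#   l(g11) = c1 log g11 + c2 log g12 + c3 log g21 + c4 log g22
#            + n22 log(g11 g22 + g12 g21) + const
.joint_coefs <- function(counts) {
  list(c1 = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
       c2 = counts[1, 2] + 2 * counts[1, 3] + counts[2, 3],
       c3 = counts[2, 1] + 2 * counts[3, 1] + counts[3, 2],
       c4 = counts[2, 3] + counts[3, 2] + 2 * counts[3, 3],
       n22 = counts[2, 2],
       const = (counts[1, 2] + counts[2, 1] + counts[2, 2] +
                counts[2, 3] + counts[3, 2]) * log(2))
}

#' Joint log-likelihood as a function of the haplotype frequency g11
#'
#' `sum_ij n_ij log P_ij` with `P_ij` from [joint_probs()] at haplotype
#' frequencies `(g11, p - g11, q - g11, 1 - p - q + g11)`. `-Inf` where an
#' observed cell has probability <= 0. Vectorized over `g11`.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @param g11 Numeric vector of MA haplotype frequencies.
#' @return Numeric vector of log-likelihood values.
#' @export
loglik_joint <- function(counts, p, q, g11) {
  counts <- genotype_counts(counts)
  k <- .joint_coefs(counts)
  g12 <- p - g11
  g21 <- q - g11
  g22 <- 1 - p - q + g11
  A <- g11 * g22 + g12 * g21
  .xlogx(k$c1, g11) + .xlogx(k$c2, g12) + .xlogx(k$c3, g21) +
    .xlogx(k$c4, g22) + .xlogx(k$n22, A) + k$const
}

#' EM "chromosome counting" estimate of the MA haplotype frequency
#'
#' With `p` and `q` fixed, all haplotype counts are read directly from the
#' genotype table except for the double heterozygotes, whose expected cis
#' fraction `w = g11 g22 / (g11 g22 + g12 g21)` is recomputed each
#' iteration: `g11 <- (2 n11 + n12 + n21 + w n22) / (2n)`. Started at
#' linkage equilibrium `g11 = p q`.
#'
#' The update is not clamped to [g11_bounds()]; when the supplied `(p, q)`
#' are inconsistent with the sample (as in ascertained designs) the fixed
#' point can fall outside the feasible interval, which is exactly the
#' failure mode of the joint method on non-random samples.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @param tol Convergence tolerance on `|change in g11|`.
#' @param max_iter Iteration cap; exceeding it sets `converged = FALSE`.
#' @return List with `g11`, `converged`, `iterations`.
#' @export
em_g11 <- function(counts, p, q, tol = 1e-10, max_iter = 10000L) {
  counts <- genotype_counts(counts)
  .check_freq(p, "p", interior = TRUE)
  .check_freq(q, "q", interior = TRUE)
  n <- sum(counts)
  if (n <= 0) stop("empty count table", call. = FALSE)
  k <- .joint_coefs(counts)
  g <- p * q
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    g22 <- 1 - p - q + g
    A <- g * g22 + (p - g) * (q - g)
    if (k$n22 > 0) {
      if (!is.finite(A) || A == 0) break  # update undefined; stop unconverged
      w <- g * g22 / A
    } else {
      w <- 0
    }
    g_new <- (k$c1 + w * k$n22) / (2 * n)
    if (!is.finite(g_new)) break
    delta <- abs(g_new - g)
    g <- g_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged)
    warning(sprintf("EM for g11 did not converge after %d iterations", it))
  list(g11 = g, converged = converged, iterations = it)
}

#' Real roots of the cubic score equation for g11
#'
#' Stationary points of [loglik_joint()] in `g11` coincide with fixed points
#' of the EM update; clearing denominators in the fixed-point equation
#' `2n g11 A = (2 n11 + n12 + n21) A + n22 g11 g22` (with
#' `A = g11 g22 + g12 g21`) yields a cubic `b3 g^3 + b2 g^2 + b1 g + b0`
#' with `b3 = 4n`, `b2 = 2n(1-2p-2q) - 2 c1 - n22`,
#' `b1 = 2npq - c1 (1-2p-2q) - n22 (1-p-q)`, `b0 = -c1 p q`, where
#' `c1 = 2 n11 + n12 + n21`. All real roots are returned with their joint
#' log-likelihood and feasibility status.
#'
#' Note the cubic's roots coincide with the stationary points of
#' [loglik_joint()] when `(p, q)` equal the sample allele frequencies
#' (the margin identities `c1 + c2 = 2np - n22`, `c1 + c3 = 2nq - n22`
#' then hold); for other plug-in frequencies [mle_D_joint()] additionally
#' scans the feasible interval.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @return Data frame with columns `g11`, `loglik`, `in_bounds`.
#' @export
cubic_g11 <- function(counts, p, q) {
  counts <- genotype_counts(counts)
  .check_freq(p, "p", interior = TRUE)
  .check_freq(q, "q", interior = TRUE)
  n <- sum(counts)
  k <- .joint_coefs(counts)
  b0 <- -k$c1 * p * q
  b1 <- 2 * n * p * q - k$c1 * (1 - 2 * p - 2 * q) - k$n22 * (1 - p - q)
  b2 <- 2 * n * (1 - 2 * p - 2 * q) - 2 * k$c1 - k$n22
  b3 <- 4 * n
  r <- polyroot(c(b0, b1, b2, b3))
  re <- Re(r)[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))]
  gb <- g11_bounds(p, q)
  data.frame(g11 = re,
             loglik = loglik_joint(counts, p, q, re),
             in_bounds = re >= gb[[1]] - 1e-9 & re <= gb[[2]] + 1e-9)
}

#' Joint maximum-likelihood estimate of D (Method H)
#'
#' `D_hat = g11_hat - p q` with `g11_hat` the maximizer of [loglik_joint()].
#'
#' In `"strict"` mode the maximizer is chosen among the in-bounds cubic
#' roots and the interval endpoints by highest likelihood, so `D_hat` always
#' respects the theoretical bounds. In `"replication"` mode the raw EM fixed
#' point is reported even when it falls outside [g11_bounds()]
#' (`out_of_bounds = TRUE`, log-likelihood undefined), reproducing the
#' method's documented behavior on ascertained/case-control samples.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @param mode `"strict"` (default) or `"replication"`.
#' @param eps Endpoint shrinkage when evaluating boundary candidates.
#' @return An `ld_estimate` of method `"joint-EM"` with LRT fields filled
#'   (NA when the likelihood is undefined at an out-of-bounds estimate).
#' @export
mle_D_joint <- function(counts, p, q, mode = c("strict", "replication"),
                        eps = 1e-9) {
  mode <- match.arg(mode)
  counts <- genotype_counts(counts)
  if (sum(counts) <= 0) stop("empty count table", call. = FALSE)
  if (.is_degenerate_freq(p) || .is_degenerate_freq(q))
    return(.degenerate_estimate("joint-EM", p, q))
  gb <- g11_bounds(p, q)
  db <- d_bounds(p, q)
  if (gb[[2]] - gb[[1]] <= 2 * eps)
    return(.degenerate_estimate("joint-EM", p, q))

  em <- suppressWarnings(em_g11(counts, p, q))
  oob <- em$g11 < gb[[1]] - 1e-9 || em$g11 > gb[[2]] + 1e-9

  if (mode == "replication" && (oob || !em$converged)) {
    g_hat <- em$g11
    ll_hat <- loglik_joint(counts, p, q, g_hat)  # -Inf / undefined when oob
    res <- new_ld_estimate(method = "joint-EM", D_hat = g_hat - p * q,
                           p_used = p, q_used = q,
                           loglik_at_Dhat = if (is.finite(ll_hat)) ll_hat else NA_real_,
                           loglik_at_0 = loglik_joint(counts, p, q, p * q),
                           bounds = db, out_of_bounds = oob,
                           extra = list(g11_hat = g_hat,
                                        em_converged = em$converged))
    return(lrt_lod(res))
  }

  roots <- cubic_g11(counts, p, q)
  cand_g <- c(roots$g11[roots$in_bounds], gb[[1]] + eps, gb[[2]] - eps)
  if (em$converged && !oob) cand_g <- c(cand_g, em$g11)
  # The cubic's roots are the likelihood's stationary points only when
  # (p, q) are the sample allele frequencies (margin identities); for
  # arbitrary plug-in frequencies scan the interval and refine, as for the
  # conditional estimator, so the strict estimate is always the maximizer.
  grid <- seq(gb[[1]] + eps, gb[[2]] - eps, length.out = 2001)
  gll <- loglik_joint(counts, p, q, grid)
  gi <- which.max(gll)
  if (is.finite(gll[gi])) {
    lo2 <- grid[max(1L, gi - 1L)]
    hi2 <- grid[min(length(grid), gi + 1L)]
    if (hi2 > lo2) {
      op <- stats::optimize(function(g) loglik_joint(counts, p, q, g),
                            c(lo2, hi2), maximum = TRUE,
                            tol = .Machine$double.eps^0.5)
      cand_g <- c(cand_g, grid[gi], op$maximum)
    } else {
      cand_g <- c(cand_g, grid[gi])
    }
  }
  cand_g <- pmin(pmax(cand_g, gb[[1]]), gb[[2]])
  cand_ll <- loglik_joint(counts, p, q, cand_g)
  top <- max(cand_ll)
  tied <- which(cand_ll >= top - 1e-10)
  pick <- tied[which.min(abs(cand_g[tied] - p * q))]
  g_hat <- cand_g[pick]
  ll_hat <- cand_ll[pick]

  res <- new_ld_estimate(method = "joint-EM", D_hat = g_hat - p * q,
                         p_used = p, q_used = q,
                         loglik_at_Dhat = ll_hat,
                         loglik_at_0 = loglik_joint(counts, p, q, p * q),
                         bounds = db,
                         at_boundary = min(g_hat - gb[[1]], gb[[2]] - g_hat) <= 1e-9 + eps,
                         out_of_bounds = FALSE,
                         extra = list(g11_hat = g_hat,
                                      em_converged = em$converged))
  lrt_lod(res)
}

#' Estimate D from a genotype count table
#'
#' Convenience front end dispatching to [mle_D_conditional()] (method
#' `"L"`) or [mle_D_joint()] (method `"H"`), with the LRT/LOD fields filled.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @param method `"L"` (conditional) or `"H"` (joint EM).
#' @param h_mode Mode passed to [mle_D_joint()] when `method = "H"`.
#' @return An `ld_estimate`.
#' @export
estimate_ld <- function(counts, p, q, method = c("L", "H"),
                        h_mode = c("strict", "replication")) {
  method <- match.arg(method)
  if (method == "L") {
    lrt_lod(mle_D_conditional(counts, p, q))
  } else {
    mle_D_joint(counts, p, q, mode = match.arg(h_mode))
  }
}
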