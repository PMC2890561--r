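# Conditional-likelihood estimator of D ("Method L"): models the disease
# genotype distribution given each marker genotype, so the number of
# individuals sampled per marker (or conditioning) class cancels out of the
# likelihood. This is what makes the estimator robust to genotype-class
# ascertainment and case-control enrichment.

# Gamete-level conditional allele frequencies:
#   Q = P(A | M gamete) = (p q + D) / p
#   R = P(A | m gamete) = ((1 - p) q - D) / (1 - p)
# They satisfy p Q + (1 - p) R = q and D = p (1 - p) (Q - R).
.cond_QR <- function(p, q, D) {
  list(Q = (p * q + D) / p, R = ((1 - p) * q - D) / (1 - p))
}

#' Conditional distribution of disease genotypes given marker genotype
#'
#' Under random mating, the two gametes of an individual are independent, so
#' given marker genotype MM each gamete carries A with probability
#' `Q = (pq + D)/p`, and given mm with probability `R = ((1-p)q - D)/(1-p)`;
#' heterozygotes Mm carry one gamete of each kind. The rows of the returned
#' table are the binomial mixtures this implies.
#'
#' @param params An [ld_params()] object with `0 < p < 1`.
#' @return A 3x3 row-stochastic matrix of class `cond_prob_table` with
#'   attributes `Q` and `R`.
#' @export
conditional_probs <- function(params) {
  stopifnot(inherits(params, "ld_params"))
  p <- params$p; q <- params$q; D <- params$D
  .check_freq(p, "p", interior = TRUE)
  qr <- .cond_QR(p, q, D)
  Q <- qr$Q; R <- qr$R
  f <- rbind(MM = c(Q^2,   2 * Q * (1 - Q),   (1 - Q)^2),
             Mm = c(Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R)),
             mm = c(R^2,   2 * R * (1 - R),   (1 - R)^2))
  colnames(f) <- .DISEASE_GT
  structure(f, Q = Q, R = R, class = c("cond_prob_table", class(matrix())))
}

# n * log(x) with the conventions 0 * log(0) = 0 and n > 0, x <= 0 -> -Inf.
# Vectorized over x (n scalar).
.xlogx <- function(n, x) {
  if (n == 0) return(rep(0, length(x)))
  out <- rep(-Inf, length(x))
  ok <- x > 0
  out[ok] <- n * log(x[ok])
  out
}

# Grouped cell-count coefficients of the conditional log-likelihood:
# sum_ij n_ij log f_ij  =  a log Q + b log(1-Q) + c log R + d log(1-R)
#                          + n22 log(Q + R - 2QR) + (n12 + n32) log 2
.cond_coefs <- function(counts) {
  list(a = 2 * counts[1, 1] + counts[1, 2] + counts[2, 1],
       b = counts[1, 2] + 2 * counts[1, 3] + counts[2, 3],
       cc = counts[2, 1] + 2 * counts[3, 1] + counts[3, 2],
       d = counts[2, 3] + counts[3, 2] + 2 * counts[3, 3],
       n22 = counts[2, 2],
       const = (counts[1, 2] + counts[3, 2]) * log(2))
}

#' Conditional log-likelihood of D
#'
#' `sum_ij n_ij log f_ij(p, q, D)` with `f_ij` from [conditional_probs()].
#' Returns `-Inf` for any `D` that assigns probability zero to an observed
#' cell (that `D` is infeasible for the data). Vectorized over `D`.
#'
#' @param counts A [genotype_counts()] table.
#' @inheritParams d_bounds
#' @param D Numeric vector of LD coefficient values within [d_bounds()].
#' @return Numeric vector of log-likelihood values.
#' @export
loglik_conditional <- function(counts, p, q, D) {
  counts <- genotype_counts(counts)
  .check_freq(p, "p", interior = TRUE)
  .check_freq(q, "q", interior = TRUE)
  k <- .cond_coefs(counts)
  Q <- (p * q + D) / p
  R <- ((1 - p) * q - D) / (1 - p)
  S <- Q + R - 2 * Q * R
  .xlogx(k$a, Q) + .xlogx(k$b, 1 - Q) + .xlogx(k$cc, R) +
    .xlogx(k$d, 1 - R) + .xlogx(k$n22, S) + k$const
}

# Analytic score dl/dD of the conditional log-likelihood (vectorized over D).
# Used to polish the maximizer to machine precision; the score numerator is a
# degree-5 polynomial in D, matching the quintic form of the estimating
# equation.
.cond_score <- function(counts, p, q, D) {
  counts <- genotype_counts(counts)
  k <- .cond_coefs(counts)
  Q <- (p * q + D) / p
  R <- ((1 - p) * q - D) / (1 - p)
  S <- Q + R - 2 * Q * R
  dQ <- 1 / p
  dR <- -1 / (1 - p)
  dS <- dQ * (1 - 2 * R) + dR * (1 - 2 * Q)
  term <- function(n, x, dx) ifelse(rep(n, length(x)) == 0, 0, n * dx / x)
  term(k$a, Q, dQ) + term(k$b, 1 - Q, -dQ) + term(k$cc, R, dR) +
    term(k$d, 1 - R, -dR) + term(k$n22, S, dS)
}

.degenerate_estimate <- function(method, p, q, counts = NULL) {
  new_ld_estimate(method = method, D_hat = 0, p_used = p, q_used = q,
                  loglik_at_Dhat = 0, loglik_at_0 = 0,
                  lambda = 0, lod = 0, p_value = 1,
                  bounds = c(0, 0), at_boundary = TRUE, degenerate = TRUE)
}

#' Conditional maximum-likelihood estimate of D (Method L)
#'
#' Maximizes [loglik_conditional()] over the closed feasibility interval
#' [d_bounds()] shrunk by `eps` at each end. The likelihood is scanned on a
#' dense grid, every local maximum is refined by bounded scalar optimization,
#' interior optima are polished to a root of the analytic score, and ties
#' (within 1e-10 in log-likelihood) are broken toward the smallest `|D|`.
#'
#' @param counts A [genotype_counts()] table.
#' @param p,q Marker and disease allele frequencies (supplied externally,
#'   e.g. from [estimate_freqs()]).
#' @param grid_points Number of grid points for the initial scan.
#' @param eps Shrinkage of the search interval at each bound, keeping the
#'   row probabilities strictly positive during the scan.
#' @return An [new_ld_estimate()] object of method `"conditional"` with
#'   log-likelihoods at `D_hat` and 0 filled in (LRT fields via [lrt_lod()]).
#' @export
mle_D_conditional <- function(counts, p, q, grid_points = 2001, eps = 1e-9) {
  counts <- genotype_counts(counts)
  if (sum(counts) <= 0) stop("empty count table", call. = FALSE)
  if (.is_degenerate_freq(p) || .is_degenerate_freq(q))
    return(.degenerate_estimate("conditional", p, q))
  b <- d_bounds(p, q)
  lo <- b[[1]] + eps
  hi <- b[[2]] - eps
  if (hi <= lo) return(.degenerate_estimate("conditional", p, q))

  obj <- function(d) loglik_conditional(counts, p, q, d)
  grid <- seq(lo, hi, length.out = grid_points)
  ll <- obj(grid)
  if (!any(is.finite(ll)))
    stop("log-likelihood is -Inf on the entire feasible interval", call. = FALSE)

  # candidate maximizers: every grid local maximum, refined locally
  is_locmax <- ll >= c(-Inf, ll[-grid_points]) & ll >= c(ll[-1], -Inf)
  cand_idx <- which(is_locmax & is.finite(ll) & ll >= max(ll) - 25)
  cand_D <- numeric(0); cand_ll <- numeric(0)
  for (i in cand_idx) {
    l2 <- grid[max(1L, i - 1L)]
    h2 <- grid[min(grid_points, i + 1L)]
    if (h2 > l2) {
      op <- stats::optimize(obj, c(l2, h2), maximum = TRUE,
                            tol = .Machine$double.eps^0.5)
      dm <- op$maximum
      # polish interior optima to a root of the analytic score
      s_l <- .cond_score(counts, p, q, l2)
      s_h <- .cond_score(counts, p, q, h2)
      if (is.finite(s_l) && is.finite(s_h) && s_l * s_h < 0) {
        rt <- tryCatch(
          stats::uniroot(function(d) .cond_score(counts, p, q, d),
                         c(l2, h2), tol = .Machine$double.eps)$root,
          error = function(e) NULL)
        if (!is.null(rt) && is.finite(obj(rt)) && obj(rt) >= op$objective - 1e-9)
          dm <- rt
      }
      cand_D <- c(cand_D, dm); cand_ll <- c(cand_ll, obj(dm))
    }
    cand_D <- c(cand_D, grid[i]); cand_ll <- c(cand_ll, ll[i])
  }
  # include the interval endpoints (boundary maxima have non-zero score)
  cand_D <- c(cand_D, lo, hi)
  cand_ll <- c(cand_ll, obj(lo), obj(hi))

  top <- max(cand_ll)
  tied <- which(cand_ll >= top - 1e-10)
  pick <- tied[which.min(abs(cand_D[tied]))]
  D_hat <- cand_D[pick]
  ll_hat <- cand_ll[pick]
  ll0 <- obj(0)

  new_ld_estimate(method = "conditional", D_hat = D_hat,
                  p_used = p, q_used = q,
                  loglik_at_Dhat = ll_hat, loglik_at_0 = ll0,
                  bounds = b,
                  at_boundary = min(D_hat - b[[1]], b[[2]] - D_hat) <= 1e-9 + eps)
}

#' Likelihood-ratio and LOD-score test for D = 0
#'
#' Fills `lambda = 2 (l(D_hat) - l(0))`, the upper-tail chi-square(1)
#' p-value, and `LOD = lambda / (2 ln 10)` into an estimation result whose
#' log-likelihoods were computed with the same `(p, q)`.
#'
#' @param result An `ld_estimate` with `loglik_at_Dhat` and `loglik_at_0` set.
#' @return The result with `lambda`, `lod`, `p_value` filled.
#' @export
lrt_lod <- function(result) {
  stopifnot(inherits(result, "ld_estimate"))
  if (!is.finite(result$loglik_at_Dhat) || !is.finite(result$loglik_at_0)) {
    result$lambda <- NA_real_; result$lod <- NA_real_
    result$p_value <- NA_real_
    return(result)
  }
  lambda <- 2 * (result$loglik_at_Dhat - result$loglik_at_0)
  lambda <- max(0, lambda)  # numeric guard: D = 0 is always feasible
  result$lambda <- lambda
  result$lod <- lambda / (2 * log(10))
  result$p_value <- stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  result
}

#' LOD profile of the conditional estimator over disease allele frequencies
#'
#' When no reliable external estimate of the disease allele frequency `q`
#' exists, the conditional likelihood can be profiled over a grid of `q`
#' values; the recommended `q` (and its `D_hat`) is the grid argmax of the
#' LOD score.
#'
#' @param counts A [genotype_counts()] table.
#' @param p Marker allele frequency.
#' @param q_grid Non-empty vector of candidate `q` values in (0, 1).
#' @return A data frame with columns `q`, `D_hat`, `lod`, `lambda`,
#'   `p_value`, `at_boundary`; attribute `best` holds the argmax row index.
#' @export
q_profile <- function(counts, p, q_grid) {
  counts <- genotype_counts(counts)
  if (length(q_grid) == 0) stop("`q_grid` must be non-empty", call. = FALSE)
  if (any(q_grid <= 0 | q_grid >= 1))
    stop("`q_grid` values must lie strictly in (0, 1)", call. = FALSE)
  rows <- lapply(q_grid, function(qv) {
    r <- lrt_lod(mle_D_conditional(counts, p, qv))
    data.frame(q = qv, D_hat = r$D_hat, lod = r$lod, lambda = r$lambda,
               p_value = r$p_value, at_boundary = r$at_boundary)
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- which.max(out$lod)
  out
}
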