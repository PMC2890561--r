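# Population parameters and theoretical feasibility bounds.

.check_freq <- function(x, name, interior = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < 0 || x > 1)
    stop(sprintf("`%s` must lie in [0, 1], got %g", name, x), call. = FALSE)
  if (interior && (x <= 0 || x >= 1))
    stop(sprintf("`%s` must lie strictly in (0, 1), got %g", name, x),
         call. = FALSE)
  invisible(x)
}

.is_degenerate_freq <- function(x) x <= 0 || x >= 1

#' Theoretical bounds for the linkage-disequilibrium coefficient D
#'
#' For marker allele frequency `p` and disease allele frequency `q`, D is
#' constrained so that all four gamete (haplotype) frequencies are
#' non-negative: `D_min = max(-p*q, -(1-p)*(1-q))`,
#' `D_max = min(p*(1-q), (1-p)*q)`.
#'
#' @param p Marker allele frequency in `[0, 1]`.
#' @param q Disease allele frequency in `[0, 1]`.
#' @return Named numeric vector `c(D_min, D_max)` with `D_min <= 0 <= D_max`.
#'   Degenerate frequencies (0 or 1) collapse the interval to `{0}`.
#' @examples
#' d_bounds(0.5, 0.01)  # (-0.005, 0.005)
#' d_bounds(0.3, 0.3)   # (-0.09, 0.21)
#' @export
d_bounds <- function(p, q) {
  .check_freq(p, "p")
  .check_freq(q, "q")
  c(D_min = max(-p * q, -(1 - p) * (1 - q)),
    D_max = min(p * (1 - q), (1 - p) * q))
}

#' Theoretical bounds for the MA haplotype frequency g11
#'
#' `g11 = p*q + D`, so the feasible interval is the D interval shifted by
#' `p*q`: `max(0, p + q - 1) <= g11 <= min(p, q)`.
#'
#' @inheritParams d_bounds
#' @return Named numeric vector `c(g_min, g_max)`.
#' @export
g11_bounds <- function(p, q) {
  .check_freq(p, "p")
  .check_freq(q, "q")
  c(g_min = max(0, p + q - 1), g_max = min(p, q))
}

#' Two-locus population parameters (p, q, D)
#'
#' Bundles the marker allele frequency `p`, disease allele frequency `q` and
#' the LD coefficient `D` on the gamete-frequency scale, after checking that
#' `D` lies inside its theoretical bounds (so that the four implied gamete
#' frequencies are a valid probability distribution).
#'
#' @inheritParams d_bounds
#' @param D LD coefficient; must lie within [d_bounds()].
#' @return An object of class `ld_params`.
#' @seealso [haplotype_freqs()], [d_bounds()]
#' @examples
#' pp <- ld_params(0.5, 0.5, 0.2)
#' haplotype_freqs(pp)
#' @export
ld_params <- function(p, q, D = 0) {
  .check_freq(p, "p")
  .check_freq(q, "q")
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D))
    stop("`D` must be a single finite number", call. = FALSE)
  b <- d_bounds(p, q)
  if (D < b[[1]] - 1e-12 || D > b[[2]] + 1e-12)
    stop(sprintf("D = %g outside theoretical bounds [%g, %g] for p = %g, q = %g",
                 D, b[[1]], b[[2]], p, q), call. = FALSE)
  structure(list(p = unname(p), q = unname(q), D = unname(D)),
            class = "ld_params")
}

#' Gamete (haplotype) frequencies implied by (p, q, D)
#'
#' @param params An [ld_params()] object.
#' @return Named vector `c(g11, g12, g21, g22)` for gametes MA, Ma, mA, ma.
#'   Tiny negative values from floating-point cancellation are clamped to 0.
#' @export
haplotype_freqs <- function(params) {
  stopifnot(inherits(params, "ld_params"))
  g <- c(g11 = params$p * params$q + params$D,
         g12 = params$p * (1 - params$q) - params$D,
         g21 = (1 - params$p) * params$q - params$D,
         g22 = (1 - params$p) * (1 - params$q) + params$D)
  pmin(pmax(g, 0), 1)
}

#' @export
print.ld_params <- function(x, ...) {
  b <- d_bounds(x$p, x$q)
  cat(sprintf("Two-locus population: p = %g, q = %g, D = %g (bounds [%g, %g])\n",
              x$p, x$q, x$D, b[[1]], b[[2]]))
  invisible(x)
}
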