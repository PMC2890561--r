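# Pairwise LD scan of a genotype panel against a focal (disease) locus.

# Cross-tabulate marker x focal codes into a 3x3 table; code 2 = two copies
# of the designated allele (MM / AA), code 0 = none.
.pair_table <- function(marker_codes, focal_codes) {
  keep <- !is.na(marker_codes) & !is.na(focal_codes)
  m <- marker_codes[keep]
  f <- focal_codes[keep]
  x <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2)
    x[3 - i, 3 - j] <- sum(m == i & f == j)
  genotype_counts(x)
}

#' Pairwise LD scan against a focal locus
#'
#' For every non-focal locus, builds the 3x3 marker x focal genotype count
#' table on pairwise-complete individuals and estimates D (with LOD and
#' theoretical bounds computed from that pair's allele frequencies). This
#' is the scan used to survey disequilibrium around a disease mutation in a
#' case-enriched panel; with `method = "L"` every reported estimate is
#' guaranteed to respect its theoretical bounds.
#'
#' @param matrix_ A [genotype_matrix()].
#' @param focal Name of the focal (disease) locus.
#' @param method `"L"` (conditional) or `"H"` (joint EM; `h_mode`
#'   `"replication"` reproduces the out-of-bounds behavior of the joint
#'   method on ascertained panels).
#' @param p_source `"sample"` (marker allele counting on pairwise-complete
#'   individuals) or `"controls"` (controls only; requires labels).
#' @param q_value Optional fixed disease-allele frequency (e.g. from a
#'   population survey). Default: allele counting at the focal locus.
#' @param h_mode Passed to [mle_D_joint()] for `method = "H"`.
#' @return Data frame, one row per non-focal locus: `locus`, `n_complete`,
#'   `p_hat`, `q_used`, `D_min`, `D_max`, `D_hat`, `lod`, `p_value`,
#'   `p_bonf`, `out_of_bounds`, `skipped` (monomorphic loci are flagged and
#'   carry NA estimates).
#' @export
ld_scan <- function(matrix_, focal, method = c("L", "H"),
                    p_source = c("sample", "controls"), q_value = NULL,
                    h_mode = c("strict", "replication")) {
  stopifnot(inherits(matrix_, "genotype_matrix"))
  method <- match.arg(method)
  p_source <- match.arg(p_source)
  h_mode <- match.arg(h_mode)
  if (!focal %in% matrix_$loci)
    stop("focal locus not found: ", focal, call. = FALSE)
  if (p_source == "controls" && is.null(matrix_$labels))
    stop("p_source = 'controls' requires case/control labels", call. = FALSE)
  others <- setdiff(matrix_$loci, focal)
  fc <- matrix_$codes[, focal]
  rows <- vector("list", length(others))
  for (k in seq_along(others)) {
    loc <- others[k]
    mc <- matrix_$codes[, loc]
    counts <- .pair_table(mc, fc)
    n_complete <- sum(counts)
    row <- data.frame(locus = loc, n_complete = n_complete,
                      p_hat = NA_real_, q_used = NA_real_,
                      D_min = NA_real_, D_max = NA_real_, D_hat = NA_real_,
                      lod = NA_real_, p_value = NA_real_, p_bonf = NA_real_,
                      out_of_bounds = FALSE, skipped = TRUE,
                      stringsAsFactors = FALSE)
    if (n_complete >= 1) {
      af <- allele_freqs(counts)
      p_hat <- if (p_source == "controls") {
        keep <- matrix_$labels == "control" & !is.na(mc) & !is.na(fc)
        ctrl <- mc[keep]
        if (!length(ctrl)) NA_real_ else sum(ctrl) / (2 * length(ctrl))
      } else af[["p"]]
      q_used <- if (is.null(q_value)) af[["q"]] else q_value
      if (is.finite(p_hat) && !.is_degenerate_freq(p_hat) &&
          !.is_degenerate_freq(q_used)) {
        est <- estimate_ld(counts, p_hat, q_used, method = method,
                           h_mode = h_mode)
        b <- d_bounds(p_hat, q_used)
        row$p_hat <- p_hat; row$q_used <- q_used
        row$D_min <- b[[1]]; row$D_max <- b[[2]]
        row$D_hat <- est$D_hat; row$lod <- est$lod
        row$p_value <- est$p_value
        row$out_of_bounds <- isTRUE(est$out_of_bounds)
        row$skipped <- FALSE
      }
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  m_eff <- sum(!out$skipped)
  out$p_bonf <- pmin(1, out$p_value * max(1, m_eff))
  out
}
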