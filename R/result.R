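# Container for an LD estimation result.

new_ld_estimate <- function(method, D_hat, p_used, q_used,
                            p_source = "supplied", q_source = "supplied",
                            loglik_at_Dhat = NA_real_, loglik_at_0 = NA_real_,
                            lambda = NA_real_, lod = NA_real_,
                            p_value = NA_real_, bounds = c(NA_real_, NA_real_),
                            at_boundary = FALSE, out_of_bounds = FALSE,
                            degenerate = FALSE, extra = list()) {
  structure(c(list(method = method, D_hat = D_hat,
                   p_used = p_used, q_used = q_used,
                   p_source = p_source, q_source = q_source,
                   loglik_at_Dhat = loglik_at_Dhat, loglik_at_0 = loglik_at_0,
                   lambda = lambda, lod = lod, p_value = p_value,
                   bounds = unname(bounds),
                   at_boundary = at_boundary, out_of_bounds = out_of_bounds,
                   degenerate = degenerate), extra),
            class = "ld_estimate")
}

#' @export
print.ld_estimate <- function(x, ...) {
  cat(sprintf("LD estimate (method %s)\n", x$method))
  cat(sprintf("  D_hat = %.6g  (bounds [%.6g, %.6g])%s%s\n",
              x$D_hat, x$bounds[1], x$bounds[2],
              if (isTRUE(x$at_boundary)) " [at boundary]" else "",
              if (isTRUE(x$out_of_bounds)) " [OUT OF BOUNDS]" else ""))
  cat(sprintf("  p = %.4g (%s), q = %.4g (%s)\n",
              x$p_used, x$p_source, x$q_used, x$q_source))
  if (is.finite(x$lambda))
    cat(sprintf("  Lambda = %.4g, LOD = %.4g, p-value = %.3g\n",
                x$lambda, x$lod, x$p_value))
  if (isTRUE(x$degenerate)) cat("  (degenerate allele frequencies)\n")
  invisible(x)
}

#' @export
as.data.frame.ld_estimate <- function(x, ...) {
  data.frame(method = x$method, D_hat = x$D_hat,
             p_used = x$p_used, q_used = x$q_used,
             p_source = x$p_source, q_source = x$q_source,
             D_min = x$bounds[1], D_max = x$bounds[2],
             lambda = x$lambda, lod = x$lod, p_value = x$p_value,
             at_boundary = x$at_boundary, out_of_bounds = x$out_of_bounds,
             degenerate = x$degenerate, stringsAsFactors = FALSE)
}
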