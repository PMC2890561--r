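# Monte-Carlo samplers for the three sampling designs and the replication
# driver aggregating estimator performance over many simulated samples.
#
# Scheme I   : n individuals drawn at random (multinomial on the joint
#              genotype distribution).
# Scheme II  : as Scheme I but one marker genotype class (n_i. = 0) or one
#              marker-disease cell (n_ii = 0) is excluded during sampling;
#              sampling continues until n individuals are collected, which
#              is distributionally a multinomial on the renormalized table.
# Scheme III : case-control: fixed numbers of cases (disease genotype AA or
#              Aa) and controls (aa), marker genotypes drawn conditionally.

.EXCLUDED_CODES <- c("n1.", "n2.", "n3.", "n11", "n22", "n33")

#' Specification of a simulated sampling design
#'
#' @param scheme 1, 2 or 3 (or "I"/"II"/"III").
#' @param p,q,D Population parameters (validated via [ld_params()]).
#' @param n Total sample size (Schemes I and II; for Scheme III it is
#'   derived as `n_case + n_control`).
#' @param excluded Scheme II only: one of `"n1."`, `"n2."`, `"n3."` (marker
#'   genotype row MM/Mm/mm excluded) or `"n11"`, `"n22"`, `"n33"` (diagonal
#'   marker-disease cell excluded).
#' @param n_case,n_control Scheme III only: numbers of cases and controls.
#' @param q_mode Scheme III only: `"survey"` (use the population `q`, as
#'   from an epidemiological survey) or `"sample"` (allele counting on the
#'   pooled case-control sample).
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(scheme, p, q, D, n = NULL, excluded = NULL,
                        n_case = NULL, n_control = NULL,
                        q_mode = c("survey", "sample")) {
  if (is.character(scheme)) {
    scheme <- if (grepl("^[0-9]+$", scheme)) as.numeric(scheme) else
      match(toupper(scheme), c("I", "II", "III"))
  }
  scheme <- as.integer(scheme)
  if (!scheme %in% 1:3) stop("`scheme` must be 1, 2 or 3", call. = FALSE)
  params <- ld_params(p, q, D)
  q_mode <- match.arg(q_mode)
  if (scheme %in% 1:2) {
    if (is.null(n) || n < 1) stop("`n` required for Schemes I/II", call. = FALSE)
    n <- as.integer(n)
  }
  if (scheme == 2) {
    if (is.null(excluded) || length(excluded) != 1L ||
        !excluded %in% .EXCLUDED_CODES)
      stop("Scheme II requires `excluded`, one of: ",
           paste(.EXCLUDED_CODES, collapse = ", "), call. = FALSE)
  } else {
    excluded <- NULL
  }
  if (scheme == 3) {
    if (is.null(n_case) || is.null(n_control) || n_case < 1 || n_control < 1)
      stop("Scheme III requires positive `n_case` and `n_control`",
           call. = FALSE)
    n_case <- as.integer(n_case); n_control <- as.integer(n_control)
    n <- n_case + n_control
  } else {
    n_case <- NULL; n_control <- NULL
  }
  structure(list(scheme = scheme, params = params, n = n,
                 excluded = excluded, n_case = n_case,
                 n_control = n_control, q_mode = q_mode),
            class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("Sampling Scheme %s: p = %g, q = %g, D = %g, n = %d\n",
              c("I", "II", "III")[x$scheme],
              x$params$p, x$params$q, x$params$D, x$n))
  if (x$scheme == 2) cat("  excluded class:", x$excluded, "\n")
  if (x$scheme == 3)
    cat(sprintf("  %d cases + %d controls, q from %s\n",
                x$n_case, x$n_control, x$q_mode))
  invisible(x)
}

.rmultinom_table <- function(n, prob) {
  genotype_counts(matrix(stats::rmultinom(1, n, as.vector(prob)), 3, 3))
}

#' Scheme I: random sample from the joint genotype distribution
#'
#' @param params An [ld_params()] object.
#' @param n Sample size.
#' @return A [genotype_counts()] table with `sum = n`.
#' @export
sample_scheme1 <- function(params, n) {
  .rmultinom_table(n, joint_probs(params))
}

.excluded_mask <- function(excluded) {
  m <- matrix(FALSE, 3, 3)
  row <- match(excluded, c("n1.", "n2.", "n3."))
  if (!is.na(row)) m[row, ] <- TRUE
  cell <- match(excluded, c("n11", "n22", "n33"))
  if (!is.na(cell)) m[cell, cell] <- TRUE
  m
}

#' Scheme II: random sample with one genotype class excluded
#'
#' Individuals of the excluded class are rejected and sampling continues
#' until `n` individuals are obtained; this is distributionally identical
#' to a multinomial draw from the renormalized joint distribution with the
#' excluded class zeroed (`method = "renormalize"`, the default). The
#' literal rejection sampler is kept for validation.
#'
#' @inheritParams sample_scheme1
#' @param excluded Exclusion code, see [scheme_spec()].
#' @param method `"renormalize"` or `"rejection"`.
#' @return A [genotype_counts()] table with zeros in the excluded class.
#' @export
sample_scheme2 <- function(params, n, excluded,
                           method = c("renormalize", "rejection")) {
  method <- match.arg(method)
  if (!excluded %in% .EXCLUDED_CODES)
    stop("`excluded` must be one of: ",
         paste(.EXCLUDED_CODES, collapse = ", "), call. = FALSE)
  P <- unclass(joint_probs(params))
  mask <- .excluded_mask(excluded)
  kept <- sum(P[!mask])
  if (kept <= 0)
    stop("excluded class has probability 1: nothing left to sample",
         call. = FALSE)
  if (method == "renormalize") {
    P[mask] <- 0
    .rmultinom_table(n, P / sum(P))
  } else {
    counts <- matrix(0, 3, 3)
    remaining <- n
    pv <- as.vector(P)
    keep_idx <- which(!as.vector(mask))
    while (remaining > 0) {
      batch <- max(16L, ceiling(remaining / kept * 1.2))
      draw <- stats::rmultinom(1, batch, pv)
      draw[-keep_idx] <- 0
      take <- min(remaining, sum(draw))
      # accept individuals in draw order until quota filled
      if (sum(draw) > take) {
        idx <- rep(seq_len(9), draw)
        idx <- idx[sample.int(length(idx))][seq_len(take)]
        draw <- tabulate(idx, nbins = 9)
      }
      counts <- counts + matrix(draw, 3, 3)
      remaining <- n - sum(counts)
    }
    genotype_counts(counts)
  }
}

#' Scheme III: case-control sample
#'
#' Draws `n_case` cases (disease genotype AA or Aa, in the HWE-conditional
#' ratio `q^2 : 2q(1-q)`) and `n_control` controls (aa). Each individual's
#' marker genotype is generated from its two gametes: a gamete carrying the
#' disease allele A bears the marker allele M with probability
#' `P(M|A) = (pq + D)/q`, a gamete carrying a with probability
#' `P(M|a) = (p(1-q) - D)/(1-q)`. This is exact conditional sampling, with
#' no rejection even for rare diseases.
#'
#' @inheritParams sample_scheme1
#' @param n_case,n_control Numbers of cases and controls.
#' @return An object of class `case_control_sample`: list with elements
#'   `cases`, `controls` (each a [genotype_counts()] table), `combined`,
#'   `n_case`, `n_control`.
#' @export
sample_scheme3 <- function(params, n_case, n_control) {
  p <- params$p; q <- params$q
  if (q <= 0 || q >= 1)
    stop("Scheme III requires 0 < q < 1 (both cases and controls must exist)",
         call. = FALSE)
  g <- haplotype_freqs(params)
  pMA <- g[["g11"]] / q        # P(marker M | gamete carries A)
  pMa <- g[["g12"]] / (1 - q)  # P(marker M | gamete carries a)

  cases <- matrix(0, 3, 3)
  n_AA <- stats::rbinom(1, n_case, q / (2 - q))  # q^2 / (q^2 + 2q(1-q))
  n_Aa <- n_case - n_AA
  if (n_AA > 0)  # both gametes carry A
    cases[, 1] <- stats::rmultinom(1, n_AA,
                                   c(pMA^2, 2 * pMA * (1 - pMA), (1 - pMA)^2))
  if (n_Aa > 0)  # one A gamete, one a gamete
    cases[, 2] <- stats::rmultinom(1, n_Aa,
                                   c(pMA * pMa,
                                     pMA * (1 - pMa) + (1 - pMA) * pMa,
                                     (1 - pMA) * (1 - pMa)))
  controls <- matrix(0, 3, 3)
  controls[, 3] <- stats::rmultinom(1, n_control,
                                    c(pMa^2, 2 * pMa * (1 - pMa), (1 - pMa)^2))
  cases <- genotype_counts(cases)
  controls <- genotype_counts(controls)
  structure(list(cases = cases, controls = controls,
                 combined = genotype_counts(unclass(cases) + unclass(controls)),
                 n_case = n_case, n_control = n_control),
            class = "case_control_sample")
}

#' @export
print.case_control_sample <- function(x, ...) {
  cat(sprintf("Case-control sample: %d cases, %d controls\n",
              x$n_case, x$n_control))
  print(unclass(x$combined))
  invisible(x)
}

#' Scheme-appropriate allele-frequency estimation
#'
#' Schemes I/II: allele counting on the full sample. Scheme III: the marker
#' frequency `p` is counted from the controls only (no selection acts on
#' their marker genotypes); the disease frequency `q` is either the
#' population (survey) value or counted from the pooled sample, per the
#' spec's `q_mode`.
#'
#' @param sample A [genotype_counts()] table (Schemes I/II) or
#'   `case_control_sample` (Scheme III).
#' @param spec The [scheme_spec()] that generated the sample.
#' @return List with `p_hat`, `q_hat`, `p_source`, `q_source`.
#' @export
estimate_freqs <- function(sample, spec) {
  stopifnot(inherits(spec, "scheme_spec"))
  if (spec$scheme %in% 1:2) {
    af <- allele_freqs(sample)
    return(list(p_hat = af[["p"]], q_hat = af[["q"]],
                p_source = "sample", q_source = "sample"))
  }
  stopifnot(inherits(sample, "case_control_sample"))
  if (sum(sample$controls) <= 0)
    stop("empty control sub-sample", call. = FALSE)
  p_hat <- allele_freqs(sample$controls)[["p"]]
  if (spec$q_mode == "survey") {
    list(p_hat = p_hat, q_hat = spec$params$q,
         p_source = "controls", q_source = "survey")
  } else {
    list(p_hat = p_hat, q_hat = allele_freqs(sample$combined)[["q"]],
         p_source = "controls", q_source = "sample")
  }
}

.draw_sample <- function(spec) {
  switch(spec$scheme,
         sample_scheme1(spec$params, spec$n),
         sample_scheme2(spec$params, spec$n, spec$excluded),
         sample_scheme3(spec$params, spec$n_case, spec$n_control))
}

#' Replicated simulation study for one sampling configuration
#'
#' Runs `reps` independent cycles of sample -> allele-frequency estimation
#' -> D estimation (+ LRT/LOD) for the requested methods, and aggregates
#' means and standard deviations, mirroring one row of the bias/power
#' tables. Per-replicate seeds are drawn once from `base_seed`, so runs are
#' reproducible and replicates are independent.
#'
#' @param spec A [scheme_spec()].
#' @param reps Number of replicates (>= 2).
#' @param methods Character subset of `c("L", "H")`.
#' @param base_seed Integer seed for the whole study.
#' @param h_mode Mode for [mle_D_joint()] (`"strict"` or `"replication"`).
#' @param l_freqs Frequency source for Method L under Schemes I/II:
#'   `"scheme"` (default) uses [estimate_freqs()] (allele counting on the
#'   sample); `"survey"` plugs in the true simulated `(p, q)`, the variant
#'   under which the conditional estimator is provably insensitive to
#'   marker-class exclusion (see the methods vignette). Scheme III is
#'   unaffected (p from controls, q per `q_mode` in both variants). Method
#'   H always uses [estimate_freqs()].
#' @param keep_draws If TRUE, per-replicate estimates are kept in `$draws`.
#' @return An object of class `sim_summary`.
#' @export
replicate_study <- function(spec, reps = 1000, methods = c("L", "H"),
                            base_seed = 1L, h_mode = c("strict", "replication"),
                            l_freqs = c("scheme", "survey"),
                            keep_draws = FALSE) {
  stopifnot(inherits(spec, "scheme_spec"), reps >= 2)
  h_mode <- match.arg(h_mode)
  l_freqs <- match.arg(l_freqs)
  methods <- match.arg(methods, c("L", "H"), several.ok = TRUE)
  set.seed(base_seed)
  seeds <- sample.int(2147483646L, reps, replace = FALSE)
  D_L <- lod_L <- lam_L <- D_H <- lod_H <- rep(NA_real_, reps)
  oob_H <- rep(NA, reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    ok <- tryCatch({
      smp <- .draw_sample(spec)
      fr <- estimate_freqs(smp, spec)
      counts <- if (inherits(smp, "case_control_sample")) smp$combined else smp
      if ("L" %in% methods) {
        if (l_freqs == "survey" && spec$scheme %in% 1:2) {
          pl <- spec$params$p; ql <- spec$params$q
        } else {
          pl <- fr$p_hat; ql <- fr$q_hat
        }
        rl <- lrt_lod(mle_D_conditional(counts, pl, ql))
        D_L[r] <- rl$D_hat; lod_L[r] <- rl$lod; lam_L[r] <- rl$lambda
      }
      if ("H" %in% methods) {
        rh <- suppressWarnings(
          mle_D_joint(counts, fr$p_hat, fr$q_hat, mode = h_mode))
        D_H[r] <- rh$D_hat; lod_H[r] <- rh$lod; oob_H[r] <- rh$out_of_bounds
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failures <- failures + 1L
  }
  summ <- function(x) c(mean = mean(x, na.rm = TRUE),
                        sd = stats::sd(x, na.rm = TRUE))
  out <- structure(list(
    spec = spec, reps = reps, methods = methods, h_mode = h_mode,
    l_freqs = l_freqs, base_seed = base_seed, failures = failures,
    D_L = summ(D_L), lod_L = summ(lod_L), lambda_L = summ(lam_L),
    D_H = summ(D_H), lod_H = summ(lod_H),
    oob_frac = if ("H" %in% methods) mean(oob_H, na.rm = TRUE) else NA_real_),
    class = "sim_summary")
  if (keep_draws)
    out$draws <- data.frame(D_L = D_L, lod_L = lod_L, lambda_L = lam_L,
                            D_H = D_H, lod_H = lod_H, oob_H = oob_H)
  if (failures > 0)
    warning(sprintf("%d of %d replicates failed and were dropped",
                    failures, reps))
  out
}

#' @export
print.sim_summary <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d replicates (%d failed), seed %d\n",
              x$reps, x$failures, x$base_seed))
  if ("H" %in% x$methods)
    cat(sprintf("  Method H: D = %.4f +/- %.4f  (out-of-bounds fraction %.3f)\n",
                x$D_H[["mean"]], x$D_H[["sd"]], x$oob_frac))
  if ("L" %in% x$methods)
    cat(sprintf("  Method L: D = %.4f +/- %.4f, LOD = %.3f +/- %.3f\n",
                x$D_L[["mean"]], x$D_L[["sd"]],
                x$lod_L[["mean"]], x$lod_L[["sd"]]))
  invisible(x)
}

#' Write a simulation summary row as TSV
#'
#' Columns mirror the bias/power table layout: `scheme p q D n mean_H sd_H
#' mean_L sd_L mean_LOD sd_LOD oob_frac`.
#'
#' @param x A `sim_summary`.
#' @param path Output file path.
#' @export
write_summary_tsv <- function(x, path) {
  stopifnot(inherits(x, "sim_summary"))
  df <- data.frame(scheme = c("I", "II", "III")[x$spec$scheme],
                   p = x$spec$params$p, q = x$spec$params$q,
                   D = x$spec$params$D, n = x$spec$n, reps = x$reps,
                   mean_H = x$D_H[["mean"]], sd_H = x$D_H[["sd"]],
                   mean_L = x$D_L[["mean"]], sd_L = x$D_L[["sd"]],
                   mean_LOD = x$lod_L[["mean"]], sd_LOD = x$lod_L[["sd"]],
                   oob_frac = x$oob_frac)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value simulation configuration file
#'
#' Lines of the form `key = value` (or `key value`); `#` starts a comment.
#' Recognized keys: scheme, p, q, D, n, n_case, n_control, excluded,
#' q_mode, reps, seed, methods (comma-separated).
#'
#' @param path Config file path.
#' @return List with `spec` (a [scheme_spec()]), `reps`, `seed`, `methods`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=?\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line: ", ln, call. = FALSE)
    kv[[m[2]]] <- trimws(m[3])
  }
  num <- function(key) if (is.null(kv[[key]])) NULL else as.numeric(kv[[key]])
  spec <- scheme_spec(scheme = kv$scheme %||% stop("config needs `scheme`"),
                      p = num("p"), q = num("q"), D = num("D"),
                      n = num("n"), excluded = kv$excluded,
                      n_case = num("n_case"), n_control = num("n_control"),
                      q_mode = kv$q_mode %||% "survey")
  methods <- if (is.null(kv$methods)) c("L", "H") else
    toupper(trimws(strsplit(kv$methods, ",")[[1]]))
  list(spec = spec, reps = as.integer(kv$reps %||% 1000),
       seed = as.integer(kv$seed %||% 1), methods = methods)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
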