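test_that("sample_scheme1 draws from the joint distribution", {
  set.seed(1)
  pp <- ld_params(0.5, 0.5, 0.25)
  s <- sample_scheme1(pp, 200)
  expect_equal(sum(s), 200)
  # complete LD: only the diagonal cells have positive probability
  off <- unclass(s); diag(off) <- 0
  expect_equal(sum(off), 0)
  # law of large numbers: cell frequencies match joint_probs within 3 SE
  pp2 <- ld_params(0.3, 0.4, 0.05)
  P <- unclass(joint_probs(pp2))
  reps <- 2000; n <- 100
  acc <- matrix(0, 3, 3)
  for (r in seq_len(reps)) acc <- acc + unclass(sample_scheme1(pp2, n))
  freq <- acc / (reps * n)
  se <- sqrt(P * (1 - P) / (reps * n))
  expect_true(all(abs(freq - P) <= 3 * se + 1e-12))
})

test_that("sample_scheme2 zeroes the excluded class and renormalizes", {
  set.seed(2)
  pp <- ld_params(0.3, 0.3, 0.09)
  s_row <- sample_scheme2(pp, 200, "n2.")
  expect_equal(sum(s_row), 200)
  expect_equal(unname(unclass(s_row)[2, ]), c(0, 0, 0))
  s_cell <- sample_scheme2(pp, 200, "n22")
  expect_equal(s_cell[2, 2], 0)
  # excluding an impossible class leaves the distribution unchanged
  pp_ld <- ld_params(0.5, 0.5, 0.25)   # P(MmAA) = 0
  expect_silent(sample_scheme2(pp_ld, 50, "n11"))
  expect_error(scheme_spec(2, 0.3, 0.3, 0.09, n = 200), "excluded")
  # rejection sampling and renormalized multinomial agree in distribution
  reps <- 400; n <- 100
  em <- ldnr:::.excluded_mask("n2.")
  P <- unclass(joint_probs(pp)); P[em] <- 0; P <- P / sum(P)
  acc_a <- acc_b <- matrix(0, 3, 3)
  for (r in seq_len(reps)) {
    acc_a <- acc_a + unclass(sample_scheme2(pp, n, "n2."))
    acc_b <- acc_b + unclass(sample_scheme2(pp, n, "n2.", method = "rejection"))
  }
  keep <- P > 0
  exp_counts <- reps * n * P[keep]
  chi_a <- sum((acc_a[keep] - exp_counts)^2 / exp_counts)
  chi_b <- sum((acc_b[keep] - exp_counts)^2 / exp_counts)
  crit <- stats::qchisq(0.999, df = sum(keep) - 1)
  expect_lt(chi_a, crit)
  expect_lt(chi_b, crit)
})

test_that("sample_scheme3 separates cases and controls correctly", {
  set.seed(3)
  pp <- ld_params(0.5, 0.1, 0.04)
  s <- sample_scheme3(pp, 100, 100)
  expect_equal(sum(s$cases), 100)
  expect_equal(sum(s$controls), 100)
  expect_equal(sum(unclass(s$cases)[, 3]), 0)        # cases: AA/Aa only
  expect_equal(sum(unclass(s$controls)[, 1:2]), 0)   # controls: aa only
  # case AA:Aa split follows the conditional HWE ratio q^2 : 2q(1-q)
  q <- 0.1
  reps <- 400
  nAA <- 0
  for (r in seq_len(reps)) {
    s2 <- sample_scheme3(pp, 50, 1)
    nAA <- nAA + sum(unclass(s2$cases)[, 1])
  }
  pAA <- q / (2 - q)
  se <- sqrt(pAA * (1 - pAA) / (reps * 50))
  expect_lt(abs(nAA / (reps * 50) - pAA), 4 * se)
  # D = 0: control marker allele frequency is p
  pp0 <- ld_params(0.4, 0.1, 0)
  tot <- 0; m <- 0
  for (r in seq_len(200)) {
    s3 <- sample_scheme3(pp0, 1, 100)
    m <- m + 2 * sum(unclass(s3$controls)[1, ]) + sum(unclass(s3$controls)[2, ])
    tot <- tot + 200
  }
  expect_lt(abs(m / tot - 0.4), 4 * sqrt(0.4 * 0.6 / tot))
})

test_that("estimate_freqs follows scheme-specific sources", {
  spec1 <- scheme_spec(1, 0.5, 0.5, 0.2, n = 200)
  all_MmAa <- genotype_counts(matrix(c(0, 0, 0, 0, 200, 0, 0, 0, 0), 3, 3))
  fr <- estimate_freqs(all_MmAa, spec1)
  expect_equal(fr$p_hat, 0.5)
  expect_equal(fr$q_hat, 0.5)
  expect_equal(fr$p_source, "sample")
  spec3 <- scheme_spec(3, 0.5, 0.01, 0.004, n_case = 100, n_control = 100,
                       q_mode = "survey")
  set.seed(4)
  s <- sample_scheme3(spec3$params, 100, 100)
  fr3 <- estimate_freqs(s, spec3)
  expect_equal(fr3$q_hat, 0.01)          # survey value, exactly
  expect_equal(fr3$q_source, "survey")
  expect_equal(fr3$p_source, "controls")
  expect_equal(fr3$p_hat, allele_freqs(s$controls)[["p"]])
  # sample mode: pooled allele counting
  spec3s <- scheme_spec(3, 0.5, 0.25, 0, n_case = 100, n_control = 100,
                        q_mode = "sample")
  cases <- matrix(0, 3, 3); cases[2, 2] <- 100       # 100 cases, all MmAa
  ctrl <- matrix(0, 3, 3); ctrl[2, 3] <- 100         # 100 controls Mm aa
  cc <- structure(list(cases = genotype_counts(cases),
                       controls = genotype_counts(ctrl),
                       combined = genotype_counts(cases + ctrl),
                       n_case = 100, n_control = 100),
                  class = "case_control_sample")
  fr3s <- estimate_freqs(cc, spec3s)
  expect_equal(fr3s$q_hat, 100 / 400)
  expect_equal(fr3s$q_source, "sample")
})

test_that("replicate_study is deterministic and aggregates sanely", {
  spec <- scheme_spec(1, 0.5, 0.5, 0.2, n = 100)
  a <- replicate_study(spec, reps = 25, base_seed = 99)
  b <- replicate_study(spec, reps = 25, base_seed = 99)
  expect_identical(a$D_L, b$D_L)
  expect_identical(a$D_H, b$D_H)
  expect_identical(a$lod_L, b$lod_L)
  expect_gt(a$D_L[["sd"]], 0)
  expect_equal(a$failures, 0)
  c2 <- replicate_study(spec, reps = 25, base_seed = 100)
  expect_false(identical(a$D_L, c2$D_L))
})

test_that("non-random samples violate marker HWE while random ones do not", {
  set.seed(6)
  pp <- ld_params(0.3, 0.3, 0.09)
  reps <- 200
  rej1 <- rej2 <- 0
  for (r in seq_len(reps)) {
    s1 <- sample_scheme1(pp, 200)
    m1 <- rowSums(unclass(s1))
    if (hwe_chisq(m1[1], m1[2], m1[3])$p_value < 0.05) rej1 <- rej1 + 1
    s2 <- sample_scheme2(pp, 200, "n2.")
    m2 <- rowSums(unclass(s2))
    if (hwe_chisq(m2[1], m2[2], m2[3])$p_value < 0.05) rej2 <- rej2 + 1
  }
  # Scheme I: nominal 5% rate (binomial 3 sigma band around 0.05)
  expect_lt(abs(rej1 / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 1e-9)
  # Scheme II with the heterozygote class removed: overwhelming rejection
  expect_gt(rej2 / reps, 0.99)
  # Scheme III: the disease locus in the pooled sample is wildly non-HWE
  pp3 <- ld_params(0.5, 0.1, 0.04)
  rej3 <- 0
  for (r in seq_len(50)) {
    s3 <- sample_scheme3(pp3, 100, 100)
    dcol <- colSums(unclass(s3$combined))
    if (hwe_chisq(dcol[1], dcol[2], dcol[3])$p_value < 0.05) rej3 <- rej3 + 1
  }
  expect_gte(rej3 / 50, 0.9)
})

test_that("sim config round-trips through the reader", {
  cfg <- tempfile(fileext = ".cfg")
  writeLines(c("# demo config", "scheme = 3", "p = 0.5", "q = 0.1",
               "D = 0.04", "n_case = 100", "n_control = 100",
               "q_mode = survey", "reps = 10", "seed = 7", "methods = L"),
             cfg)
  parsed <- read_sim_config(cfg)
  expect_equal(parsed$spec$scheme, 3L)
  expect_equal(parsed$spec$params$q, 0.1)
  expect_equal(parsed$reps, 10L)
  expect_equal(parsed$methods, "L")
  summ <- replicate_study(parsed$spec, reps = parsed$reps, methods = "L",
                          base_seed = parsed$seed)
  out <- tempfile(fileext = ".tsv")
  write_summary_tsv(summ, out)
  back <- utils::read.delim(out)
  expect_equal(back$mean_L, summ$D_L[["mean"]], tolerance = 1e-12)
  expect_equal(back$scheme, "III")
})
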