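test_that("imputation eligibility and determinism follow the replicate rules", {
  ## 24-column matrix, 6 reps per group; protein rows crafted per case
  design <- make_design(6L)
  g <- paste(design$construct, design$genotype)
  cw <- which(g == "cilia-BioID2 WT")
  base <- matrix(2^20, 4L, 24L,
                 dimnames = list(sprintf("P%d", 1:4), design$sample))
  base["P2", cw[1:2]] <- 0           # 2 of 6 zeros -> eligible
  base["P3", cw[1:4]] <- 0           # 4 of 6 zeros -> untouched
  mat <- lfq_matrix(base, design)

  ip0 <- imputation_params(width_factor = 0, seed = 3L)
  out <- impute_missing(mat, ip0)
  ## no-zero rows unchanged
  expect_identical(out$intensities["P1", ], mat$intensities["P1", ])
  ## >= half zeros retained
  expect_identical(out$intensities["P3", ], mat$intensities["P3", ])
  ## degenerate sd = 0 with width 0: imputed exactly mean - 1.8 * 0
  expect_equal(unname(out$intensities["P2", cw[1:2]]), rep(2^20, 2L))
  ## nonzero entries never modified
  nz <- mat$intensities > 0
  expect_identical(out$intensities[nz], mat$intensities[nz])
  ## deterministic under seed
  m2 <- matrix(2^rnorm(24 * 5, 20, 1), 5L, 24L,
               dimnames = list(sprintf("Q%d", 1:5), design$sample))
  m2[cbind(c(1, 2, 4), c(1, 2, 13))] <- 0
  mat2 <- lfq_matrix(m2, design)
  ipa <- impute_missing(mat2, imputation_params(seed = 11L))
  ipb <- impute_missing(mat2, imputation_params(seed = 11L))
  expect_identical(ipa$intensities, ipb$intensities)
  expect_true(all(is.finite(ipa$intensities)))
  ## literal_mean mode also only touches eligible zeros
  lit <- impute_missing(mat2, imputation_params(mode = "literal_mean",
                                                seed = 5L))
  expect_identical(lit$intensities[m2 > 0], m2[m2 > 0])
})

test_that("group ratios use medians and pseudovalues two units beyond the range", {
  mat <- make_lfq(list(
    A = c(400, 100, 50, 50),          # log2(100/400) = -2
    B = c(1, 2^-3.1, 10, 10),         # min finite ratio -3.1
    C = c(1, 2^2.4, 10, 10),          # max finite ratio +2.4
    D = c(0, 64, 10, 10),             # WT median 0 -> +Inf -> 2.4 + 2
    E = c(64, 0, 10, 10),             # KO median 0 -> -Inf -> -3.1 - 2
    F = c(0, 0, 10, 10)))             # both medians 0 -> dropped
  rr <- suppressMessages(group_log2_ratio(mat, "cilia-BioID2"))
  expect_equal(rr$log2_ratio[rr$protein == "A"], -2, tolerance = 1e-12)
  expect_equal(rr$log2_ratio[rr$protein == "D"], 4.4, tolerance = 1e-9)
  expect_equal(rr$log2_ratio[rr$protein == "E"], -5.1, tolerance = 1e-9)
  expect_identical(rr$ratio_type[rr$protein == "F"], "dropped")
  expect_true(is.na(rr$log2_ratio[rr$protein == "F"]))
  ## substituted values sit strictly outside the finite range by exactly 2
  fin <- rr$log2_ratio[rr$ratio_type == "finite"]
  expect_equal(max(rr$log2_ratio, na.rm = TRUE), max(fin) + 2)
  expect_equal(min(rr$log2_ratio, na.rm = TRUE), min(fin) - 2)
})

test_that("all-infinite ratios abort the contrast", {
  mat <- make_lfq(list(A = c(0, 8, 1, 1), B = c(8, 0, 1, 1)))
  expect_error(group_log2_ratio(mat, "cilia-BioID2"), "infinite")
})

test_that("t-test handles identical groups, single proteins and matches a BH oracle", {
  mat <- make_lfq(list(A = c(50, 50, 50, 50)), n_reps = 3L)
  tt <- ttest_bh(mat, "cilia-BioID2")
  expect_equal(tt$t_p, 1)
  expect_equal(tt$q, 1)          # m = 1: q = p
  ## zero variance, different means -> p ~ 0
  mat2 <- make_lfq(list(A = c(50, 100, 50, 50)), n_reps = 3L)
  expect_equal(ttest_bh(mat2, "cilia-BioID2")$t_p, 0)
  ## BH equals the brute-force step-up oracle on a simulated matrix
  sim <- generate_lfq_experiment(synth_proteomics_params(n_proteins = 300L,
                                                         n_spiked = 30L,
                                                         dropout_slope = 0,
                                                         seed = 17L))
  tt3 <- ttest_bh(sim$matrix, "cilia-BioID2")
  expect_equal(tt3$q, bh_stepup(tt3$t_p), tolerance = 1e-12)
  expect_true(all(tt3$q >= tt3$t_p))
})

test_that("significance A reproduces its closed form and quantile conventions", {
  set.seed(42)
  r <- rnorm(5000)
  qs <- quantile(r, c(0.1587, 0.5, 0.8413), names = FALSE)
  ## a ratio exactly at the median scores 0.5
  r2 <- c(r, qs[2])
  expect_equal(significance_a(r2)[length(r2)], 0.5, tolerance = 1e-12)
  ## closed form at median + 5 * (r1 - r0); the quantiles are re-estimated
  ## on the augmented vector, so recompute the exact z they imply
  r3 <- c(r, qs[2] + 5 * (qs[3] - qs[2]))
  qs3 <- quantile(r3, c(0.1587, 0.5, 0.8413), names = FALSE)
  z <- (r3[length(r3)] - qs3[2]) / (qs3[3] - qs3[2])
  expect_equal(significance_a(r3)[length(r3)], pnorm(-z), tolerance = 1e-12)
  ## numerically ~ erfc(5 / sqrt(2)) / 2 = 2.87e-7
  expect_equal(significance_a(r3)[length(r3)], 2.866516e-07,
               tolerance = 0.02)
  ## degenerate distribution and minimum-size guards
  expect_error(significance_a(rep(1, 100)), "degenerate")
  expect_error(significance_a(rnorm(5)), "at least")
  ## NA ratios pass through as NA
  expect_true(is.na(significance_a(c(r, NA))[5001]))
})

test_that("significance A tail probabilities are calibrated as documented", {
  set.seed(7)
  r <- rnorm(1e4)
  p1 <- significance_a(r)
  ## directional convention: both tails are scored, so P(p <= a) = 2a
  expect_gt(mean(p1 <= 0.05), 0.08)
  expect_lt(mean(p1 <= 0.05), 0.12)
  ## two-sided convention: P(p <= a) = a
  p2 <- significance_a(r, two_sided = TRUE)
  expect_gt(mean(p2 <= 0.05), 0.04)
  expect_lt(mean(p2 <= 0.05), 0.06)
})

test_that("the control filter excludes any-tier-grade control hits and keeps absentees", {
  cil <- data.frame(protein = c("A", "B", "C", "D"))
  ctl <- data.frame(protein = c("A", "B", "C"),
                    q = c(0.01, 0.5, NA), sigA_p = c(0.2, 0.01, NA),
                    ratio_type = c("finite", "finite", "dropped"))
  fl <- NULL
  expect_message(fl <- control_filter(cil, ctl), "absent")
  expect_identical(fl, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("tier assignment follows the two-test stringency table", {
  rows <- data.frame(protein = sprintf("P%d", 1:5),
                     log2_ratio = c(-1, 2, -3, 0.5, -2),
                     t_p = 0.01,
                     q = c(0.01, 0.20, 0.01, 0.20, 0.01),
                     sigA_p = c(0.01, 0.01, 0.20, 0.20, 0.01),
                     control_significant = c(FALSE, FALSE, FALSE, FALSE,
                                             TRUE))
  out <- assign_tiers(rows)
  expect_identical(out$tier, c("Tier1", "Tier2", "Tier3", "NS", "excluded"))
  expect_identical(out$direction,
                   c("depleted", "enriched", "depleted", "none", "none"))
  ## boundaries are inclusive
  out2 <- assign_tiers(transform(rows[1, ], q = 0.05, sigA_p = 0.05))
  expect_identical(out2$tier, "Tier1")
})

test_that("the full pipeline is reproducible and its tier partition is exhaustive", {
  sim <- generate_lfq_experiment(synth_proteomics_params(n_proteins = 400L,
                                                         n_spiked = 30L,
                                                         n_contaminants = 20L,
                                                         seed = 23L))
  d1 <- suppressMessages(run_diff_pipeline(sim$matrix,
                                           imputation_params(seed = 29L)))
  d2 <- suppressMessages(run_diff_pipeline(sim$matrix,
                                           imputation_params(seed = 29L)))
  expect_identical(d1$table, d2$table)
  tab <- d1$table
  scored <- tab[!is.na(tab$tier), ]
  expect_true(all(scored$tier %in%
                    c("Tier1", "Tier2", "Tier3", "NS", "excluded")))
  ## non-excluded proteins carry exactly one tier label; ratios all finite
  expect_true(all(is.finite(scored$log2_ratio)))
  expect_true(all(tab$q >= tab$t_p, na.rm = TRUE))
})

test_that("detection power rises with effect size and replicate number", {
  recall <- function(fc, n_reps) {
    sim <- generate_lfq_experiment(
      synth_proteomics_params(n_proteins = 300L, n_reps = n_reps,
                              n_spiked = 40L, spike_log2fc = -fc,
                              n_contaminants = 0L, dropout_slope = 0,
                              seed = 37L))
    d <- suppressMessages(run_diff_pipeline(sim$matrix,
                                            imputation_params(seed = 41L)))
    sp <- sim$truth$class == "spiked"
    mean(d$table$tier[sp] == "Tier1")
  }
  by_fc <- vapply(c(0.3, 1, 2), recall, 0, n_reps = 6L)
  expect_true(all(diff(by_fc) >= 0))
  by_n <- vapply(c(3L, 6L, 12L), function(n) recall(1, n), 0)
  expect_true(all(diff(by_n) >= -0.02))  # monotone up to sampling noise
})
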