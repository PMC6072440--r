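test_that("hypergeometric downsampling preserves proportions", {
  tab <- data.table::data.table(gene = c("a", "b", "z"),
                                count_BY = c(100L, 200L, 0L),
                                count_RM = c(120L, 180L, 0L))
  # equal grand totals: unchanged
  t0 <- data.table::data.table(gene = c("a", "b"), count_BY = c(10L, 20L),
                               count_RM = c(15L, 15L))
  expect_identical(downsample_counts(t0), t0)
  # zero-count gene stays zero; grand totals match afterwards
  d <- downsample_counts(tab, seed = 5)
  expect_equal(sum(d$count_BY), sum(d$count_RM))
  expect_equal(d$count_BY[3], 0L)
  # halving: per-gene expectation halves (hypergeometric-moment oracle)
  big <- data.table::data.table(gene = paste0("g", 1:4),
                                count_BY = c(400L, 300L, 200L, 100L),
                                count_RM = c(200L, 150L, 100L, 50L))
  means <- Reduce(`+`, lapply(1:400, function(s)
    downsample_counts(big, seed = s)$count_BY)) / 400
  expval <- big$count_BY / 2
  se <- sqrt(big$count_BY * 0.25) / sqrt(400)  # conservative bound
  expect_true(all(abs(means - expval) < 4 * se + 0.5))
})

test_that("binomial ASE test: filters, p-values, Bonferroni, fold changes", {
  tab <- data.table::data.table(
    gene = c("bal", "skew", "small", "zero"),
    count_BY = c(50L, 20L, 10L, 0L),
    count_RM = c(50L, 80L, 9L, 40L))
  res <- ase_test(tab, n_tests = 3340)
  expect_false("small" %in% res$gene)       # 19 reads: excluded
  expect_equal(res$p_value[res$gene == "bal"], 1)
  expect_equal(res$log2_fold_change[res$gene == "bal"], 0)
  expect_false(res$significant[res$gene == "bal"])
  # Bonferroni cutoff for 3340 tests
  expect_equal(attr(res, "cutoff"), 0.05 / 3340)
  expect_lt(attr(res, "cutoff"), 1.5e-5)
  expect_gt(attr(res, "cutoff"), 1.49e-5)
  expect_identical(res$p_value[res$gene == "skew"],
                   binom.test(80, 100, 0.5)$p.value)
  expect_true(res$zero_count_flag[res$gene == "zero"])
  expect_equal(res$log2_fold_change[res$gene == "zero"], log2(40 / 0.5))
})

test_that("ASE p-values are uniform under the binomial null", {
  # coverages vary across genes so the discrete p-value atoms smear out
  set.seed(6)
  totals <- sample(200:3000, 10000, replace = TRUE)
  s <- simulate_ase_counts(totals, 0, rho = 0, seed = 6)
  res <- ase_test(s[, c("gene", "count_BY", "count_RM")], n_tests = 10000)
  # an exact discrete test cannot pass a literal KS-vs-continuous-uniform
  # check at this sample size (atoms at p = 1 alone give D ~ 0.02); assert
  # the operational meaning instead: tail calibration at the levels that
  # drive discovery, within 3 binomial SE plus discreteness slack
  for (a in c(0.001, 0.01, 0.05, 0.1, 0.5)) {
    se <- sqrt(a * (1 - a) / nrow(res))
    expect_lt(abs(mean(res$p_value <= a) - a), 3 * se + 0.01)
  }
  # and no excess of small p-values at all (validity)
  expect_lte(mean(res$p_value <= 0.001), 0.002)
})

test_that("beta-binomial overdispersion is recovered and invariant", {
  s <- simulate_ase_counts(rep(1000L, 3000), 0, rho = 0.005, seed = 7)
  fit <- fit_overdispersion(s[, c("gene", "count_BY", "count_RM")])
  expect_gt(fit$rho, 0.004)
  expect_lt(fit$rho, 0.006)
  # rho = 0 data: estimate collapses to the boundary
  s0 <- simulate_ase_counts(rep(800L, 1500), 0, rho = 0, seed = 8)
  fit0 <- fit_overdispersion(s0[, c("gene", "count_BY", "count_RM")])
  expect_lt(fit0$rho, 0.001)
  # invariance to gene order and dataset duplication
  tab <- s[, c("gene", "count_BY", "count_RM")]
  fit_a <- fit_overdispersion(tab[sample(nrow(tab)), ])
  fit_b <- fit_overdispersion(rbind(tab, tab))
  expect_equal(fit_a$rho, fit$rho, tolerance = 1e-6)
  expect_equal(fit_b$rho, fit$rho, tolerance = 1e-4)
  expect_error(fit_overdispersion(tab[1:5, ]), ">= 10 genes")
  # rho = 0 limit of the density is exactly binomial
  expect_equal(dbetabinom(3, 10, 0.4, 0), dbinom(3, 10, 0.4))
})

test_that("ASE power is calibrated at the null and monotone", {
  pw <- ase_power(total = c(100, 1000), log2fc = c(0, 0.25, 0.5),
                  rho = 0, n_sims = 400, seed = 9)
  p0 <- pw$power_0.05[pw$log2fc == 0]
  expect_true(all(abs(p0 - 0.05) < 0.035))  # discrete-test slack + MC error
  # monotone (up to MC error) in coverage and effect size
  for (tt in c(100, 1000)) {
    pcol <- pw$power_0.05[pw$total == tt]
    expect_true(all(diff(pcol) > -0.05))
  }
  expect_true(all(pw$power_0.05[pw$total == 1000 & pw$log2fc > 0] >=
                    pw$power_0.05[pw$total == 100 & pw$log2fc > 0] - 0.05))
  # sign agreement rises with effect size
  sa <- pw$sign_agreement[pw$total == 1000 & pw$log2fc > 0]
  expect_true(all(diff(sa) > -0.05))
  gm <- ase_power_gene_matched(c(200L, 5000L), c(0.1, 0.1), rho = 0.005,
                               n_sims = 100, seed = 10)
  expect_lte(gm[1], gm[2] + 0.05)
})

test_that("simulated replicate datasets correlate like real hybrids", {
  # two independent draws sharing true per-gene proportions at rho ~ 0.005
  set.seed(11)
  ng <- 2000
  fc <- rnorm(ng, 0, 0.35)
  s1 <- simulate_ase_counts(rep(1000L, ng), fc, rho = 0.005, seed = 12)
  s2 <- simulate_ase_counts(rep(200L, ng), fc, rho = 0.005, seed = 13)
  f1 <- log2((s1$count_RM + 0.5) / (s1$count_BY + 0.5))
  f2 <- log2((s2$count_RM + 0.5) / (s2$count_BY + 0.5))
  expect_gt(cor(f1, f2), 0.35)
  expect_lt(cor(f1, f2), 0.75)
})

test_that("SMA slope and closed-form confidence interval", {
  set.seed(14)
  x <- rnorm(50)
  expect_equal(sma_slope(x, 2 * x)$slope, 2)
  expect_equal(sma_slope(x, -x)$slope, -1)
  expect_error(sma_slope(rep(1, 10), rnorm(10)), "zero variance")
  # bivariate normal with sd_y/sd_x = 0.94, r = 0.67, n = 1974
  n <- 1974
  z1 <- rnorm(n); z2 <- rnorm(n)
  x2 <- z1
  y2 <- 0.94 * (0.67 * z1 + sqrt(1 - 0.67^2) * z2)
  fit <- sma_slope(x2, y2)
  expect_lt(abs(fit$slope - 0.94), 0.03)
  # closed-form CI width: slope * ((sqrt(B+1)+sqrt(B)) - (sqrt(B+1)-sqrt(B)))
  r2 <- fit$r2
  B <- qf(0.95, 1, n - 2) * (1 - r2) / (n - 2)
  expect_equal(diff(fit$slope_ci), fit$slope * 2 * sqrt(B), tolerance = 1e-10)
  expect_true(fit$slope_ci[1] < fit$slope & fit$slope < fit$slope_ci[2])
})
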