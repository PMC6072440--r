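test_that("LOD formula values and regression identity", {
  # frozen high-precision evaluations of -n ln(1-r^2)/(2 ln 10)
  expect_equal(crossqtl:::lod_from_r2(0.025, 1012), 5.5637, tolerance = 1e-4)
  expect_equal(crossqtl:::lod_from_r2(0.1, 100), 2.2879, tolerance = 1e-4)
  expect_equal(crossqtl:::lod_from_r2(0, 500), 0)

  # algebraic identity with (n/2) log10(RSS0/RSS1), 1e-9
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(30:200, 1)
    x <- rmarker(n)
    y <- runif(1, -0.5, 0.5) * x + rnorm(n)
    ls <- lod_scan(y, cbind(x))
    f1 <- lm(y ~ x)
    lod_reg <- (n / 2) * log10(sum((y - mean(y))^2) / sum(resid(f1)^2))
    expect_equal(ls$lod, lod_reg, tolerance = 1e-9)
    expect_equal(sign(ls$r), sign(coef(f1)[2]), ignore_attr = TRUE)
  }
  expect_warning(lod_scan(rnorm(30), cbind(rep(1, 30))), "zero-variance")
})

test_that("fdr_threshold implements the expected/observed count ratio", {
  cfg <- scan_config(n_perm = 1)
  # everything observed far above a silent null: smallest grid value wins
  r1 <- fdr_threshold(c(10, 10, 10), matrix(1.2, 4, 3), cfg)
  expect_equal(r1$threshold, 1.5)
  # direct ratio arithmetic: 5 observed > 3.0, expected 0.1 -> FDR 0.02
  obs <- c(3.4, 3.5, 3.6, 3.7, 3.8)
  perm <- matrix(1.6, 10, 5); perm[1, 1] <- 3.2   # mean count above 3.0 = 0.1
  r2 <- fdr_threshold(obs, perm, cfg)
  tab <- r2$table
  expect_equal(tab$fdr[tab$grid == 3.0], 0.1 / 5)
  expect_lte(r2$threshold, 3.0)
  # observed all below the grid: no detections
  r3 <- fdr_threshold(c(1.0, 1.2), matrix(2.0, 3, 2), cfg)
  expect_true(is.na(r3$threshold))
  # zero observed & zero expected at high T -> FDR 0 there
  expect_equal(tail(tab$fdr, 1), 0)
})

test_that("LOD-drop intervals cover spikes, plateaus and LD groups", {
  lod <- c(0.2, 0.4, 9, 0.5, 0.3)
  ci <- lod_drop_interval(lod, 3)
  expect_equal(c(ci$left, ci$right), c(3, 3))
  lod2 <- c(1, 6.2, 6.4, 6.4, 6.2, 1)
  ci2 <- lod_drop_interval(lod2, 3)
  expect_equal(c(ci2$left, ci2$right), c(2, 5))
  # one-sided at the chromosome end
  ci3 <- lod_drop_interval(c(8, 4, 1), 1)
  expect_equal(ci3$left, 1)
  # LD extension widens the bp bounds to group members
  X <- matrix(rep(rmarker(40), 3), 40, 3)
  X <- cbind(X, rmarker(40))
  colnames(X) <- paste0("chrI_", c(100, 200, 300, 400))
  geno <- structure(list(values = X,
                         map = data.table::data.table(marker = colnames(X),
                                                      chrom = "chrI",
                                                      pos = c(100L, 200L, 300L, 400L)),
                         ld_groups = NULL), class = "genotype_matrix")
  cg <- collapse_perfect_ld(geno)
  lod4 <- c(7, 0.5)
  ci4 <- lod_drop_interval(lod4, 1, geno = cg, chromosome = "chrI")
  expect_equal(ci4$bp_lo, 100)
  expect_equal(ci4$bp_hi, 300)  # members of the collapsed peak marker
})

test_that("local classification honours the strand-aware window", {
  ann <- data.table::data.table(gene = c("gp", "gm", "gx"),
                                chrom = c("chrI", "chrI", "chrII"),
                                start = c(5000L, 5000L, 1000L),
                                end = c(6000L, 6000L, 2000L),
                                strand = c("+", "-", "+"))
  rec <- data.table::data.table(
    gene = c("gp", "gp", "gm", "gx"),
    chrom = c("chrI", "chrI", "chrI", "chrI"),
    peak_marker = "m", peak_pos = c(5500L, 2000L, 6500L, 1500L),
    lod = 5, ci_left_pos = c(5400L, 1000L, 6400L, 1400L),
    ci_right_pos = c(5600L, 4000L, 7000L, 1600L),
    r = 0.3, var_expl = 0.09, step = 1L, threshold = 3)
  out <- classify_local(rec, ann)
  expect_true(out$local[1])          # CI inside gene body
  expect_true(out$local[2])          # CI touches start-1000 exactly (closed)
  expect_true(out$local[3])          # - strand: downstream window reaches 6500
  expect_false(out$local[4])         # other chromosome
  expect_equal(sum(out$primary_local[out$gene == "gp"]), 1)
  expect_true(out$primary_local[1])  # the closer of the two local eQTLs
})

test_that("background screen finds planted large effects", {
  g1 <- fix_one_chrom(n = 500, n_markers = 60, seed = 41)
  X <- g1$values
  set.seed(42)
  # one QTL at 20% variance
  y1 <- sqrt(0.2) * X[, 30] + rnorm(500, 0, sqrt(0.8))
  # three QTLs of ~8% each on one chromosome (well separated)
  y3 <- sqrt(0.08) * (X[, 8] + X[, 30] - X[, 52]) + rnorm(500, 0, sqrt(0.7))
  P <- cbind(q1 = y1, q3 = y3, null = rnorm(500))
  Z <- detect_background_effects(P, NULL, g1, scan_config())
  expect_true(any(abs(g1$map$pos[Z[["q1"]]] - g1$map$pos[30]) < 20000))
  expect_equal(length(Z[["q3"]]), 3)
  hit <- vapply(c(8, 30, 52), function(i)
    any(abs(g1$map$pos[Z[["q3"]]] - g1$map$pos[i]) < 30000), TRUE)
  expect_true(all(hit))
  expect_equal(length(Z[["null"]]), 0)
})

test_that("forward scan separates two linked QTLs and reports signed effects", {
  g1 <- fix_one_chrom(n = 600, n_markers = 80, morgans = 5, seed = 43)
  X <- g1$values
  set.seed(44)
  y <- sqrt(0.10) * X[, 15] - sqrt(0.05) * X[, 65] + rnorm(600, 0, sqrt(0.85))
  P <- matrix(y, dimnames = list(NULL, "g2q"))
  eq <- forward_scan(P, NULL, g1, scan_config(n_perm = 200, seed = 45))
  expect_gte(nrow(eq), 2)
  d1 <- min(abs(eq$peak_pos - g1$map$pos[15]))
  d2 <- min(abs(eq$peak_pos - g1$map$pos[65]))
  expect_lt(d1, 30000)
  expect_lt(d2, 30000)
  r1 <- eq$r[which.min(abs(eq$peak_pos - g1$map$pos[15]))]
  r2 <- eq$r[which.min(abs(eq$peak_pos - g1$map$pos[65]))]
  expect_gt(r1, 0)
  expect_lt(r2, 0)
  # CI contains the peak and the joint r^2 stays below 1
  expect_true(all(eq$ci_left_pos <= eq$peak_pos & eq$peak_pos <= eq$ci_right_pos))
  expect_lt(sum(eq$var_expl), 1 + 1e-8)
})

test_that("cross-validated variance explained matches the planted fraction", {
  g1 <- fix_one_chrom(n = 400, n_markers = 60, seed = 46)
  X <- g1$values
  set.seed(47)
  P <- cbind(qtl = sqrt(0.3) * X[, 30] + rnorm(400, 0, sqrt(0.7)),
             null = rnorm(400))
  cov <- data.table::data.table(batch = factor(rep(1:10, each = 40)),
                                growth = rnorm(400))
  ve <- cross_validated_variance(P, cov, g1,
                                 scan_config(n_perm = 100, seed = 48))
  expect_lt(abs(ve[["qtl"]] - 0.30), 0.05)
  expect_lt(ve[["null"]], 0.02)
  expect_error(cross_validated_variance(P, data.table::data.table(
    batch = factor(rep(1, 400))), g1), "batches")
})

test_that("detection power behaves at the extremes", {
  expect_equal(detection_power(1012, 0.20, 3.5, n_sims = 300, seed = 3), 1)
  p0 <- detection_power(500, 0, 3.5, n_sims = 400, seed = 4)
  expect_lt(p0, 0.02)  # null exceedance of a single test at LOD 3.5
  expect_error(detection_power(100, 1, 3), "variance_explained")
})

test_that("local-only scan rescues weak local eQTLs", {
  g1 <- fix_one_chrom(n = 600, n_markers = 50, seed = 49)
  X <- g1$values
  set.seed(50)
  ng <- 30
  gstart <- as.integer(g1$map$pos[seq(1, 50, length.out = ng)])
  ann <- data.table::data.table(gene = sprintf("g%02d", 1:ng), chrom = "chrI",
                                start = gstart, end = gstart + 1000L,
                                strand = "+")
  closest <- vapply(gstart, function(s) which.min(abs(g1$map$pos - s)), 0L)
  # weak local effects (3% of variance: expected LOD ~4, far below the
  # genome-wide detection range but visible in a one-test-per-gene scan)
  P <- matrix(rnorm(600 * ng), 600, ng, dimnames = list(NULL, ann$gene))
  P[, 1:15] <- P[, 1:15] * sqrt(0.97) +
    X[, closest[1:15]] %*% diag(sqrt(0.03), 15)
  expr <- structure(list(values = P, annotation = ann),
                    class = "expression_matrix")
  res <- local_scan(expr, NULL, g1, scan_config(n_perm = 150, seed = 51))
  expect_gte(sum(res$significant[1:15]), 10)     # most weak locals found
  expect_lte(sum(res$significant[16:30]), 3)     # nulls controlled
  expect_lt(res$threshold[1], 2.5)               # far below genome-wide scale
})

test_that("interaction-to-additive variance ratio summary", {
  f <- function(a, aa) structure(list(sigma2_A = a, sigma2_AA = aa,
                                      sigma2_E = 1), class = "variance_components")
  s <- aa_ratio_summary(list(f(1, 0.1), f(3, 0.3)))
  expect_equal(s$ratio_of_averages, 0.1)
  expect_equal(s$per_gene_ratio, c(0.1, 0.1))
  expect_error(aa_ratio_summary(list(structure(list(sigma2_A = 1, sigma2_AA = NULL),
                                               class = "variance_components"))),
               "two-component")
})
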