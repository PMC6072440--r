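test_that("multivariate LOD reduces to univariate at m=1 and resists rotations", {
  set.seed(51)
  for (rep in 1:100) {
    n <- 60
    x <- rmarker(n)
    y <- 0.3 * x + rnorm(n)
    uni <- lod_scan(y, cbind(x))$lod
    expect_equal(mv_lod(matrix(y), x), uni, tolerance = 1e-9)
  }
  # invariance to invertible recombination of L's columns
  n <- 80
  L <- matrix(rnorm(n * 3), n, 3)
  x <- rmarker(n)
  L[, 1] <- L[, 1] + 0.4 * x
  base <- mv_lod(L, x)
  for (rep in 1:10) {
    Tm <- matrix(rnorm(9), 3, 3)
    while (abs(det(Tm)) < 0.1) Tm <- matrix(rnorm(9), 3, 3)
    expect_equal(mv_lod(L %*% Tm, x), base, tolerance = 1e-8)
  }
  # orthogonal x gives LOD 0
  L0 <- qr.resid(qr(cbind(1, x)), matrix(rnorm(n * 2), n, 2))
  expect_lt(mv_lod(L0, x), 1e-8)
})

test_that("m=2 multivariate LOD matches an explicit dense-algebra oracle", {
  set.seed(52)
  n <- 50
  x <- rmarker(n)
  L <- cbind(0.5 * x + rnorm(n), rnorm(n))
  # independent oracle: explicit projection matrices and eigenvalue determinants
  P0 <- diag(n) - tcrossprod(rep(1, n)) / n
  X1 <- cbind(1, x)
  P1 <- diag(n) - X1 %*% solve(crossprod(X1), t(X1))
  RSS0 <- t(L) %*% P0 %*% L
  RSS1 <- t(L) %*% P1 %*% L
  oracle <- (n / 2) * log10(prod(eigen(RSS0)$values) / prod(eigen(RSS1)$values))
  expect_equal(mv_lod(L, x), oracle, tolerance = 1e-9)
  # vectorized scan agrees with the per-marker computation
  X <- replicate(7, rmarker(n))
  sc <- crossqtl:::mv_scan(L, X)
  for (j in 1:7) expect_equal(sc[j], mv_lod(L, X[, j]), tolerance = 1e-9)
})

test_that("jQTL scan detects planted hotspots and self-extinguishes", {
  g1 <- fix_one_chrom(n = 300, n_markers = 100, seed = 53)
  X <- g1$values
  map_c <- g1$map
  hp <- plant_hotspot(X, hs = 60, ng = 80, seed = 54)
  L <- scores_from(hp$P, 2)
  pk <- jqtl_scan(L, X, map_c, n_perm = 60, seed = 55)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$pos[1] - map_c$pos[60]), 25000)
  # after subtracting the detected effect, the same marker is below threshold
  Lr <- qr.resid(qr(cbind(1, X[, pk$peak_idx[1]])), L)
  expect_lt(crossqtl:::mv_scan(Lr, X)[pk$peak_idx[1]], pk$threshold[1])
  # null matrix: permuted rows give no peaks
  set.seed(56)
  Ln <- L[sample(nrow(L)), ]
  expect_equal(nrow(jqtl_scan(Ln, X, map_c, n_perm = 60, seed = 57)), 0)
})

test_that("two separated hotspots are both recovered", {
  g1 <- fix_one_chrom(n = 400, n_markers = 100, seed = 58)
  X <- g1$values
  set.seed(59)
  P <- cbind(plant_hotspot(X, 25, 60, seed = 60)$P,
             plant_hotspot(X, 75, 60, seed = 61)$P)
  L <- scores_from(P, 3)
  pk <- jqtl_scan(L, X, g1$map, n_perm = 60, seed = 62)
  expect_gte(nrow(pk), 2)
  expect_lt(min(abs(pk$pos - g1$map$pos[25])), 25000)
  expect_lt(min(abs(pk$pos - g1$map$pos[75])), 25000)
  # refinement keeps both true peaks
  rf <- refine_peaks(L, X, g1$map, pk)
  expect_gte(nrow(rf), 2)
})

test_that("residual factors are detected with a calibrated permutation null", {
  st <- fix_study()
  eq <- data.table::data.table(gene = st$truth$genes[1:30],
                               peak_marker = st$geno$map$marker[1:30])
  # pure-noise residuals: expression replaced by noise -> no factor kept
  set.seed(63)
  Pn <- matrix(rnorm(nrow(st$geno$values) * 30), ncol = 30,
               dimnames = list(NULL, st$truth$genes[1:30]))
  fac0 <- residual_factor_covariates(Pn, NULL, eq, st$geno, seed = 64)
  expect_lte(ncol(fac0), 1)
  # one planted shared factor across genes -> exactly one factor, cor > 0.9
  f <- rnorm(nrow(Pn))
  Pf <- Pn + outer(f, runif(30, 0.5, 1))
  colnames(Pf) <- colnames(Pn)
  fac1 <- residual_factor_covariates(Pf, NULL, eq, st$geno, seed = 65)
  expect_equal(ncol(fac1), 1)
  expect_gt(abs(cor(fac1[, 1], f)), 0.9)
  # k_max cap honoured with many planted factors
  set.seed(66)
  # orthonormal factors of equal strength so all 25 clear the retention null
  Fm <- qr.Q(qr(matrix(rnorm(nrow(Pn) * 25), ncol = 25))) * sqrt(nrow(Pn))
  load25 <- matrix(sample(c(-1, 1), 25 * 120, TRUE) * 3, 25, 120)
  Pm <- matrix(rnorm(nrow(Pn) * 120), ncol = 120) + Fm %*% load25
  colnames(Pm) <- sprintf("gene_%04d", 1:120)
  eqm <- data.table::data.table(gene = colnames(Pm),
                                peak_marker = st$geno$map$marker[1:120])
  facm <- residual_factor_covariates(Pm, NULL, eqm, st$geno, seed = 67)
  expect_equal(ncol(facm), 20)
  expect_error(residual_factor_covariates(Pn, NULL, eq[0, ], st$geno),
               "no genes")
})

test_that("trans matrix construction keeps only supported components", {
  g1 <- fix_one_chrom(n = 300, n_markers = 60, seed = 68)
  hp <- plant_hotspot(g1$values, hs = 30, ng = 50, seed = 69)
  ann <- data.table::data.table(gene = colnames(hp$P), chrom = "chrV",
                                start = 1000L, end = 2000L, strand = "+")
  eq <- data.table::data.table(gene = colnames(hp$P), chrom = "chrI",
                               peak_marker = g1$map$marker[30])
  tm <- build_trans_matrix("chrI", hp$P, NULL, eq, g1, annotation = ann,
                           seed = 70)
  expect_gte(tm$m, 1)
  expect_gt(abs(cor(tm$L[, 1], g1$values[, 30])), 0.8)
  # genes whose only signal is regressed out -> empty L
  eq2 <- data.table::data.table(gene = colnames(hp$P),
                                chrom = c("chrI", "chrII")[c(1, 2)][
                                  rep(1:2, length.out = 50)],
                                peak_marker = g1$map$marker[30])
  # all signal assigned off-chromosome for half the genes; use noise traits
  set.seed(71)
  Pn <- matrix(rnorm(300 * 50), 300, 50, dimnames = list(NULL, colnames(hp$P)))
  tmn <- build_trans_matrix("chrI", Pn, NULL, eq, g1, annotation = ann,
                            seed = 72)
  expect_equal(tmn$m, 0)
})

test_that("ghost test is gated and bootstrap CI validates input", {
  g1 <- fix_one_chrom(n = 200, n_markers = 60, seed = 73)
  hp <- plant_hotspot(g1$values, hs = 30, ng = 30, seed = 74)
  L <- scores_from(hp$P, 2)
  # moderate peak: below the LOD-200 gate -> not tested
  gt <- ghost_test(L, g1$values, g1$map, peak_idx = 30, n_perm = 20, seed = 75)
  expect_false(gt$tested)
  expect_false(gt$two_locus)
  expect_error(bootstrap_ci(L, g1$values, g1$map, 30, B = 0), "B must")
  # overwhelming effect: every bootstrap peak identical
  y <- g1$values[, 30] + 0.01 * rnorm(200)
  bc <- bootstrap_ci(matrix(y), g1$values, g1$map, 30, B = 50, seed = 76)
  expect_equal(bc$ci_lo, g1$map$pos[30])
  expect_equal(bc$ci_hi, g1$map$pos[30])
})

test_that("hotspot target counts are FDR-consistent", {
  g1 <- fix_one_chrom(n = 400, n_markers = 50, seed = 77)
  X <- g1$values
  ng <- 150; n_aff <- 60
  set.seed(78)
  P <- matrix(rnorm(400 * ng), 400, ng,
              dimnames = list(NULL, sprintf("gene_%04d", 1:ng)))
  b <- runif(n_aff, 0.25, 0.4) * sample(c(-1, 1), n_aff, TRUE)
  P[, 1:n_aff] <- P[, 1:n_aff] + X[, 25] %*% t(b)
  ann <- data.table::data.table(gene = colnames(P), chrom = "chrV",
                                start = 1000L, end = 2000L, strand = "+")
  eq <- data.table::data.table(gene = character(), chrom = character(),
                               peak_marker = character(), local = logical(),
                               primary_local = logical())
  ht <- hotspot_targets(P, NULL, g1, g1$map$marker[25], eq, annotation = ann,
                        cfg = scan_config(n_perm = 100, seed = 79))
  cnt <- ht$counts$n_targets[1]
  expect_gte(cnt, 0.9 * n_aff)
  expect_lte(cnt, n_aff + 0.05 * ng + 3)
  # signs of recovered coefficients match the planted ones
  co <- ht$coefficients[ht$coefficients$gene %in% colnames(P)[1:n_aff], ]
  i <- match(co$gene, colnames(P))
  expect_gte(mean(sign(co$coef) == sign(b[i])), 0.99)
})

test_that("subtelomeric peaks are flagged", {
  map_c <- data.table::data.table(marker = paste0("chrI_", c(1000, 50000, 99000)),
                                  chrom = "chrI", pos = c(1000L, 50000L, 99000L))
  pk <- data.table::data.table(pos = c(3000L, 50000L, 96000L))
  expect_identical(subtelomeric_flag(pk, map_c), c(TRUE, FALSE, TRUE))
})
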