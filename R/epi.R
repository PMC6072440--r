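#' Reduce markers by pairwise-correlation pruning
#'
#' Greedy elimination: while any marker pair has |r| above the cutoff, the
#' member of the worst (highest-|r|) pair with the larger mean absolute
#' correlation to all remaining markers is removed (ties: the leftmost is
#' removed).  Deterministic given the input order.
#'
#' @param geno a \code{genotype_matrix} or plain marker matrix.
#' @param cutoff absolute correlation cutoff (default 0.99).
#' @return integer indices of retained markers (in input order).
#' @export
reduce_markers <- function(geno, cutoff = 0.99) {
  X <- if (inherits(geno, "genotype_matrix")) geno$values else geno
  m <- ncol(X)
  if (m < 2) return(seq_len(m))
  cr <- abs(suppressWarnings(cor(X)))
  cr[!is.finite(cr)] <- 1
  diag(cr) <- 0
  alive <- rep(TRUE, m)
  repeat {
    w <- which.max(cr)
    if (cr[w] <= cutoff) break
    i <- (w - 1) %% m + 1
    j <- (w - 1) %/% m + 1
    mi <- mean(cr[i, alive])
    mj <- mean(cr[j, alive])
    drop <- if (mi > mj) i else if (mj > mi) j else min(i, j)
    alive[drop] <- FALSE
    cr[drop, ] <- 0
    cr[, drop] <- 0
  }
  which(alive)
}

#' Residuals for interaction scanning
#'
#' Per-gene residual after batch/growth covariates, the gene's significant
#' additive eQTLs (fixed effects) and the whole-genome polygenic BLUP.
#'
#' @param expr an \code{expression_matrix} or matrix.
#' @param covariates covariate table.
#' @param eqtls additive eQTL records.
#' @param geno a \code{genotype_matrix}.
#' @return segregants x genes residual matrix.
#' @export
interaction_residual <- function(expr, covariates, eqtls, geno) {
  P <- if (inherits(expr, "expression_matrix")) expr$values else expr
  eig <- kinship_eigen(additive_kinship(geno))
  R <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  for (g in seq_len(ncol(P))) {
    mk <- eqtls$peak_marker[eqtls$gene == colnames(P)[g]]
    fm <- if (length(mk)) geno$values[, mk, drop = FALSE] else NULL
    R[, g] <- polygenic_residual(P[, g], eig, covariates, fm)
  }
  R
}

# Interaction LOD for all pairs of +/-1 markers against one residual
# vector, via closed-form Gram algebra (x^2 = 1 exploited).  Returns the
# full upper-triangular LOD matrix.
pair_lod_matrix <- function(y, X) {
  n <- length(y)
  stopifnot(all(X %in% c(-1, 1)))
  p <- ncol(X)
  s <- colSums(X)
  G <- crossprod(X)
  sy <- sum(y)
  xy <- as.vector(crossprod(X, y))
  yy <- sum(y^2)
  M <- crossprod(X, X * y)            # M[i,j] = sum x_i x_j y
  Syy <- yy - sy^2 / n
  Cd <- n - s^2 / n                   # centred marker variances * n
  lod <- matrix(0, p, p)
  for (i in seq_len(p - 1)) {
    j <- (i + 1):p
    Cij <- G[i, j] - s[i] * s[j] / n
    cyi <- xy[i] - s[i] * sy / n
    cyj <- xy[j] - s[j] * sy / n
    det2 <- Cd[i] * Cd[j] - Cij^2
    ok <- det2 > 1e-8
    b1 <- (Cd[j] * cyi - Cij * cyj) / det2
    b2 <- (Cd[i] * cyj - Cij * cyi) / det2
    rss1 <- Syy - (b1 * cyi + b2 * cyj)
    # product term w = x_i * x_j, centred moments from the Gram pieces
    cww <- n - G[i, j]^2 / n
    cwi <- s[j] - G[i, j] * s[i] / n
    cwj <- s[i] - G[i, j] * s[j] / n
    cwy <- M[i, j] - G[i, j] * sy / n
    a1 <- (Cd[j] * cwi - Cij * cwj) / det2
    a2 <- (Cd[i] * cwj - Cij * cwi) / det2
    vw <- cww - (a1 * cwi + a2 * cwj)
    cv <- cwy - (a1 * cyi + a2 * cyj)
    rss2 <- rss1 - ifelse(vw > 1e-8, cv^2 / vw, 0)
    # guard catastrophic cancellation for near-perfect interactions
    rss2 <- pmax(rss2, rss1 * 1e-12)
    li <- ifelse(ok & rss1 > 1e-12, (n / 2) * log10(rss1 / rss2), 0)
    lod[i, j] <- pmax(li, 0)
  }
  lod
}

# greedy 2D peak extraction: take the global max above `floor`, mask +/-
# `radius` marker indices (same chromosome) around both coordinates, repeat.
extract_pair_peaks <- function(lod, chrom, floor, radius = 20) {
  peaks <- list()
  repeat {
    w <- which.max(lod)
    v <- lod[w]
    if (!length(v) || v <= floor) break
    p <- nrow(lod)
    i <- (w - 1) %% p + 1
    j <- (w - 1) %/% p + 1
    peaks[[length(peaks) + 1L]] <- c(i, j, v)
    mask_i <- which(chrom == chrom[i] & abs(seq_len(p) - i) <= radius)
    mask_j <- which(chrom == chrom[j] & abs(seq_len(p) - j) <= radius)
    lod[mask_i, ] <- 0; lod[, mask_i] <- 0
    lod[mask_j, ] <- 0; lod[, mask_j] <- 0
  }
  if (!length(peaks))
    return(data.table::data.table(i = integer(), j = integer(), lod = numeric()))
  m <- do.call(rbind, peaks)
  data.table::data.table(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                         lod = m[, 3])
}

#' Full two-locus interaction scan
#'
#' For each gene, every admissible marker pair (same-chromosome pairs
#' closer than \code{exclusion} marker indices are skipped) is tested with
#' the interaction LOD: (n/2) log10(RSS_marginal / RSS_full), the product
#' term over the model already containing both marginal effects.  Peaks
#' are extracted greedily above \code{floor}, masking \code{exclusion}
#' markers around both coordinates.
#'
#' @param residuals segregants x genes matrix from
#'   [interaction_residual()].
#' @param geno a \code{genotype_matrix} already restricted to the reduced
#'   marker set (see [reduce_markers()]).
#' @param exclusion same-chromosome index exclusion radius (default 20).
#' @param floor working LOD floor for peak extraction (default 2).
#' @return data.table: gene, i, j, marker1, marker2, lod (marker1 before
#'   marker2 in genome order).
#' @export
scan_pairs <- function(residuals, geno, exclusion = 20, floor = 2) {
  X <- geno$values
  chrom <- geno$map$chrom
  p <- ncol(X)
  same <- outer(chrom, chrom, "==") & abs(outer(seq_len(p), seq_len(p), "-")) <= exclusion
  out <- list()
  for (g in seq_len(ncol(residuals))) {
    lod <- pair_lod_matrix(residuals[, g], X)
    lod[same] <- 0
    pk <- extract_pair_peaks(lod, chrom, floor, exclusion)
    if (nrow(pk)) {
      pk$gene <- colnames(residuals)[g]
      out[[length(out) + 1L]] <- pk
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else
    data.table::data.table(i = integer(), j = integer(), lod = numeric(),
                           gene = character())
  if (nrow(res)) {
    res$marker1 <- geno$map$marker[res$i]
    res$marker2 <- geno$map$marker[res$j]
  } else { res$marker1 <- character(0); res$marker2 <- character(0) }
  data.table::setcolorder(res, c("gene", "i", "j", "marker1", "marker2", "lod"))
  res
}

#' Permutation FDR for interaction peaks
#'
#' FDR(T) = mean permuted peak count above T / observed count above T over
#' a LOD grid; returns the smallest grid value with FDR below alpha and
#' the significant records.  The marginal-scan variant restricts both
#' observed and permuted peaks to pairs where one member carries a
#' significant additive eQTL for the gene.
#'
#' @param observed peak table from [scan_pairs()].
#' @param permuted list of peak tables from permuted scans.
#' @param grid LOD grid (default seq(2, 12, 0.05)).
#' @param alpha target FDR (default 0.10).
#' @return list(threshold, significant, table).
#' @export
pair_fdr <- function(observed, permuted, grid = seq(2, 12, by = 0.05),
                     alpha = 0.10) {
  n_obs <- vapply(grid, function(T) sum(observed$lod > T), 0L)
  n_exp <- rowMeans(vapply(permuted, function(p)
    vapply(grid, function(T) sum(p$lod > T), 0L), integer(length(grid))))
  fdr <- ifelse(n_obs > 0, n_exp / n_obs, ifelse(n_exp == 0, 0, Inf))
  i <- which(fdr < alpha)
  thr <- if (length(i)) grid[i[1]] else NA_real_
  sig <- if (is.na(thr)) observed[0, ] else observed[observed$lod > thr, ]
  list(threshold = thr, significant = sig,
       table = data.table::data.table(grid = grid, observed = n_obs,
                                      expected = n_exp, fdr = fdr))
}

#' Interaction tests between significant additive eQTL peak markers
#'
#' For each gene with at least two additive eQTLs, the product term of
#' every peak-marker pair is F-tested over the model with both marginal
#' effects; significance is a permutation FDR on the F grid.
#'
#' @param residuals per-gene residuals (additive effects + polygenic
#'   removed), from [interaction_residual()].
#' @param eqtls additive eQTL records.
#' @param geno a \code{genotype_matrix}.
#' @param n_perm permutation runs (default 10).
#' @param alpha target FDR (default 0.10).
#' @param seed integer seed.
#' @return list(threshold, significant, all) of data.tables (gene,
#'   marker1, marker2, F, p).
#' @export
additive_pair_test <- function(residuals, eqtls, geno, n_perm = 10,
                               alpha = 0.10, seed = 1L) {
  tests <- function(R) {
    out <- list()
    for (g in colnames(R)) {
      mk <- unique(eqtls$peak_marker[eqtls$gene == g])
      if (length(mk) < 2) next
      y <- R[, g]
      for (a in seq_len(length(mk) - 1)) for (b in (a + 1):length(mk)) {
        x1 <- geno$values[, mk[a]]; x2 <- geno$values[, mk[b]]
        f0 <- stats::lm.fit(cbind(1, x1, x2), y)
        f1 <- stats::lm.fit(cbind(1, x1, x2, x1 * x2), y)
        rss0 <- sum(f0$residuals^2); rss1 <- sum(f1$residuals^2)
        df2 <- length(y) - 4
        Fv <- (rss0 - rss1) / (rss1 / df2)
        out[[length(out) + 1L]] <- data.table::data.table(
          gene = g, marker1 = mk[a], marker2 = mk[b], F = Fv,
          p = pf(Fv, 1, df2, lower.tail = FALSE))
      }
    }
    if (length(out)) data.table::rbindlist(out) else
      data.table::data.table(gene = character(), marker1 = character(),
                             marker2 = character(), F = numeric(), p = numeric())
  }
  obs <- tests(residuals)
  if (!nrow(obs))
    return(list(threshold = NA_real_, significant = obs, all = obs))
  set.seed(seed)
  n <- nrow(residuals)
  perm_F <- lapply(seq_len(n_perm), function(k)
    tests(residuals[sample.int(n), , drop = FALSE])$F)
  grid <- seq(1, max(obs$F) + 1, length.out = 200)
  n_obs <- vapply(grid, function(T) sum(obs$F > T), 0L)
  n_exp <- rowMeans(vapply(perm_F, function(f)
    vapply(grid, function(T) sum(f > T), 0L), integer(length(grid))))
  fdr <- ifelse(n_obs > 0, n_exp / n_obs, ifelse(n_exp == 0, 0, Inf))
  i <- which(fdr < alpha)
  thr <- if (length(i)) grid[i[1]] else NA_real_
  sig <- if (is.na(thr)) obs[0, ] else obs[obs$F > thr, ]
  list(threshold = thr, significant = sig, all = obs)
}

#' Variance explained by a marker-pair interaction
#'
#' Squared correlation between the phenotype and the centred product
#' x1 * x2 after both marginal effects are removed.
#'
#' @param y phenotype vector.
#' @param x1,x2 marker genotype vectors.
#' @return fraction of variance from the product term.
#' @export
interaction_variance <- function(y, x1, x2) {
  q0 <- qr(cbind(1, x1, x2))
  ry <- qr.resid(q0, y)
  rw <- qr.resid(q0, x1 * x2)
  if (sd(rw) < 1e-12) return(0)
  rss1 <- sum(ry^2)
  rss2 <- sum(qr.resid(qr(cbind(1, x1, x2, x1 * x2)), y)^2)
  (rss1 - rss2) / sum((y - mean(y))^2)
}
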