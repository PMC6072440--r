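#' Screen for large background genetic effects
#'
#' Three rounds of a coarse genome scan on covariate-corrected expression:
#' in each round, the per-chromosome max-LOD marker is appended to a
#' per-gene background set Z when its LOD exceeds \code{cfg$bg_lod} (3.5),
#' and the expression is re-residualized on the accumulated set before the
#' next round.  Z later serves as fixed covariates when mapping on other
#' chromosomes; the loci themselves are detected formally by the forward
#' scan.
#'
#' @param P segregants x genes expression matrix (or expression_matrix).
#' @param covariates covariate table.
#' @param geno a \code{genotype_matrix}.
#' @param cfg a [scan_config()].
#' @return named list per gene of marker column indices (possibly empty),
#'   up to \code{bg_rounds} per chromosome.
#' @export
detect_background_effects <- function(P, covariates, geno,
                                      cfg = scan_config()) {
  if (inherits(P, "expression_matrix")) P <- P$values
  X <- geno$values
  n <- nrow(P)
  W <- design_matrix(covariates, n)
  R <- qr.resid(qr(W), P)
  chroms <- unique(geno$map$chrom)
  idx_by_chrom <- lapply(chroms, function(cn) marker_index(geno, cn))
  Z <- setNames(vector("list", ncol(P)), colnames(P))
  for (g in seq_along(Z)) Z[[g]] <- integer(0)
  Xs <- scale(X)
  for (round in seq_len(cfg$bg_rounds)) {
    r <- crossprod(scale(R), Xs) / (n - 1)
    r[!is.finite(r)] <- 0
    lod <- lod_from_r2(r^2, n)
    changed <- FALSE
    for (ci in seq_along(chroms)) {
      mi <- idx_by_chrom[[ci]]
      mx <- row_max(lod[, mi, drop = FALSE])
      hit <- which(mx$value > cfg$bg_lod)
      for (g in hit) {
        mk <- mi[mx$index[g]]
        if (!(mk %in% Z[[g]])) { Z[[g]] <- c(Z[[g]], mk); changed <- TRUE }
      }
    }
    if (!changed) break
    if (round < cfg$bg_rounds) {
      for (g in which(lengths(Z) > 0)) {
        R[, g] <- qr.resid(qr(cbind(W, X[, Z[[g]], drop = FALSE])), P[, g])
      }
    }
  }
  Z
}

# Residualize every gene for mapping on one chromosome: covariates +
# off-chromosome background markers (+ LOCO polygenic BLUP).
loco_residual_matrix <- function(P, covariates, geno, Z, chromosome,
                                 polygenic = TRUE) {
  n <- nrow(P)
  on_c <- marker_index(geno, chromosome)
  X <- geno$values
  R <- matrix(0, n, ncol(P), dimnames = dimnames(P))
  if (ncol(X) - length(on_c) < 2) polygenic <- FALSE  # nothing to fit LOCO on
  if (polygenic) {
    setup <- loco_setup(geno, chromosome, covariates)
    for (g in seq_len(ncol(P))) {
      zg <- setdiff(Z[[g]], on_c)
      fm <- if (length(zg)) X[, zg, drop = FALSE] else NULL
      R[, g] <- loco_residual(P[, g], setup, fm)
    }
  } else {
    W <- design_matrix(covariates, n)
    for (g in seq_len(ncol(P))) {
      zg <- setdiff(Z[[g]], on_c)
      R[, g] <- qr.resid(qr(cbind(W, X[, zg, drop = FALSE])), P[, g])
    }
  }
  R
}

# One FDR-controlled detection round on one chromosome: returns the
# threshold, per-gene max LOD/marker, and the permutation count table.
scan_round <- function(Rc, Xc, cfg, seed) {
  n <- nrow(Rc)
  Rs <- scale(Rc); Rs[!is.finite(Rs)] <- 0
  Xs <- scale(Xc); Xs[!is.finite(Xs)] <- 0
  r <- crossprod(Rs, Xs) / (n - 1)
  lod <- lod_from_r2(r^2, n)
  mx <- row_max(lod)
  set.seed(seed)
  n_exp <- numeric(length(cfg$grid))
  for (k in seq_len(cfg$n_perm)) {
    pidx <- sample.int(n)  # one ordering shared across all genes
    rp <- crossprod(Rs[pidx, , drop = FALSE], Xs) / (n - 1)
    pm <- row_max(lod_from_r2(rp^2, n))$value
    ps <- sort(pm)
    n_exp <- n_exp + (length(ps) - findInterval(cfg$grid, ps))
  }
  n_exp <- n_exp / cfg$n_perm
  thr <- fdr_threshold(mx$value, n_exp, cfg)
  list(threshold = thr$threshold, fdr_table = thr$table,
       max_lod = mx$value, max_idx = mx$index, lod = lod, r = r)
}

#' Forward-stepwise additive eQTL mapping with permutation FDR
#'
#' For each chromosome, every gene is residualized against covariates,
#' off-chromosome background markers and (optionally) the LOCO polygenic
#' BLUP; then a forward procedure repeats \{scan all active genes, take the
#' per-gene max-LOD marker, derive the permutation-grid FDR threshold,
#' accept peaks above it, residualize accepted genes on their peak\} until
#' no gene has an additional significant linkage.  Permutations use one
#' segregant ordering shared across genes per run, preserving inter-gene
#' correlation.  Ties at the max LOD go to the leftmost marker.
#'
#' @param expr an \code{expression_matrix} (or plain matrix).
#' @param covariates covariate table.
#' @param geno a \code{genotype_matrix}.
#' @param cfg a [scan_config()].
#' @param Z optional precomputed [detect_background_effects()] result.
#' @return data.table of eQTL records: gene, chrom, peak_marker, peak_pos,
#'   lod, ci_left_pos, ci_right_pos, r (signed, RM-positive), var_expl,
#'   step, threshold; plus attribute \code{thresholds} (first-round
#'   threshold per chromosome).
#' @export
forward_scan <- function(expr, covariates, geno, cfg = scan_config(),
                         Z = NULL) {
  ann <- NULL
  if (inherits(expr, "expression_matrix")) { ann <- expr$annotation; expr <- expr$values }
  P <- expr
  n <- nrow(P)
  genes <- colnames(P)
  if (is.null(Z)) Z <- detect_background_effects(P, covariates, geno, cfg)
  chroms <- sort(unique(geno$map$chrom))
  records <- list()
  thresholds <- setNames(rep(NA_real_, length(chroms)), chroms)
  for (cn in chroms) {
    on_c <- marker_index(geno, cn)
    Xc <- geno$values[, on_c, drop = FALSE]
    map_c <- geno$map[on_c, ]
    Rc <- loco_residual_matrix(P, covariates, geno, Z, cn, cfg$polygenic)
    active <- seq_along(genes)
    for (step in seq_len(cfg$max_iter)) {
      sr <- scan_round(Rc[, active, drop = FALSE], Xc, cfg,
                       seed = cfg$seed + step)
      if (step == 1) thresholds[cn] <- sr$threshold
      if (is.na(sr$threshold)) break
      sig <- which(sr$max_lod > sr$threshold)
      if (!length(sig)) break
      for (si in sig) {
        g <- active[si]
        pk <- sr$max_idx[si]
        ci <- lod_drop_interval(sr$lod[si, ], pk, cfg$ci_drop, geno, cn)
        records[[length(records) + 1L]] <- data.table::data.table(
          gene = genes[g], chrom = cn,
          peak_marker = map_c$marker[pk], peak_pos = map_c$pos[pk],
          lod = sr$max_lod[si],
          ci_left_pos = ci$bp_lo, ci_right_pos = ci$bp_hi,
          r = sr$r[si, pk], var_expl = sr$r[si, pk]^2,
          step = step, threshold = sr$threshold)
        Rc[, g] <- qr.resid(qr(cbind(1, Xc[, pk])), Rc[, g])
      }
      active <- active[sig]
    }
  }
  out <- if (length(records)) data.table::rbindlist(records) else
    data.table::data.table(gene = character(), chrom = character(),
                           peak_marker = character(), peak_pos = integer(),
                           lod = numeric(), ci_left_pos = integer(),
                           ci_right_pos = integer(), r = numeric(),
                           var_expl = numeric(), step = integer(),
                           threshold = numeric())
  if (!is.null(ann)) out <- classify_local(out, ann)
  data.table::setattr(out, "thresholds", thresholds)
  out
}

#' Classify eQTLs as local or distant
#'
#' An eQTL is local when its confidence interval overlaps the gene window
#' expanded by 1000 bp upstream and 200 bp downstream (strand-aware,
#' closed intervals).  Among multiple local eQTLs of one gene, the one
#' whose peak is closest to the gene is flagged \code{primary_local}.
#'
#' @param records eQTL data.table from [forward_scan()].
#' @param annotation data.table(gene, chrom, start, end, strand).
#' @return records with added logical columns \code{local} and
#'   \code{primary_local}.
#' @export
classify_local <- function(records, annotation) {
  if (!nrow(records)) {
    records$local <- logical(0); records$primary_local <- logical(0)
    return(records)
  }
  i <- match(records$gene, annotation$gene)
  if (anyNA(i)) warning("unannotated gene(s) classified as distant")
  strand <- annotation$strand[i]
  win_lo <- ifelse(strand == "+", annotation$start[i] - 1000L,
                   annotation$start[i] - 200L)
  win_hi <- ifelse(strand == "+", annotation$end[i] + 200L,
                   annotation$end[i] + 1000L)
  records$local <- !is.na(i) & records$chrom == annotation$chrom[i] &
    records$ci_right_pos >= win_lo & records$ci_left_pos <= win_hi
  dist <- pmax(win_lo - records$peak_pos, records$peak_pos - win_hi, 0)
  records$primary_local <- FALSE
  for (g in unique(records$gene[records$local])) {
    j <- which(records$gene == g & records$local)
    records$primary_local[j[which.min(dist[j])]] <- TRUE
  }
  records
}

# row subset helpers for cross-validation
subset_geno <- function(geno, idx) {
  structure(list(values = geno$values[idx, , drop = FALSE], map = geno$map,
                 ld_groups = geno$ld_groups), class = "genotype_matrix")
}

#' Local-only eQTL scan at reduced multiple-testing burden
#'
#' Tests exactly one marker per gene -- the marker closest to the gene
#' start -- on covariate-corrected expression, with the permutation-grid
#' FDR applied across genes.  Because only one test is made per gene, the
#' threshold is far lower than in the genome-wide scan, rescuing weak
#' local eQTLs.
#'
#' @param expr an \code{expression_matrix} (annotation required).
#' @param covariates covariate table.
#' @param geno a \code{genotype_matrix}.
#' @param cfg a [scan_config()].
#' @return data.table: gene, marker, pos, lod, r, significant, threshold.
#' @export
local_scan <- function(expr, covariates, geno, cfg = scan_config()) {
  ann <- expr$annotation
  P <- expr$values
  n <- nrow(P)
  genes <- colnames(P)
  i <- match(genes, ann$gene)
  mk <- vapply(seq_along(genes), function(g) {
    idx <- which(geno$map$chrom == ann$chrom[i[g]])
    idx[which.min(abs(geno$map$pos[idx] - ann$start[i[g]]))]
  }, 0L)
  R <- residualize(P, covariates)
  Rs <- scale(R); Rs[!is.finite(Rs)] <- 0
  Xs <- scale(geno$values[, mk, drop = FALSE])
  r <- colSums(Rs * Xs) / (n - 1)
  lod <- lod_from_r2(r^2, n)
  set.seed(cfg$seed)
  n_exp <- numeric(length(cfg$grid))
  for (k in seq_len(cfg$n_perm)) {
    pidx <- sample.int(n)
    lp <- sort(lod_from_r2((colSums(Rs[pidx, , drop = FALSE] * Xs) / (n - 1))^2, n))
    n_exp <- n_exp + (length(lp) - findInterval(cfg$grid, lp))
  }
  thr <- fdr_threshold(lod, n_exp / cfg$n_perm, cfg)
  data.table::data.table(gene = genes, marker = geno$map$marker[mk],
                         pos = geno$map$pos[mk], lod = lod, r = r,
                         significant = !is.na(thr$threshold) & lod > thr$threshold,
                         threshold = thr$threshold)
}

#' Cross-validated variance explained by detected eQTLs
#'
#' Leave-one-batch-out: eQTLs are re-detected and their joint effects fit
#' on the training batches; the variance explained in the held-out batch
#' is the squared correlation between predicted and observed
#' (covariate-corrected) expression, averaged over folds per gene.
#'
#' @param expr an \code{expression_matrix} or matrix.
#' @param covariates covariate table with a \code{batch} column.
#' @param geno a \code{genotype_matrix}.
#' @param cfg a [scan_config()] (use a reduced \code{n_perm} for speed).
#' @return named per-gene vector of cross-validated variance explained.
#' @export
cross_validated_variance <- function(expr, covariates, geno,
                                     cfg = scan_config()) {
  P <- if (inherits(expr, "expression_matrix")) expr$values else expr
  batch <- covariates$batch
  if (length(unique(batch)) < 2) stop("need >= 2 batches")
  # two-stage: covariate correction first, markers cross-validated
  Pr <- residualize(P, covariates)
  genes <- colnames(P)
  ve <- matrix(NA_real_, length(unique(batch)), length(genes))
  X <- geno$values
  for (bi in seq_along(unique(batch))) {
    b <- unique(batch)[bi]
    test <- which(batch == b)
    train <- which(batch != b)
    eq <- forward_scan(Pr[train, , drop = FALSE], NULL,
                       subset_geno(geno, train), cfg)
    for (gi in seq_along(genes)) {
      mk <- eq$peak_marker[eq$gene == genes[gi]]
      if (!length(mk)) { ve[bi, gi] <- 0; next }
      Xtr <- X[train, mk, drop = FALSE]
      fit <- stats::lm.fit(cbind(1, Xtr), Pr[train, gi])
      pred <- cbind(1, X[test, mk, drop = FALSE]) %*% fit$coefficients
      ve[bi, gi] <- if (sd(pred) > 0) cor(pred, Pr[test, gi])^2 else 0
    }
  }
  setNames(colMeans(ve, na.rm = TRUE), genes)
}
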