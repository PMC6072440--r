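#' Residual-factor covariates for hotspot mapping
#'
#' For every gene with at least one detected eQTL, removes covariates, its
#' significant eQTL fixed effects and the whole-genome polygenic BLUP;
#' scales the residuals; and extracts left-singular vectors across genes.
#' Retained are the top min(k_max, k*) components, where k* is the number
#' of singular values exceeding the maximum singular value of a
#' column-permuted copy.  These factors capture systematic expression
#' variation not attributable to known covariates or mapped genetics and
#' are appended to the covariate design when mapping hotspots.
#'
#' @param expr an \code{expression_matrix} or matrix.
#' @param covariates covariate table.
#' @param eqtls eQTL records from [forward_scan()].
#' @param geno a \code{genotype_matrix}.
#' @param k_max cap on retained factors (default 20).
#' @param n_perm column-permuted copies for the retention null; the max
#'   singular value across all copies is the cutoff, so under the null a
#'   spurious factor is kept with probability ~1/(n_perm+1).
#' @param seed seed for the permutation null.
#' @return segregants x k matrix of factor covariates (k may be 0).
#' @export
residual_factor_covariates <- function(expr, covariates, eqtls, geno,
                                       k_max = 20, n_perm = 19, seed = 1L) {
  P <- if (inherits(expr, "expression_matrix")) expr$values else expr
  genes <- intersect(colnames(P), unique(eqtls$gene))
  if (!length(genes)) stop("no genes with detected eQTLs")
  eig <- kinship_eigen(additive_kinship(geno))
  R <- matrix(0, nrow(P), length(genes))
  for (i in seq_along(genes)) {
    mk <- eqtls$peak_marker[eqtls$gene == genes[i]]
    R[, i] <- polygenic_residual(P[, genes[i]], eig, covariates,
                                 geno$values[, mk, drop = FALSE])
  }
  R <- scale(R)
  sv <- svd(R, nu = min(k_max, ncol(R)), nv = 0)
  set.seed(seed)
  d_perm_max <- max(vapply(seq_len(n_perm), function(k)
    svd(apply(R, 2, sample), nu = 0, nv = 0)$d[1], 0))
  k <- min(k_max, sum(sv$d > d_perm_max))
  if (k == 0) return(matrix(0, nrow(P), 0))
  sv$u[, seq_len(k), drop = FALSE]
}

#' Build the trans score matrix L for one chromosome
#'
#' Genes with a significant eQTL on the chromosome that do not physically
#' reside on it are residualized (OLS) against covariates, residual-factor
#' eigenvector covariates, and their significant eQTL peaks on other
#' chromosomes; the scaled residuals are decomposed by SVD and components
#' whose singular values beat a column-permutation null are retained.
#' Columns of L are principal-component scores (left-singular vectors
#' scaled by singular values; set \code{scores = FALSE} for unscaled
#' eigenvectors).
#'
#' @param chromosome target chromosome.
#' @param expr an \code{expression_matrix} (needs annotation) or matrix
#'   plus explicit \code{annotation}.
#' @param covariates covariate table or design matrix (should already
#'   include the residual-factor columns).
#' @param eqtls eQTL records.
#' @param geno a \code{genotype_matrix}.
#' @param annotation gene annotation (defaults to the one in \code{expr}).
#' @param scores scale left-singular vectors by singular values?
#' @param n_perm column-permuted copies for the retention null (max rule,
#'   as in [residual_factor_covariates()]).
#' @param seed seed for the permutation null.
#' @return list of class \code{trans_matrix}: L (n x m), genes, loadings,
#'   chromosome, m.  m = 0 when no gene qualifies or no component beats
#'   the null.
#' @export
build_trans_matrix <- function(chromosome, expr, covariates, eqtls, geno,
                               annotation = NULL, scores = TRUE,
                               n_perm = 19, seed = 1L) {
  if (inherits(expr, "expression_matrix")) {
    if (is.null(annotation)) annotation <- expr$annotation
    expr <- expr$values
  }
  on_c <- eqtls$gene[eqtls$chrom == chromosome]
  resides <- annotation$gene[annotation$chrom == chromosome]
  genes <- setdiff(intersect(on_c, colnames(expr)), resides)
  if (!length(genes))
    return(structure(list(L = matrix(0, nrow(expr), 0), genes = character(),
                          loadings = NULL, chromosome = chromosome, m = 0L),
                     class = "trans_matrix"))
  W <- design_matrix(covariates, nrow(expr))
  R <- matrix(0, nrow(expr), length(genes))
  for (i in seq_along(genes)) {
    mk <- eqtls$peak_marker[eqtls$gene == genes[i] & eqtls$chrom != chromosome]
    X <- cbind(W, geno$values[, mk, drop = FALSE])
    R[, i] <- qr.resid(qr(X), expr[, genes[i]])
  }
  R <- scale(R)
  sv <- svd(R)
  set.seed(seed)
  d_perm_max <- max(vapply(seq_len(n_perm), function(k)
    svd(apply(R, 2, sample), nu = 0, nv = 0)$d[1], 0))
  m <- sum(sv$d > d_perm_max)
  m <- min(m, nrow(R) - 3L, length(genes))
  if (m <= 0)
    return(structure(list(L = matrix(0, nrow(expr), 0), genes = genes,
                          loadings = NULL, chromosome = chromosome, m = 0L),
                     class = "trans_matrix"))
  L <- sv$u[, seq_len(m), drop = FALSE]
  if (scores) L <- sweep(L, 2, sv$d[seq_len(m)], `*`)
  structure(list(L = L, genes = genes,
                 loadings = sv$v[, seq_len(m), drop = FALSE],
                 chromosome = chromosome, m = as.integer(m)),
            class = "trans_matrix")
}

#' Multivariate (joint) LOD for one marker
#'
#' LOD = (n/2) log10(|RSS0| / |RSS|), where RSS and RSS0 are the residual
#' cross-product matrices of the columns of L regressed on the marker
#' (plus intercept and optional covariates) and on the reduced model.
#' With m = 1 this reduces exactly to the univariate formula.
#'
#' @param L n x m score matrix (m >= 1).
#' @param x marker genotype vector.
#' @param covariates optional numeric matrix of additional fixed effects
#'   present in both models.
#' @return the LOD score (>= 0).
#' @export
mv_lod <- function(L, x, covariates = NULL) {
  L <- as.matrix(L)
  n <- nrow(L); m <- ncol(L)
  stopifnot(m >= 1, n > m + 2)
  X0 <- cbind(rep(1, n), covariates)
  X1 <- cbind(X0, x)
  E0 <- qr.resid(qr(X0), L)
  E1 <- qr.resid(qr(X1), L)
  RSS0 <- crossprod(E0)
  RSS1 <- crossprod(E1)
  ld0 <- determinant(RSS0, logarithm = TRUE)$modulus[1]
  ld1 <- determinant(RSS1, logarithm = TRUE)$modulus[1]
  if (!is.finite(ld1)) stop("singular RSS matrix; collinear L columns upstream")
  (n / 2) * (ld0 - ld1) / log(10)
}

# Vectorized multivariate LOD over all markers via the rank-one identity
#   det(RSS0 - u u') = det(RSS0) (1 - u' RSS0^-1 u),  u = Lc' xc / ||xc||.
# L and X are residualized on (intercept + covariates) first.
mv_scan <- function(L, X, covariates = NULL) {
  n <- nrow(L)
  X0 <- cbind(rep(1, n), covariates)
  qr0 <- qr(X0)
  Lc <- qr.resid(qr0, as.matrix(L))
  Xc <- qr.resid(qr0, as.matrix(X))
  RSS0 <- crossprod(Lc)
  xn <- colSums(Xc^2)
  K <- crossprod(Lc, Xc)
  U <- sweep(K, 2, sqrt(pmax(xn, 1e-300)), `/`)
  q <- colSums(U * solve(RSS0, U))
  q[xn < 1e-10] <- 0
  q <- pmin(q, 1 - 1e-15)
  -(n / 2) * log10(1 - q)
}

#' Iterative multivariate hotspot (jQTL) scan on one chromosome
#'
#' Repeats \{scan all markers with the multivariate LOD; compare the max
#' to the 99% quantile of per-permutation max LODs (rows of L permuted
#' jointly); if significant, record the peak, subtract its fitted effect
#' from every column of L, rescan\} until no significant peak remains.
#'
#' @param trans a \code{trans_matrix} (or plain n x m matrix L).
#' @param Xc marker genotypes of the chromosome (n x p).
#' @param map_c marker map rows for the chromosome.
#' @param n_perm permutations per round (default 100).
#' @param q quantile of permutation maxima (default 0.99).
#' @param seed integer seed.
#' @param max_peaks safety cap.
#' @return data.table: peak_idx, marker, pos, lod, threshold (ordered by
#'   detection).
#' @export
jqtl_scan <- function(trans, Xc, map_c, n_perm = 100, q = 0.99, seed = 1L,
                      max_peaks = 20) {
  L <- if (inherits(trans, "trans_matrix")) trans$L else as.matrix(trans)
  if (ncol(L) == 0) return(empty_peaks())
  set.seed(seed)
  out <- list()
  Lcur <- L
  for (it in seq_len(max_peaks)) {
    lods <- mv_scan(Lcur, Xc)
    pm <- vapply(seq_len(n_perm), function(k)
      max(mv_scan(Lcur[sample.int(nrow(Lcur)), , drop = FALSE], Xc)), 0)
    thr <- quantile(pm, q, names = FALSE)
    pk <- which.max(lods)
    if (lods[pk] <= thr) break
    out[[it]] <- data.table::data.table(
      peak_idx = pk, marker = map_c$marker[pk], pos = map_c$pos[pk],
      lod = lods[pk], threshold = thr)
    Lcur <- qr.resid(qr(cbind(1, Xc[, pk])), Lcur)
  }
  if (length(out)) data.table::rbindlist(out) else empty_peaks()
}

empty_peaks <- function() {
  data.table::data.table(peak_idx = integer(), marker = character(),
                         pos = integer(), lod = numeric(),
                         threshold = numeric())
}

#' Refine jQTL peak positions by drop-one rescans
#'
#' Each peak is dropped from the joint model one at a time, the chromosome
#' is rescanned with the remaining peaks as covariates, and the peak
#' position recomputed.  Peaks that move by more than \code{move_bp} are
#' removed; others are updated to the refit position.
#'
#' @param trans a \code{trans_matrix} or L matrix.
#' @param Xc chromosome marker genotypes.
#' @param map_c chromosome marker map.
#' @param peaks data.table from [jqtl_scan()].
#' @param move_bp removal rule for moved peaks (default 75 kb).
#' @return refined peaks data.table (column \code{moved_bp} added).
#' @export
refine_peaks <- function(trans, Xc, map_c, peaks, move_bp = 75000) {
  L <- if (inherits(trans, "trans_matrix")) trans$L else as.matrix(trans)
  if (!nrow(peaks)) return(peaks)
  keep <- logical(nrow(peaks))
  new_idx <- peaks$peak_idx
  for (i in seq_len(nrow(peaks))) {
    others <- new_idx[-i]
    covs <- if (length(others)) Xc[, others, drop = FALSE] else NULL
    lods <- mv_scan(L, Xc, covariates = covs)
    pk <- which.max(lods)
    moved <- abs(map_c$pos[pk] - peaks$pos[i])
    keep[i] <- moved <= move_bp
    if (keep[i]) {
      new_idx[i] <- pk
      peaks$peak_idx[i] <- pk
      peaks$marker[i] <- map_c$marker[pk]
      peaks$pos[i] <- map_c$pos[pk]
      peaks$lod[i] <- lods[pk]
    }
    peaks$moved_bp <- if (i == 1 && is.null(peaks$moved_bp)) NA_real_ else peaks$moved_bp
    peaks$moved_bp[i] <- moved
  }
  peaks[keep, ]
}

# two-locus joint LOD for all admissible pairs via a rank-two identity;
# returns the best pair and its LOD.  cand = candidate marker indices.
best_two_locus <- function(Lc, Xc, cand) {
  RSS0 <- crossprod(Lc)
  K <- crossprod(Lc, Xc[, cand, drop = FALSE])
  G <- crossprod(K, solve(RSS0, K))      # B' RSS0^-1 B, all candidates
  C <- crossprod(Xc[, cand, drop = FALSE])
  n <- nrow(Lc)
  p <- length(cand)
  best <- c(-Inf, NA, NA)
  for (a in seq_len(p - 1)) {
    b <- (a + 1):p
    caa <- C[a, a]; cbb <- diag(C)[b]; cab <- C[a, b]
    gaa <- G[a, a]; gbb <- diag(G)[b]; gab <- G[a, b]
    detC <- caa * cbb - cab^2
    ok <- detC > 1e-8
    a11 <- (cbb * gaa - cab * gab) / detC
    a12 <- (cbb * gab - cab * gbb) / detC
    a21 <- (-cab * gaa + caa * gab) / detC
    a22 <- (-cab * gab + caa * gbb) / detC
    ratio <- (1 - a11) * (1 - a22) - a12 * a21
    ratio[!ok] <- 1
    ratio <- pmax(ratio, 1e-300)
    lod2 <- -(n / 2) * log10(ratio)
    j <- which.max(lod2)
    if (lod2[j] > best[1]) best <- c(lod2[j], cand[a], cand[b[j]])
  }
  list(lod = best[1], pair = as.integer(best[2:3]))
}

#' Ghost-jQTL test: one locus or two neighbouring loci?
#'
#' For a peak with LOD above \code{lod_gate} (200), compares the best
#' two-locus model -- both loci required to lie outside a +/- 10-marker
#' window around the peak -- with the best one-locus model.  The peak is
#' replaced by the two-locus model when the observed LOD difference
#' exceeds the 99% permutation quantile of the difference by more than
#' \code{margin} (10).
#'
#' @param trans a \code{trans_matrix} or L matrix.
#' @param Xc chromosome marker genotypes.
#' @param map_c chromosome marker map.
#' @param peak_idx marker index of the interrogated peak.
#' @param other_idx marker indices of other jQTL peaks (covariates).
#' @param n_perm permutations (default 100).
#' @param lod_gate only peaks above this LOD are tested (default 200).
#' @param margin required excess over the permutation quantile (default 10).
#' @param exclude half-width of the exclusion window in markers (default 10).
#' @param q permutation quantile (default 0.99).
#' @param seed integer seed.
#' @return list(tested, two_locus, pair, delta_obs, delta_crit).
#' @export
ghost_test <- function(trans, Xc, map_c, peak_idx, other_idx = integer(0),
                       n_perm = 100, lod_gate = 200, margin = 10,
                       exclude = 10, q = 0.99, seed = 1L) {
  L <- if (inherits(trans, "trans_matrix")) trans$L else as.matrix(trans)
  n <- nrow(L)
  covs <- if (length(other_idx)) Xc[, other_idx, drop = FALSE] else NULL
  qr0 <- qr(cbind(rep(1, n), covs))
  Lc <- qr.resid(qr0, L)
  Xcc <- qr.resid(qr0, Xc)
  lods <- mv_scan_resid(Lc, Xcc)
  if (lods[peak_idx] <= lod_gate)
    return(list(tested = FALSE, two_locus = FALSE, pair = NULL,
                delta_obs = NA_real_, delta_crit = NA_real_))
  cand <- setdiff(seq_len(ncol(Xc)),
                  seq(max(1, peak_idx - exclude), min(ncol(Xc), peak_idx + exclude)))
  if (length(cand) < 2) {
    warning("chromosome too short for the ghost-test exclusion window")
    return(list(tested = FALSE, two_locus = FALSE, pair = NULL,
                delta_obs = NA_real_, delta_crit = NA_real_))
  }
  delta <- function(Lc_) {
    b1 <- max(mv_scan_resid(Lc_, Xcc))
    b2 <- best_two_locus(Lc_, Xcc, cand)
    list(delta = b2$lod - b1, pair = b2$pair)
  }
  obs <- delta(Lc)
  set.seed(seed)
  dp <- vapply(seq_len(n_perm), function(k)
    delta(Lc[sample.int(n), , drop = FALSE])$delta, 0)
  crit <- quantile(dp, q, names = FALSE)
  list(tested = TRUE, two_locus = obs$delta > crit + margin,
       pair = obs$pair, delta_obs = obs$delta, delta_crit = crit)
}

# mv_scan on pre-residualized inputs
mv_scan_resid <- function(Lc, Xc) {
  n <- nrow(Lc)
  RSS0 <- crossprod(Lc)
  xn <- colSums(Xc^2)
  U <- sweep(crossprod(Lc, Xc), 2, sqrt(pmax(xn, 1e-300)), `/`)
  qv <- colSums(U * solve(RSS0, U))
  qv[xn < 1e-10] <- 0
  -(n / 2) * log10(1 - pmin(qv, 1 - 1e-15))
}

#' Bootstrap confidence interval for a jQTL location
#'
#' Segregants are resampled with replacement B times; each resample is
#' refit with the other peaks as covariates and the multivariate-LOD
#' argmax within a window of \code{window} markers centred on the peak is
#' recorded.  The CI is the central 95% of bootstrap peak positions,
#' extended over the perfect-LD groups of the boundary markers.
#'
#' @param trans a \code{trans_matrix} or L matrix.
#' @param Xc chromosome marker genotypes.
#' @param map_c chromosome marker map.
#' @param peak_idx marker index of the peak.
#' @param other_idx other jQTL peak indices (covariates).
#' @param B bootstrap resamples (default 1000; must be >= 1).
#' @param window window size in markers (default 80), truncated at ends.
#' @param level central coverage (default 0.95).
#' @param geno optional \code{genotype_matrix} for LD extension.
#' @param seed integer seed.
#' @return list(ci_lo, ci_hi, peaks_bp, histogram).
#' @export
bootstrap_ci <- function(trans, Xc, map_c, peak_idx, other_idx = integer(0),
                         B = 1000, window = 80, level = 0.95, geno = NULL,
                         seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  L <- if (inherits(trans, "trans_matrix")) trans$L else as.matrix(trans)
  n <- nrow(L)
  half <- window %/% 2
  win <- seq(max(1, peak_idx - half), min(ncol(Xc), peak_idx + half - 1))
  set.seed(seed)
  peaks_bp <- integer(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, replace = TRUE)
    covs <- if (length(other_idx)) Xc[idx, other_idx, drop = FALSE] else NULL
    qr0 <- qr(cbind(rep(1, n), covs))
    Lc <- qr.resid(qr0, L[idx, , drop = FALSE])
    Xw <- qr.resid(qr0, Xc[idx, win, drop = FALSE])
    peaks_bp[b] <- map_c$pos[win[which.max(mv_scan_resid(Lc, Xw))]]
  }
  alpha <- (1 - level) / 2
  ci <- quantile(peaks_bp, c(alpha, 1 - alpha), names = FALSE, type = 1)
  ci_lo <- ci[1]; ci_hi <- ci[2]
  if (!is.null(geno) && !is.null(geno$ld_groups)) {
    cn <- map_c$chrom[1]
    for (bp in ci) {
      mk <- map_c$marker[map_c$pos == bp][1]
      mem <- geno$ld_groups[[mk]]
      if (!is.null(mem)) {
        mpos <- as.integer(sub(".*_", "", mem[startsWith(mem, paste0(cn, "_"))]))
        if (length(mpos)) {
          ci_lo <- min(ci_lo, mpos); ci_hi <- max(ci_hi, mpos)
        }
      }
    }
  }
  hist_tab <- data.table::as.data.table(table(pos = peaks_bp))
  list(ci_lo = ci_lo, ci_hi = ci_hi, peaks_bp = peaks_bp,
       histogram = hist_tab)
}

#' Genes affected by hotspots: targeted forward scan
#'
#' For each chromosome with hotspots, each gene is residualized on
#' covariates and its significant eQTLs on other chromosomes; a forward
#' selection restricted to the candidate set -- the hotspot markers plus
#' the gene's local eQTL peak (or its closest marker when the gene resides
#' on the chromosome) -- is run under the 5%-FDR permutation criterion,
#' and signed coefficients come from a final joint multiple regression.
#'
#' @param expr an \code{expression_matrix} (annotation required) or matrix.
#' @param covariates covariate table or design (typically including the
#'   residual-factor columns).
#' @param geno a \code{genotype_matrix}.
#' @param hotspot_markers character vector of hotspot peak marker ids.
#' @param eqtls eQTL records from [forward_scan()] (with \code{local}).
#' @param annotation gene annotation (defaults to the one in \code{expr}).
#' @param cfg a [scan_config()].
#' @return list: \code{coefficients} (data.table gene, marker, coef) and
#'   \code{counts} (data.table marker, n_targets).
#' @export
hotspot_targets <- function(expr, covariates, geno, hotspot_markers, eqtls,
                            annotation = NULL, cfg = scan_config()) {
  if (inherits(expr, "expression_matrix")) {
    if (is.null(annotation)) annotation <- expr$annotation
    expr <- expr$values
  }
  n <- nrow(expr)
  genes <- colnames(expr)
  W <- design_matrix(covariates, n)
  hs_chrom <- geno$map$chrom[match(hotspot_markers, geno$map$marker)]
  coefs <- list()
  for (cn in unique(hs_chrom)) {
    hs_c <- hotspot_markers[hs_chrom == cn]
    on_c <- marker_index(geno, cn)
    map_c <- geno$map[on_c, ]
    # per-gene extra candidate: local eQTL peak, else closest marker (genes on cn)
    extra <- setNames(rep(NA_character_, length(genes)), genes)
    loc <- eqtls[eqtls$chrom == cn & isTRUE_vec(eqtls$local) &
                   isTRUE_vec(eqtls$primary_local), ]
    extra[loc$gene] <- loc$peak_marker
    resident <- annotation$gene[annotation$chrom == cn]
    for (g in intersect(resident, genes)) {
      if (is.na(extra[g])) {
        gs <- annotation$start[annotation$gene == g][1]
        extra[g] <- map_c$marker[which.min(abs(map_c$pos - gs))]
      }
    }
    cand_union <- union(hs_c, stats::na.omit(extra))
    Xc <- geno$values[, cand_union, drop = FALSE]
    # mask: gene x candidate admissibility
    allow <- matrix(FALSE, length(genes), length(cand_union),
                    dimnames = list(genes, cand_union))
    allow[, hs_c] <- TRUE
    ok <- !is.na(extra)
    allow[cbind(which(ok), match(extra[ok], cand_union))] <- TRUE
    # residualize on covariates + off-chromosome significant eQTLs
    Rc <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
    for (gi in seq_along(genes)) {
      mk <- eqtls$peak_marker[eqtls$gene == genes[gi] & eqtls$chrom != cn]
      Rc[, gi] <- qr.resid(qr(cbind(W, geno$values[, mk, drop = FALSE])),
                           expr[, genes[gi]])
    }
    sel <- lapply(genes, function(g) character(0))
    names(sel) <- genes
    active <- seq_along(genes)
    for (step in seq_len(cfg$max_iter)) {
      sr <- masked_scan_round(Rc[, active, drop = FALSE], Xc,
                              allow[active, , drop = FALSE], cfg,
                              seed = cfg$seed + step)
      if (is.na(sr$threshold)) break
      sig <- which(sr$max_lod > sr$threshold)
      if (!length(sig)) break
      for (si in sig) {
        g <- active[si]
        mk <- cand_union[sr$max_idx[si]]
        sel[[g]] <- c(sel[[g]], mk)
        Rc[, g] <- qr.resid(qr(cbind(1, geno$values[, mk])), Rc[, g])
      }
      active <- active[sig]
    }
    for (g in which(lengths(sel) > 0)) {
      mk <- sel[[g]]
      y <- qr.resid(qr(cbind(W, geno$values[, eqtls$peak_marker[
        eqtls$gene == genes[g] & eqtls$chrom != cn], drop = FALSE])),
        expr[, genes[g]])
      fit <- stats::lm.fit(cbind(1, geno$values[, mk, drop = FALSE]), y)
      coefs[[length(coefs) + 1L]] <- data.table::data.table(
        gene = genes[g], marker = mk, coef = fit$coefficients[-1])
    }
  }
  co <- if (length(coefs)) data.table::rbindlist(coefs) else
    data.table::data.table(gene = character(), marker = character(),
                           coef = numeric())
  hs <- co[co$marker %in% hotspot_markers, ]
  counts <- data.table::data.table(marker = hotspot_markers)
  counts$n_targets <- vapply(hotspot_markers,
                             function(mk) sum(hs$marker == mk & hs$coef != 0), 0L)
  list(coefficients = co, counts = counts)
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else x %in% TRUE

# scan_round with a per-gene admissible-marker mask
masked_scan_round <- function(Rc, Xc, allow, cfg, seed) {
  n <- nrow(Rc)
  Rs <- scale(Rc); Rs[!is.finite(Rs)] <- 0
  Xs <- scale(Xc); Xs[!is.finite(Xs)] <- 0
  r <- crossprod(Rs, Xs) / (n - 1)
  lod <- lod_from_r2(r^2, n)
  lod[!allow] <- 0
  mx <- row_max(lod)
  set.seed(seed)
  n_exp <- numeric(length(cfg$grid))
  for (k in seq_len(cfg$n_perm)) {
    pidx <- sample.int(n)
    lp <- lod_from_r2((crossprod(Rs[pidx, , drop = FALSE], Xs) / (n - 1))^2, n)
    lp[!allow] <- 0
    ps <- sort(row_max(lp)$value)
    n_exp <- n_exp + (length(ps) - findInterval(cfg$grid, ps))
  }
  thr <- fdr_threshold(mx$value, n_exp / cfg$n_perm, cfg)
  list(threshold = thr$threshold, max_lod = mx$value, max_idx = mx$index)
}

#' Flag subtelomeric hotspot peaks
#'
#' Hotspots whose peak lies within \code{dist_bp} of the first or last
#' mapped marker of their chromosome are flagged (and conventionally
#' excluded from gene-content summaries).
#'
#' @param peaks data.table with \code{pos} column (and map context).
#' @param map_c chromosome marker map.
#' @param dist_bp flag distance (default 5000).
#' @return logical vector.
#' @export
subtelomeric_flag <- function(peaks, map_c, dist_bp = 5000) {
  lo <- min(map_c$pos); hi <- max(map_c$pos)
  peaks$pos - lo <= dist_bp | hi - peaks$pos <= dist_bp
}
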