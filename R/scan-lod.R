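#' Univariate LOD scores from correlations
#'
#' LOD_j = -n * ln(1 - r_j^2) / (2 ln 10) with r_j the Pearson correlation
#' between the (residual) phenotype and marker j.  Identical to
#' (n/2) log10(RSS0/RSS1) of the one-marker regression.
#'
#' @param R residual phenotype: vector, or segregants x genes matrix.
#' @param X segregants x markers genotype matrix.
#' @return list with \code{lod} and signed \code{r} (genes x markers
#'   matrices, or vectors when \code{R} is a vector).  Zero-variance
#'   markers get LOD 0 with a warning.
#' @export
lod_scan <- function(R, X) {
  vec <- is.null(dim(R))
  Rm <- as.matrix(R)
  n <- nrow(Rm)
  stopifnot(n >= 3, nrow(X) == n)
  sdx <- apply(X, 2, sd)
  bad <- sdx == 0
  if (any(bad)) warning("zero-variance marker(s); LOD set to 0")
  Xs <- scale(X)
  Xs[, bad] <- 0
  r <- crossprod(scale(Rm), Xs) / (n - 1)
  r[!is.finite(r)] <- 0
  lod <- lod_from_r2(r^2, n)
  if (vec) list(lod = as.vector(lod), r = as.vector(r))
  else list(lod = lod, r = r)
}

# the printed LOD formula
lod_from_r2 <- function(r2, n) {
  -n * log(1 - pmin(r2, 1 - 1e-15)) / (2 * log(10))
}

# fast per-row max and argmax
row_max <- function(x) {
  j <- max.col(x, ties.method = "first")
  list(value = x[cbind(seq_len(nrow(x)), j)], index = j)
}

#' Scan configuration for additive eQTL mapping
#'
#' @param n_perm permutations per FDR evaluation (default 1000).
#' @param grid LOD threshold grid: 1.5 to 9 in 151 steps of 0.05.
#' @param alpha target FDR (default 0.05).
#' @param bg_lod,bg_rounds background-effect screen: LOD cutoff and number
#'   of screen rounds.
#' @param polygenic apply the LOCO polygenic correction?
#' @param max_iter cap on forward steps per chromosome.
#' @param ci_drop LOD-drop used for confidence intervals.
#' @param seed integer seed for the permutations.
#' @export
scan_config <- function(n_perm = 1000, grid = seq(1.5, 9, by = 0.05),
                        alpha = 0.05, bg_lod = 3.5, bg_rounds = 3,
                        polygenic = TRUE, max_iter = 30, ci_drop = 1.5,
                        seed = 1L) {
  stopifnot(all(diff(grid) > 0), alpha > 0, alpha < 1)
  list(n_perm = n_perm, grid = grid, alpha = alpha, bg_lod = bg_lod,
       bg_rounds = bg_rounds, polygenic = polygenic, max_iter = max_iter,
       ci_drop = ci_drop, seed = as.integer(seed))
}

#' Permutation-grid FDR threshold
#'
#' For each grid value T, FDR(T) = (average over permutation runs of the
#' number of genes with permuted max LOD > T) / (number of genes observed
#' with max LOD > T).  Returns the smallest grid value with FDR < alpha, or
#' NA when none qualifies (no detections this round).  When no gene is
#' observed above T the ratio is 0 if the permutation expectation is also 0
#' and +Inf otherwise.
#'
#' @param observed_max per-gene observed maximum LOD.
#' @param perm_max matrix of permuted per-gene maxima (runs x genes), or a
#'   precomputed vector of expected counts per grid value.
#' @param cfg a [scan_config()].
#' @return list(threshold, table) where table holds grid, observed and
#'   expected counts and FDR; \code{threshold} is NA when nothing passes.
#' @export
fdr_threshold <- function(observed_max, perm_max, cfg = scan_config()) {
  grid <- cfg$grid
  obs_sorted <- sort(observed_max)
  n_obs <- length(observed_max) - findInterval(grid, obs_sorted)
  if (is.matrix(perm_max)) {
    ps <- sort(as.vector(perm_max))
    n_exp <- (length(ps) - findInterval(grid, ps)) / nrow(perm_max)
  } else {
    stopifnot(length(perm_max) == length(grid))
    n_exp <- perm_max
  }
  fdr <- ifelse(n_obs > 0, n_exp / n_obs, ifelse(n_exp == 0, 0, Inf))
  # a threshold with no observed exceedances cannot yield detections
  i <- which(fdr < cfg$alpha & n_obs > 0)
  thr <- if (length(i)) grid[i[1]] else NA_real_
  list(threshold = thr,
       table = data.table::data.table(grid = grid, observed = n_obs,
                                      expected = n_exp, fdr = fdr))
}

#' 1.5-LOD-drop confidence interval around a peak
#'
#' The smallest contiguous marker interval around the peak on which the
#' LOD stays above peak - drop; the adjacent exterior markers fall below
#' the drop.  When the collapsed map is available, the bp bounds are
#' extended to cover all members of the boundary markers' perfect-LD
#' groups.
#'
#' @param lod LOD vector along one chromosome (marker order).
#' @param peak index of the peak (argmax of \code{lod}).
#' @param drop LOD drop (default 1.5).
#' @param geno optional \code{genotype_matrix} for bp bounds / LD extension.
#' @param chromosome chromosome name matching \code{lod} (needed with
#'   \code{geno}).
#' @return list(left, right) marker indices, plus bp_lo/bp_hi when a map
#'   was supplied.  A peak at the chromosome end yields a one-sided
#'   interval.
#' @export
lod_drop_interval <- function(lod, peak, drop = 1.5, geno = NULL,
                              chromosome = NULL) {
  stopifnot(peak >= 1, peak <= length(lod))
  cut <- lod[peak] - drop
  left <- peak
  while (left > 1 && lod[left - 1] >= cut) left <- left - 1
  right <- peak
  while (right < length(lod) && lod[right + 1] >= cut) right <- right + 1
  out <- list(left = left, right = right)
  if (!is.null(geno)) {
    idx <- marker_index(geno, chromosome)
    stopifnot(length(idx) == length(lod))
    map_c <- geno$map[idx, ]
    out$bp_lo <- map_c$pos[left]
    out$bp_hi <- map_c$pos[right]
    if (!is.null(geno$ld_groups)) {
      for (b in c(left, right)) {
        mem <- geno$ld_groups[[map_c$marker[b]]]
        if (!is.null(mem)) {
          # members may live anywhere pre-collapse; restrict to this chromosome
          mpos <- as.integer(sub(".*_", "", mem[startsWith(mem, paste0(chromosome, "_"))]))
          if (length(mpos)) {
            out$bp_lo <- min(out$bp_lo, mpos)
            out$bp_hi <- max(out$bp_hi, mpos)
          }
        }
      }
    }
  }
  out
}

#' Monte-Carlo single-marker detection power
#'
#' Fraction of simulated single-marker tests whose LOD exceeds a
#' threshold, for a balanced biallelic marker explaining a given fraction
#' of phenotypic variance in n segregants.
#'
#' @param n segregants.
#' @param variance_explained fraction of phenotypic variance (in [0, 1)).
#' @param threshold LOD significance threshold.
#' @param n_sims Monte-Carlo draws.
#' @param seed integer seed.
#' @return detection power in [0, 1].
#' @export
detection_power <- function(n, variance_explained, threshold, n_sims = 1000,
                            seed = 1L) {
  stopifnot(variance_explained >= 0, variance_explained < 1)
  set.seed(seed)
  b <- sqrt(variance_explained)
  hits <- 0L
  for (s in seq_len(n_sims)) {
    x <- sample(c(-1, 1), n, replace = TRUE)
    y <- b * x + rnorm(n, 0, sqrt(1 - variance_explained))
    r <- cor(x, y)
    if (lod_from_r2(r^2, n) > threshold) hits <- hits + 1L
  }
  hits / n_sims
}
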