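#' Pipeline power to detect an eQTL of given effect size
#'
#' Measures the Monte-Carlo power of the additive mapping pipeline for a
#' single eQTL explaining \code{variance_explained} of phenotypic variance
#' in a cross of \code{n_segregants}, at the pipeline's own genome-wide
#' significance criterion.  The criterion is derived exactly as in mapping:
#' a realistic synthetic study (generator defaults: polygenic genes with
#' 0-21 eQTLs of mostly small effect, hotspots, batch/growth nuisance) is
#' simulated; genes are screened for background effects, residualized per
#' chromosome with the LOCO mixed model, and the first-round
#' permutation-grid FDR threshold is computed per chromosome.  Power is
#' the fraction of independently simulated single-QTL genes whose scan on
#' the causal chromosome exceeds that chromosome's threshold.
#'
#' @param seed master seed.
#' @param n_segregants cross size (study design default 1012).
#' @param n_markers collapsed marker count (~2000 at desk scale).
#' @param n_study_genes genes in the threshold-derivation study.
#' @param n_signal_genes single-QTL genes used to measure power.
#' @param variance_explained planted variance fraction (default 0.025).
#' @param cfg a [scan_config()]; \code{cfg$n_perm} controls the FDR
#'   permutations (1000 for the full procedure).
#' @return list: power_pct, detected, thresholds (per chromosome),
#'   n_signal, study sizes.
#' @export
eqtl_power_study <- function(seed = 1L, n_segregants = 1012,
                             n_markers = 2000, n_study_genes = 1000,
                             n_signal_genes = 500,
                             variance_explained = 0.025,
                             cfg = scan_config(n_perm = 1000, seed = seed)) {
  study <- simulate_study(n_segregants, n_markers, n_study_genes,
                          seed = seed)
  geno <- study$geno
  P <- study$expression$values
  Z <- detect_background_effects(P, study$covariates, geno, cfg)
  chroms <- sort(unique(geno$map$chrom))
  thresholds <- setNames(rep(NA_real_, length(chroms)), chroms)
  for (cn in chroms) {
    idx <- marker_index(geno, cn)
    Rc <- loco_residual_matrix(P, study$covariates, geno, Z, cn,
                               cfg$polygenic)
    sr <- scan_round(Rc, geno$values[, idx, drop = FALSE], cfg,
                     seed = cfg$seed + 1L)
    thresholds[cn] <- sr$threshold
  }
  # fall back to the strictest derived threshold on chromosomes where the
  # study yields none (can happen for very small scaled-down studies)
  if (anyNA(thresholds)) thresholds[is.na(thresholds)] <- max(thresholds, na.rm = TRUE)
  # independent single-QTL genes at the stated effect size
  set.seed(seed + 1000L)
  b <- sqrt(variance_explained)
  causal <- sample.int(ncol(geno$values), n_signal_genes, replace = TRUE)
  Y <- geno$values[, causal, drop = FALSE] * b +
    matrix(rnorm(n_segregants * n_signal_genes, 0,
                 sqrt(1 - variance_explained)), n_segregants)
  detected <- logical(n_signal_genes)
  causal_chrom <- geno$map$chrom[causal]
  for (cn in unique(causal_chrom)) {
    gi <- which(causal_chrom == cn)
    idx <- marker_index(geno, cn)
    sc <- lod_scan(Y[, gi, drop = FALSE], geno$values[, idx, drop = FALSE])
    mx <- row_max(sc$lod)
    detected[gi] <- mx$value > thresholds[cn]
  }
  list(power_pct = 100 * mean(detected), detected = detected,
       thresholds = thresholds, n_signal = n_signal_genes,
       n_segregants = n_segregants, n_markers = ncol(geno$values),
       n_study_genes = n_study_genes)
}
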