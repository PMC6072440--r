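#' Hypergeometric downsampling to balance allele totals
#'
#' When the grand total of one allele exceeds the other's (e.g. a 0.5%
#' excess of reads mapping to one parental genome), that allele's per-gene
#' counts are downsampled by a multivariate hypergeometric draw so the
#' grand totals match while each gene's expected proportion is preserved.
#'
#' @param tab data.table/data.frame with columns gene, count_BY, count_RM.
#' @param seed integer seed.
#' @return the table with the larger allele downsampled.
#' @export
downsample_counts <- function(tab, seed = 1L) {
  tab <- data.table::as.data.table(tab)
  tot_by <- sum(tab$count_BY); tot_rm <- sum(tab$count_RM)
  if (tot_by == tot_rm) return(tab)
  big <- if (tot_by > tot_rm) "count_BY" else "count_RM"
  target <- min(tot_by, tot_rm)
  set.seed(seed)
  tab[[big]] <- rmvhyper(tab[[big]], target)
  tab
}

# sequential multivariate hypergeometric draw of `target` balls from urns
# with `counts` balls each
rmvhyper <- function(counts, target) {
  stopifnot(target <= sum(counts))
  out <- integer(length(counts))
  remaining <- sum(counts)
  left <- target
  for (i in seq_along(counts)) {
    remaining <- remaining - counts[i]
    out[i] <- rhyper(1, counts[i], remaining, left)
    left <- left - out[i]
  }
  out
}

#' Binomial test of allele-specific expression
#'
#' Genes with fewer than \code{min_reads} total reads are dropped; the
#' remainder get an exact two-sided binomial test against p = 0.5 and a
#' Bonferroni-corrected significance call at 0.05 / n_tests.  Fold changes
#' are log2(count_RM / count_BY); genes with a zero count use a 0.5
#' pseudo-count and are flagged.
#'
#' @param tab table with columns gene, count_BY, count_RM.
#' @param min_reads total-read filter (default 20).
#' @param n_tests Bonferroni denominator (default: number of tested genes).
#' @param alpha family-wise level (default 0.05).
#' @return data.table: gene, count_BY, count_RM, total, p_value,
#'   significant, log2_fold_change, zero_count_flag; attribute
#'   \code{cutoff} holds the Bonferroni p cutoff.
#' @export
ase_test <- function(tab, min_reads = 20, n_tests = NULL, alpha = 0.05) {
  tab <- data.table::as.data.table(tab)
  tab$total <- tab$count_BY + tab$count_RM
  tab <- tab[tab$total >= min_reads, ]
  if (is.null(n_tests)) n_tests <- nrow(tab)
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i)
    stats::binom.test(tab$count_RM[i], tab$total[i], 0.5)$p.value, 0)
  cutoff <- alpha / n_tests
  tab$significant <- tab$p_value < cutoff
  tab$zero_count_flag <- tab$count_BY == 0 | tab$count_RM == 0
  num <- ifelse(tab$count_RM == 0, 0.5, tab$count_RM)
  den <- ifelse(tab$count_BY == 0, 0.5, tab$count_BY)
  tab$log2_fold_change <- log2(num / den)
  data.table::setattr(tab, "cutoff", cutoff)
  tab
}

#' Beta-binomial overdispersion estimate from ASE counts
#'
#' Maximizes the summed beta-binomial log-likelihood of the observed
#' RM-allele counts over the overdispersion rho, with the success
#' probability fixed (0.5 by default, i.e. no true allelic imbalance
#' assumed).  rho -> 0 recovers the binomial likelihood.
#'
#' @param tab table with columns count_BY, count_RM (genes with total
#'   below \code{min_reads} are ignored).
#' @param fixed_p fixed success probability (default 0.5).
#' @param min_reads total-read filter (default 20).
#' @return list of class \code{overdispersion_fit}: rho, loglik, n_genes,
#'   boundary flag.
#' @export
fit_overdispersion <- function(tab, fixed_p = 0.5, min_reads = 20) {
  tab <- data.table::as.data.table(tab)
  total <- tab$count_BY + tab$count_RM
  keep <- total >= min_reads
  if (sum(keep) < 10) stop("need >= 10 genes with total >= ", min_reads)
  k <- tab$count_RM[keep]; nn <- total[keep]
  nll <- function(rho) -sum(dbetabinom(k, nn, fixed_p, rho, log = TRUE))
  op <- optimize(nll, c(0, 0.5), tol = 1e-8)
  rho <- op$minimum
  boundary <- rho < 1e-6
  if (boundary && nll(0) <= op$objective) rho <- 0
  structure(list(rho = rho, loglik = -nll(rho), n_genes = sum(keep),
                 boundary = boundary),
            class = "overdispersion_fit")
}

#' Monte-Carlo power to detect allele-specific expression
#'
#' Simulates beta-binomial allele counts at a given total coverage and
#' log2 fold change, applies the binomial test, and reports the fraction
#' of simulations below each alpha plus the fraction whose fold-change
#' direction agrees with the truth.
#'
#' @param total total read count (scalar or vector for a grid).
#' @param log2fc log2 fold change (scalar or vector).
#' @param rho beta-binomial overdispersion.
#' @param n_sims simulations per cell (default 1000).
#' @param alphas significance levels (default 0.05 and the Bonferroni
#'   cutoff for 3340 tests).
#' @param seed integer seed.
#' @return data.table: total, log2fc, one power column per alpha,
#'   sign_agreement.
#' @export
ase_power <- function(total, log2fc, rho, n_sims = 1000,
                      alphas = c(0.05, 0.05 / 3340), seed = 1L) {
  stopifnot(rho >= 0, rho < 1)
  grid <- data.table::CJ(total = total, log2fc = log2fc)
  set.seed(seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tt <- grid$total[i]; fc <- grid$log2fc[i]
    p <- 2^fc / (1 + 2^fc)
    k <- rbetabinom(n_sims, tt, p, rho)
    pv <- vapply(k, function(x) stats::binom.test(x, tt, 0.5)$p.value, 0)
    pow <- vapply(alphas, function(a) mean(pv < a), 0)
    agree <- if (fc == 0) NA_real_ else mean(sign(k - tt / 2) == sign(fc))
    c(pow, agree)
  })
  res <- do.call(rbind, res)
  colnames(res) <- c(paste0("power_", signif(alphas, 3)), "sign_agreement")
  cbind(grid, data.table::as.data.table(res))
}

#' Gene-matched ASE power simulation
#'
#' For each gene, simulates \code{n_sims} allele-count draws at its
#' observed coverage using a supplied effect size (e.g. its eQTL fold
#' change) and the dataset overdispersion, reporting per-gene power.
#'
#' @param totals per-gene coverages.
#' @param log2fc per-gene log2 fold changes.
#' @param rho overdispersion.
#' @param n_sims simulations per gene (default 100).
#' @param alpha significance level (default the 3340-test Bonferroni
#'   cutoff).
#' @param seed integer seed.
#' @return per-gene power vector.
#' @export
ase_power_gene_matched <- function(totals, log2fc, rho, n_sims = 100,
                                   alpha = 0.05 / 3340, seed = 1L) {
  set.seed(seed)
  p <- 2^log2fc / (1 + 2^log2fc)
  vapply(seq_along(totals), function(i) {
    k <- rbetabinom(n_sims, totals[i], p[i], rho)
    mean(vapply(k, function(x)
      stats::binom.test(x, totals[i], 0.5)$p.value, 0) < alpha)
  }, 0)
}

#' Standardized major axis (SMA) regression
#'
#' Symmetric line fit for comparing two error-prone effect-size measures:
#' slope = sign(r) * sd(y) / sd(x), intercept through the means, with the
#' standard SMA confidence interval based on r^2 and n.
#'
#' @param x,y numeric vectors.
#' @param level confidence level (default 0.95).
#' @return list: slope, intercept, r2, slope_ci (length 2), n.
#' @export
sma_slope <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  r <- cor(x, y)
  slope <- sign(ifelse(r == 0, 1, r)) * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  n <- length(x)
  B <- qf(level, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
  if (slope < 0) ci <- rev(ci)
  list(slope = slope, intercept = intercept, r2 = r^2,
       slope_ci = ci, n = n)
}
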