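#' Beta-binomial density with overdispersion rho
#'
#' Parameterized by success probability \code{p} and overdispersion
#' \code{rho} in [0, 1): shape parameters are a = p(1-rho)/rho and
#' b = (1-p)(1-rho)/rho, so the count variance is
#' n p (1-p) (1 + (n-1) rho).  rho = 0 is exactly binomial.
#'
#' @param x observed successes.
#' @param size total trials.
#' @param prob success probability.
#' @param rho overdispersion in [0, 1).
#' @param log return log density?
#' @export
dbetabinom <- function(x, size, prob, rho, log = FALSE) {
  stopifnot(rho >= 0, rho < 1)
  if (rho < 1e-12) return(dbinom(x, size, prob, log = log))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  if (log) ll else exp(ll)
}

# beta-binomial draws
rbetabinom <- function(n, size, prob, rho) {
  if (rho < 1e-12) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate allele-specific read counts
#'
#' Draws RM-allele counts from a beta-binomial with success probability
#' p = 2^fc / (1 + 2^fc) per gene (fc is the log2 RM/BY fold change) and a
#' shared overdispersion rho; the BY count is total - RM.
#'
#' @param totals per-gene total read counts (>= 0).
#' @param fold_changes per-gene log2 fold changes (RM over BY), recycled.
#' @param rho overdispersion in [0, 1).
#' @param n_sims number of simulated datasets.
#' @param seed integer seed.
#' @return data.table with columns sim, gene, total, count_RM, count_BY.
#' @export
simulate_ase_counts <- function(totals, fold_changes, rho, n_sims = 1,
                                seed = 1L) {
  if (rho >= 1 || rho < 0) stop("rho must be in [0, 1)")
  stopifnot(all(totals >= 0))
  set.seed(seed)
  ng <- length(totals)
  fold_changes <- rep_len(fold_changes, ng)
  p <- 2^fold_changes / (1 + 2^fold_changes)
  gene <- if (!is.null(names(totals))) names(totals) else
    sprintf("gene_%04d", seq_len(ng))
  out <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    rm_count <- rbetabinom(ng, totals, p, rho)
    out[[s]] <- data.table::data.table(sim = s, gene = gene,
                                       total = as.integer(totals),
                                       count_RM = as.integer(rm_count),
                                       count_BY = as.integer(totals - rm_count))
  }
  data.table::rbindlist(out)
}
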