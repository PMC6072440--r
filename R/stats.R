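#' Storey's pi1: estimated fraction of alternative tests
#'
#' pi0(lambda) = #\{p > lambda\} / (n (1 - lambda)) over a lambda grid;
#' the final pi0 is a natural cubic smoothing spline through pi0(lambda)
#' evaluated at the largest lambda, clipped to [0, 1]; pi1 = 1 - pi0.
#' Degenerate p-value distributions fall back to the fixed lambda = 0.5
#' estimate with a warning.
#'
#' @param p p-values in [0, 1] (n >= 20).
#' @param lambda_grid evaluation grid (default 0.05..0.95 by 0.05).
#' @return list of class \code{pi1_estimate}: pi1, pi0, method, n,
#'   lambda_grid.
#' @export
storey_pi1 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) < 20) stop("need n >= 20 p-values")
  n <- length(p)
  pi0_l <- vapply(lambda_grid, function(l) mean(p > l) / (1 - l), 0)
  method <- "smoother"
  pi0 <- tryCatch({
    sp <- smooth.spline(lambda_grid, pi0_l, df = 3)
    predict(sp, x = max(lambda_grid))$y
  }, error = function(e) NA_real_)
  if (!is.finite(pi0)) {
    warning("degenerate p-value distribution; fixed-lambda fallback")
    pi0 <- mean(p > 0.5) / 0.5
    method <- "fixed"
  }
  pi0 <- min(max(pi0, 0), 1)
  structure(list(pi1 = 1 - pi0, pi0 = pi0, method = method, n = n,
                 lambda_grid = lambda_grid),
            class = "pi1_estimate")
}

#' Likelihood-ratio (G) test of independence on a 2x2 table
#'
#' G = 2 sum O ln(O/E) with the 0 ln 0 = 0 convention; p from chi-square
#' with 1 df.  A zero row or column margin yields G = 0, p = 1.
#'
#' @param counts 2x2 matrix of nonnegative counts.
#' @return list(G, p).
#' @export
g_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(list(G = 0, p = 1))
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  terms <- ifelse(counts > 0, counts * log(counts / E), 0)
  G <- 2 * sum(terms)
  list(G = G, p = pchisq(G, 1, lower.tail = FALSE))
}

#' Fisher's exact 2x2 enrichment test
#'
#' Sample (cross-product) odds ratio and a two-sided p-value obtained by
#' summing hypergeometric probabilities of all tables (with the observed
#' margins) at most as probable as the observed one.
#'
#' @param counts 2x2 matrix: rows = in/out of the category, columns =
#'   in/out of the selected set.
#' @return list(odds_ratio, p).
#' @export
fisher_enrichment <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  a <- counts[1, 1]; b <- counts[1, 2]; c <- counts[2, 1]; d <- counts[2, 2]
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  m <- a + b          # row 1 margin
  k <- a + c          # column 1 margin
  nn <- a + b + c + d
  support <- max(0, k - (nn - m)):min(k, m)
  dens <- stats::dhyper(support, m, nn - m, k)
  p <- sum(dens[dens <= stats::dhyper(a, m, nn - m, k) * (1 + 1e-7)])
  list(odds_ratio = or, p = min(p, 1))
}
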