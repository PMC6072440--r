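#' Additive relatedness matrix from marker genotypes
#'
#' A = Gc Gc' / c with Gc the column-centred genotypes and c chosen so that
#' the mean diagonal is 1, making the additive variance component directly
#' interpretable on the phenotype scale.  The entries measure the fraction
#' of the genome shared between pairs of segregants (up to centring).
#'
#' @param geno a \code{genotype_matrix}.
#' @param exclude_chromosome optional chromosome name whose markers are left
#'   out (leave-one-chromosome-out kinship).
#' @param with_aa also return the Hadamard square A o A, whose entries are
#'   the fraction of marker pairs shared (pairwise-interaction kernel)?
#' @return list of class \code{kinship_matrix}: A, optionally AA, the marker
#'   ids used, and the normalization constant.
#' @export
additive_kinship <- function(geno, exclude_chromosome = NULL, with_aa = FALSE) {
  keep <- rep(TRUE, ncol(geno$values))
  if (!is.null(exclude_chromosome))
    keep <- !(geno$map$chrom %in% exclude_chromosome)
  if (sum(keep) < 2) stop("fewer than 2 markers after chromosome exclusion")
  Gc <- scale(geno$values[, keep, drop = FALSE], center = TRUE, scale = FALSE)
  A0 <- tcrossprod(Gc)
  cnorm <- mean(diag(A0))
  A <- A0 / cnorm
  out <- list(A = A, markers = colnames(geno$values)[keep], norm = cnorm)
  if (with_aa) out$AA <- A * A
  structure(out, class = "kinship_matrix")
}

# Restricted (REML) profile log-likelihood machinery for
#   y ~ N(X beta, sg2 * (K + delta I)),  delta = se2/sg2.
# Everything is computed in the eigenbasis of K: ytil = U'y, Xtil = U'X.
reml_loglik <- function(delta, ytil, Xtil, d) {
  n <- length(ytil); p <- ncol(Xtil)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xtil * w, Xtil)
  XtWy <- crossprod(Xtil * w, ytil)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  r <- ytil - Xtil %*% beta
  rss <- sum(w * r^2)
  sg2 <- rss / (n - p)
  -0.5 * ((n - p) * log(sg2) + sum(log(d + delta)) + 2 * sum(log(diag(ch))) +
            (n - p))
}

# maximize REML over delta: log-spaced grid then bounded refinement
reml_fit <- function(ytil, Xtil, d, grid_n = 41, tol = 1e-8) {
  lg <- seq(log(1e-6), log(1e6), length.out = grid_n)
  ll <- vapply(lg, function(x) reml_loglik(exp(x), ytil, Xtil, d), 0)
  i <- which.max(ll)
  lo <- lg[max(1, i - 1)]; hi <- lg[min(length(lg), i + 1)]
  op <- optimize(function(x) reml_loglik(exp(x), ytil, Xtil, d),
                 c(lo, hi), maximum = TRUE, tol = tol)
  delta <- exp(op$maximum)
  n <- length(ytil); p <- ncol(Xtil)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xtil * w, Xtil)
  beta <- solve(XtWX, crossprod(Xtil * w, ytil))
  r <- ytil - Xtil %*% beta
  sg2 <- sum(w * r^2) / (n - p)
  list(delta = delta, sg2 = sg2, se2 = delta * sg2, beta = beta,
       loglik = op$objective, converged = is.finite(op$objective))
}

#' Eigen-decomposition of a kinship matrix (cache for repeated fits)
#' @param K a \code{kinship_matrix} or plain symmetric matrix.
#' @return list(values, vectors).
#' @export
kinship_eigen <- function(K) {
  A <- if (inherits(K, "kinship_matrix")) K$A else K
  if (min(eigen(A, symmetric = TRUE, only.values = TRUE)$values[nrow(A)],
          0) < -1e-6 * nrow(A))
    stop("kinship matrix is not PSD within tolerance")
  eg <- eigen(A, symmetric = TRUE)
  eg$values <- pmax(eg$values, 0)
  eg
}

#' Variance-component (heritability) fit
#'
#' Single-component model: y ~ N(mu, sg2_A * A + sg2_E * I), fitted by REML
#' with a spectral decomposition of A and 1-D optimization of the variance
#' ratio (global log-spaced grid plus bounded refinement).  Two-component
#' model adds sg2_AA * (A o A) for pairwise marker interactions and is
#' maximized by Nelder-Mead over the simplex of variance fractions from 5
#' starts.
#'
#' Phenotypes are expected to be covariate-residualized beforehand
#' (two-stage procedure); only an intercept is fitted here.
#'
#' @param y phenotype vector.
#' @param K a \code{kinship_matrix} (with \code{AA} present for the
#'   two-component model).
#' @param components \code{"A"} or \code{c("A","AA")}.
#' @param eig optional precomputed [kinship_eigen()] of K (single-component
#'   fits only), reused across genes.
#' @return list of class \code{variance_components}: sigma2_A, sigma2_E,
#'   optionally sigma2_AA, h2 (= sigma2_A / total), h2_AA, loglik,
#'   converged.
#' @export
fit_mixed <- function(y, K, components = "A", eig = NULL) {
  stopifnot(all(is.finite(y)))
  n <- length(y)
  if (identical(components, "A")) {
    if (is.null(eig)) eig <- kinship_eigen(K)
    ytil <- crossprod(eig$vectors, y)
    Xtil <- crossprod(eig$vectors, matrix(1, n, 1))
    fit <- reml_fit(ytil, Xtil, eig$values)
    h2 <- 1 / (1 + fit$delta)
    structure(list(sigma2_A = fit$sg2, sigma2_E = fit$se2, sigma2_AA = NULL,
                   h2 = h2, loglik = fit$loglik, converged = fit$converged),
              class = "variance_components")
  } else {
    A <- K$A
    AA <- K$AA
    if (is.null(AA)) stop("two-component fit needs K$AA (with_aa = TRUE)")
    X <- matrix(1, n, 1)
    obj <- function(par) {  # softmax over (fA, fAA, fE)
      e <- exp(c(par, 0)); f <- e / sum(e)
      V0 <- f[1] * A + f[2] * AA + diag(f[3] + 1e-8, n)
      ch <- tryCatch(chol(V0), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
      Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
      XtViX <- crossprod(X, Vi_X)
      beta <- solve(XtViX, crossprod(X, Vi_y))
      r <- y - X %*% beta
      Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
      s2 <- sum(r * Vi_r) / (n - 1)
      0.5 * ((n - 1) * log(s2) + 2 * sum(log(diag(ch))) +
               determinant(XtViX)$modulus[1])
    }
    starts <- list(c(0, 0), c(2, -2), c(-2, -2), c(2, 2), c(-3, 3))
    best <- NULL
    for (s in starts) {
      op <- optim(s, obj, method = "Nelder-Mead",
                  control = list(maxit = 400, reltol = 1e-10))
      if (is.null(best) || op$value < best$value) best <- op
    }
    e <- exp(c(best$par, 0)); f <- e / sum(e)
    # total variance scale from the profiled sigma^2
    V0 <- f[1] * A + f[2] * AA + diag(f[3] + 1e-8, n)
    ch <- chol(V0)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% beta
    s2 <- sum(r * backsolve(ch, forwardsolve(t(ch), r))) / (n - 1)
    structure(list(sigma2_A = s2 * f[1], sigma2_AA = s2 * f[2],
                   sigma2_E = s2 * f[3],
                   h2 = f[1], h2_AA = f[2],
                   loglik = -best$value,
                   converged = best$convergence == 0),
              class = "variance_components")
  }
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components: sigma2_A =", signif(x$sigma2_A, 4),
      if (!is.null(x$sigma2_AA)) paste(" sigma2_AA =", signif(x$sigma2_AA, 4)),
      " sigma2_E =", signif(x$sigma2_E, 4), "\n  h2 =", signif(x$h2, 4), "\n")
  invisible(x)
}

#' Across-gene interaction-to-additive variance ratio
#'
#' Bookkeeping summary for two-component fits: the ratio of the average
#' pairwise-interaction component (sigma2_AA) to the average additive
#' component (sigma2_A) across genes.  The per-gene ratio is also
#' returned but is dominated by outliers (many genes fit sigma2_AA = 0
#' while a few small-sigma2_A genes explode), so the across-gene ratio
#' of averages is the headline number.
#'
#' @param fits list of two-component \code{variance_components}.
#' @return list(ratio_of_averages, per_gene_ratio).
#' @export
aa_ratio_summary <- function(fits) {
  sA <- vapply(fits, function(f) f$sigma2_A, 0)
  sAA <- vapply(fits, function(f) if (is.null(f$sigma2_AA)) NA_real_ else f$sigma2_AA, 0)
  if (anyNA(sAA)) stop("all fits must be two-component (A, AA)")
  list(ratio_of_averages = mean(sAA) / mean(sA),
       per_gene_ratio = ifelse(sA > 0, sAA / sA, NA_real_))
}

#' Precompute the LOCO context for one chromosome
#'
#' Eigen-decomposition of the off-chromosome kinship plus rotated covariate
#' design; reused across genes by [loco_residual()].
#'
#' @param geno a \code{genotype_matrix}.
#' @param chromosome focal chromosome (its markers are excluded).
#' @param covariates covariate table / matrix (see [residualize()]).
#' @return list used by [loco_residual()].
#' @export
loco_setup <- function(geno, chromosome, covariates = NULL) {
  K <- additive_kinship(geno, exclude_chromosome = chromosome)
  eg <- kinship_eigen(K)
  n <- nrow(geno$values)
  W <- design_matrix(covariates, n)
  qrW <- qr(W)
  W <- W[, qrW$pivot[seq_len(qrW$rank)], drop = FALSE]
  list(chromosome = chromosome, eig = eg, U = eg$vectors, d = eg$values,
       W = W, Wtil = crossprod(eg$vectors, W), n = n)
}

#' Leave-one-chromosome-out mixed-model residual
#'
#' Fits y = W alpha + Z_L c + a_L + e with a_L ~ N(0, sg2 * A_L) where A_L
#' excludes the focal chromosome, and returns y minus the fixed-effect fit
#' minus the BLUP of a_L.  Signal on the focal chromosome is retained.
#'
#' @param y phenotype vector.
#' @param setup a [loco_setup()] for the focal chromosome.
#' @param fixed_markers optional matrix of off-chromosome marker genotypes
#'   (large background effects Z_L) included as fixed effects.
#' @return residual vector.
#' @export
loco_residual <- function(y, setup, fixed_markers = NULL) {
  X <- setup$W
  Xtil <- setup$Wtil
  if (!is.null(fixed_markers)) {
    fm <- as.matrix(fixed_markers)
    X <- cbind(X, fm)
    Xtil <- cbind(Xtil, crossprod(setup$U, fm))
  }
  ytil <- crossprod(setup$U, y)
  fit <- reml_fit(ytil, Xtil, setup$d, grid_n = 25, tol = 1e-6)
  r_fixed_til <- ytil - Xtil %*% fit$beta
  # BLUP of a_L = U diag(d/(d+delta)) U'(y - X beta)
  blup <- setup$U %*% ((setup$d / (setup$d + fit$delta)) * r_fixed_til)
  as.vector(y - X %*% fit$beta - blup)
}

#' Whole-genome polygenic + fixed-effect residual
#'
#' Per-gene residual after covariates, a set of fixed marker effects and
#' the BLUP of a genome-wide polygenic term; used by the hotspot and
#' epistasis stages.
#'
#' @param y phenotype vector.
#' @param eig [kinship_eigen()] of the genome-wide kinship.
#' @param covariates covariate table / matrix.
#' @param fixed_markers optional marker genotype matrix (fixed effects).
#' @return residual vector.
#' @export
polygenic_residual <- function(y, eig, covariates = NULL, fixed_markers = NULL) {
  n <- length(y)
  X <- design_matrix(covariates, n)
  if (!is.null(fixed_markers)) X <- cbind(X, as.matrix(fixed_markers))
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  ytil <- crossprod(eig$vectors, y)
  Xtil <- crossprod(eig$vectors, X)
  fit <- reml_fit(ytil, Xtil, eig$values, grid_n = 25, tol = 1e-6)
  r_fixed_til <- ytil - Xtil %*% fit$beta
  blup <- eig$vectors %*% ((eig$values / (eig$values + fit$delta)) * r_fixed_til)
  as.vector(y - X %*% fit$beta - blup)
}
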