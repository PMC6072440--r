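#' Draw a ground-truth genetic architecture for synthetic expression traits
#'
#' Emulates the regulatory architecture seen in large yeast-cross eQTL
#' panels: per-gene eQTL counts around a median of ~6 (capped at 21), mostly
#' small marker effects (median ~2% of variance), a local eQTL for most
#' genes, a handful of trans hotspots each affecting a sizeable gene
#' fraction, heritabilities centred near 0.26, batch and growth nuisance
#' effects, and sparse epistatic pairs.
#'
#' Per gene: the number of eQTLs k is Poisson(\code{mean_eqtl}) truncated at
#' \code{max_eqtl}; the target heritability is Beta-distributed with mean
#' \code{h2_mean}; a fraction \code{poly_frac} of the genetic variance is
#' polygenic background spread over the relatedness structure; the remaining
#' additive variance is split over the k loci by a symmetric Dirichlet.
#' With probability \code{p_local} one eQTL sits at the marker closest to
#' the gene; each other eQTL is a hotspot marker with probability
#' \code{p_hotspot} (hotspots drawn with weights proportional to their
#' target fractions) and a uniformly random marker otherwise.
#'
#' @param geno a \code{genotype_matrix}.
#' @param n_genes number of genes.
#' @param mean_eqtl Poisson mean of per-gene eQTL counts.
#' @param max_eqtl hard cap on eQTLs per gene.
#' @param h2_mean,h2_shape mean and first shape parameter of the Beta
#'   distribution of per-gene heritability.
#' @param p_local probability that a gene has a local eQTL.
#' @param n_hotspots number of trans hotspots.
#' @param hotspot_frac_range range of per-hotspot target gene fractions.
#' @param p_hotspot probability that a trans eQTL is drawn from the hotspot
#'   set rather than placed uniformly.
#' @param poly_frac fraction of genetic variance that is polygenic.
#' @param epi_frac fraction of genes carrying one epistatic marker pair.
#' @param epi_var phenotypic variance fraction of an epistatic interaction.
#' @param n_batches number of experimental batches (round-robin assignment).
#' @param batch_sd SD of per-batch shifts, in phenotype-SD units.
#' @param growth_frac fraction of genes affected by the growth covariate.
#' @param growth_sd SD of growth-effect coefficients.
#' @param seed integer seed.
#' @return object of class \code{truth_table}.
#' @export
simulate_truth <- function(geno, n_genes = 1000,
                           mean_eqtl = 6, max_eqtl = 21,
                           h2_mean = 0.26, h2_shape = 1.6,
                           p_local = 0.75,
                           n_hotspots = 8, hotspot_frac_range = c(0.05, 0.4),
                           p_hotspot = 0.5,
                           poly_frac = 0.2,
                           epi_frac = 0.05, epi_var = 0.022,
                           n_batches = 13, batch_sd = 0.3,
                           growth_frac = 0.3, growth_sd = 0.25,
                           seed = 1L) {
  stopifnot(inherits(geno, "genotype_matrix"), h2_mean > 0, h2_mean < 1,
            poly_frac >= 0, poly_frac < 1)
  set.seed(seed)
  map <- geno$map
  m <- nrow(map)
  chroms <- unique(map$chrom)
  chrom_len <- vapply(chroms, function(cn) max(map$pos[map$chrom == cn]), 0)

  genes <- sprintf("gene_%04d", seq_len(n_genes))
  gchrom <- sample(chroms, n_genes, replace = TRUE, prob = chrom_len / sum(chrom_len))
  glen <- pmax(300L, round(rnorm(n_genes, 1400, 400)))
  gstart <- vapply(seq_len(n_genes), function(i) {
    sample.int(max(1L, as.integer(chrom_len[gchrom[i]]) - glen[i]), 1L)
  }, 0L)
  annotation <- data.table::data.table(
    gene = genes, chrom = gchrom, start = gstart,
    end = gstart + glen - 1L,
    strand = sample(c("+", "-"), n_genes, replace = TRUE))

  hotspot_idx <- sort(sample.int(m, n_hotspots))
  hotspot_frac <- runif(n_hotspots, hotspot_frac_range[1], hotspot_frac_range[2])

  k <- pmin(rpois(n_genes, mean_eqtl), max_eqtl)
  h2 <- rbeta(n_genes, h2_shape, h2_shape * (1 - h2_mean) / h2_mean)
  h2 <- pmin(h2, 0.95)
  h2[k == 0] <- h2[k == 0] * poly_frac  # genes without planted loci keep only background

  effects <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    if (k[i] == 0L) { effects[[i]] <- data.table::data.table(
      marker = character(), coef = numeric(), var_frac = numeric()); next }
    vfrac <- as.vector(rdirichlet1(k[i], 0.8)) * (1 - poly_frac) * h2[i]
    idx <- integer(k[i])
    j0 <- 1L
    if (runif(1) < p_local) {
      on_c <- which(map$chrom == gchrom[i])
      idx[1] <- on_c[which.min(abs(map$pos[on_c] - gstart[i]))]
      j0 <- 2L
    }
    if (j0 <= k[i]) for (j in j0:k[i]) {
      idx[j] <- if (runif(1) < p_hotspot)
        hotspot_idx[sample.int(n_hotspots, 1L, prob = hotspot_frac)]
      else sample.int(m, 1L)
    }
    # duplicate assignments collapse to distinct markers
    dup <- duplicated(idx)
    while (any(dup)) { idx[dup] <- sample.int(m, sum(dup)); dup <- duplicated(idx) }
    effects[[i]] <- data.table::data.table(
      marker = map$marker[idx],
      coef = sample(c(-1, 1), k[i], replace = TRUE) * sqrt(vfrac),
      var_frac = vfrac)
  }
  names(effects) <- genes

  epi_genes <- which(runif(n_genes) < epi_frac & k >= 0)
  epistasis <- data.table::data.table(
    gene = genes[epi_genes],
    marker1 = map$marker[sample.int(m, length(epi_genes), replace = TRUE)],
    marker2 = map$marker[sample.int(m, length(epi_genes), replace = TRUE)],
    coef = sample(c(-1, 1), length(epi_genes), replace = TRUE) * sqrt(epi_var))
  epistasis <- epistasis[epistasis$marker1 != epistasis$marker2, ]

  batch <- factor(rep_len(seq_len(n_batches), nrow(geno$values)))
  batch_effects <- matrix(rnorm(n_batches * n_genes, 0, batch_sd), n_batches, n_genes)
  growth_coef <- ifelse(runif(n_genes) < growth_frac, rnorm(n_genes, 0, growth_sd), 0)

  structure(list(genes = genes, annotation = annotation,
                 effects = effects, h2_true = setNames(h2, genes),
                 hotspots = data.table::data.table(
                   marker = map$marker[hotspot_idx], frac = hotspot_frac),
                 epistasis = epistasis,
                 poly_frac = poly_frac,
                 batch = batch, batch_effects = batch_effects,
                 growth_coef = setNames(growth_coef, genes),
                 baseline = setNames(rnorm(n_genes, 5, 2), genes),
                 seed = as.integer(seed)),
            class = "truth_table")
}

# one draw from a symmetric Dirichlet(alpha) of dimension k
rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

#' Generate expression phenotypes from a ground truth
#'
#' The generative model per gene is
#' phenotype = planted marker effects + epistatic terms + polygenic
#' background + Gaussian noise, with the noise variance chosen so that the
#' realized genetic variance fraction equals the gene's target heritability
#' exactly, followed by batch shifts, a growth-covariate effect and a
#' baseline shift (values live on a log2(TPM+0.5)-like scale).
#'
#' @param geno a \code{genotype_matrix}.
#' @param truth a [simulate_truth()] object.
#' @param seed integer seed for noise, polygenic draws and the growth
#'   covariate (defaults to \code{truth$seed + 1}).
#' @return list with \code{expression} (class \code{expression_matrix}),
#'   \code{covariates} (data.table: segregant, batch, growth) and
#'   \code{truth}, where the truth gains \code{genetic} (segregants x genes
#'   matrix of realized scaled genetic values) and \code{achieved_h2}.
#' @export
plant_expression <- function(geno, truth, seed = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  if (any(truth$h2_true < 0 | truth$h2_true > 1))
    stop("h2_true outside [0,1]")
  if (is.null(seed)) seed <- truth$seed + 1L
  set.seed(seed)
  X <- geno$values
  n <- nrow(X)
  genes <- truth$genes
  ng <- length(genes)

  poly_base <- NULL
  if (truth$poly_frac > 0) {
    A <- additive_kinship(geno)$A
    # PSD square root via eigen; polygenic draws u = E sqrt(d) z have cov A
    eg <- eigen(A, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    poly_base <- eg$vectors %*% (sqrt(d) * matrix(rnorm(n * ng), n, ng))
  }
  growth <- rnorm(n)

  P <- matrix(0, n, ng, dimnames = list(rownames(X), genes))
  genetic <- matrix(0, n, ng, dimnames = list(rownames(X), genes))
  achieved <- numeric(ng)
  col_of <- setNames(seq_len(ncol(X)), colnames(X))
  for (i in seq_len(ng)) {
    ef <- truth$effects[[i]]
    g <- numeric(n)
    if (nrow(ef) > 0) g <- g + X[, col_of[ef$marker], drop = FALSE] %*% ef$coef
    ei <- truth$epistasis[truth$epistasis$gene == genes[i], ]
    if (nrow(ei) > 0) for (r in seq_len(nrow(ei)))
      g <- g + ei$coef[r] * (X[, col_of[ei$marker1[r]]] * X[, col_of[ei$marker2[r]]])
    if (!is.null(poly_base)) {
      vg <- var(as.vector(g))
      s_poly <- if (vg > 0)
        sqrt(truth$poly_frac / (1 - truth$poly_frac) * vg)
      else sqrt(truth$h2_true[i])  # pure-background gene
      g <- g + s_poly * poly_base[, i] / max(sd(poly_base[, i]), 1e-12)
    }
    h2 <- truth$h2_true[i]
    vg <- var(as.vector(g))
    if (vg > 0 && h2 > 0) {
      e <- rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
      sc <- 1 / sqrt(vg / h2)  # total (genetic + noise) variance -> 1
      y <- (g + e) * sc
      genetic[, i] <- g * sc
    } else {
      y <- rnorm(n)
    }
    achieved[i] <- if (var(y) > 0) var(genetic[, i]) / var(as.vector(y)) else 0
    y <- y + truth$batch_effects[as.integer(truth$batch), i] +
      truth$growth_coef[i] * growth + truth$baseline[i]
    P[, i] <- y
  }
  truth$genetic <- genetic
  truth$achieved_h2 <- setNames(achieved, genes)
  expr <- structure(list(values = P, annotation = truth$annotation),
                    class = "expression_matrix")
  cov <- data.table::data.table(segregant = rownames(X),
                                batch = truth$batch, growth = growth)
  list(expression = expr, covariates = cov, truth = truth)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "segregants x", ncol(x$values), "genes\n")
  invisible(x)
}

#' One-call synthetic study
#'
#' Convenience wrapper: simulate a cross, a truth table and planted
#' expression with a single seed.
#'
#' @param n_segregants,n_markers,n_genes study dimensions.
#' @param seed master seed; cross, truth and noise seeds are derived from it.
#' @param ... passed to [simulate_truth()].
#' @return list(geno, expression, covariates, truth).
#' @export
simulate_study <- function(n_segregants = 1000, n_markers = 2000,
                           n_genes = 1000, seed = 1L, ...) {
  des <- cross_design(n_segregants, n_markers = n_markers, seed = seed)
  geno <- simulate_cross(des)
  truth <- simulate_truth(geno, n_genes = n_genes, seed = seed + 1L, ...)
  pe <- plant_expression(geno, truth, seed = seed + 2L)
  list(geno = geno, expression = pe$expression, covariates = pe$covariates,
       truth = pe$truth)
}
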