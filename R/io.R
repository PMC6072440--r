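#' Filter a raw TPM matrix to analysis-ready expression values
#'
#' Applies the standard panel filters: segregants with fewer than
#' \code{min_reads} total reads are dropped; transcripts are dropped when
#' they are identical across all retained segregants or when
#' log2(TPM + 0.5) is below \code{low_expr} in at least \code{low_frac} of
#' the retained segregants.  Values are returned as log2(TPM + 0.5).
#'
#' @param tpm segregants x transcripts matrix of TPM values (>= 0).
#' @param read_totals per-segregant total read counts (named or in row
#'   order).
#' @param annotation optional gene annotation (gene, chrom, start, end,
#'   strand) carried into the result.
#' @param min_reads minimum total reads per segregant (default 1e6).
#' @param low_expr,low_frac transcript filter: drop when log2(TPM+0.5) <
#'   \code{low_expr} in >= \code{low_frac} of segregants.
#' @return an \code{expression_matrix}.
#' @export
filter_expression <- function(tpm, read_totals, annotation = NULL,
                              min_reads = 1e6, low_expr = 1, low_frac = 0.5) {
  stopifnot(is.matrix(tpm), all(tpm >= 0), length(read_totals) == nrow(tpm))
  keep_seg <- read_totals >= min_reads
  if (!any(keep_seg)) stop("no segregants pass the read-count filter")
  x <- log2(tpm[keep_seg, , drop = FALSE] + 0.5)
  constant <- apply(x, 2, function(v) all(v == v[1]))
  low <- colMeans(x < low_expr) >= low_frac
  keep <- !(constant | low)
  if (!any(keep)) stop("no transcripts pass the expression filters")
  x <- x[, keep, drop = FALSE]
  if (!is.null(annotation))
    annotation <- annotation[annotation$gene %in% colnames(x), ]
  structure(list(values = x, annotation = annotation),
            class = "expression_matrix")
}

#' Collapse markers in perfect linkage disequilibrium
#'
#' Markers whose genotype columns are identical (never separated by
#' recombination in the panel) are collapsed to one representative, the
#' leftmost by genome position.  A column and its negation are distinct
#' haplotypes and are not collapsed.
#'
#' @param geno a \code{genotype_matrix} with values in -1/+1.
#' @return a \code{genotype_matrix} whose \code{ld_groups} is a named list
#'   mapping each representative to its member marker ids.
#' @export
collapse_perfect_ld <- function(geno) {
  X <- geno$values
  stopifnot(all(X %in% c(-1, 1)))
  # exact integer keys from two fixed pseudo-random projections, then verify
  set.seed(77)
  r1 <- sample.int(3L, nrow(X), replace = TRUE)
  r2 <- sample.int(5L, nrow(X), replace = TRUE)
  key <- paste(crossprod(X, r1), crossprod(X, r2))
  groups <- split(seq_len(ncol(X)), key)
  rep_idx <- integer(0)
  members <- list()
  for (g in groups) {
    while (length(g) > 0) {
      same <- vapply(g, function(j) all(X[, j] == X[, g[1]]), TRUE)
      grp <- g[same]
      rep_idx <- c(rep_idx, grp[1])
      members[[colnames(X)[grp[1]]]] <- colnames(X)[grp]
      g <- g[!same]
    }
  }
  rep_idx <- sort(rep_idx)
  ord <- colnames(X)[rep_idx]
  structure(list(values = X[, rep_idx, drop = FALSE],
                 map = geno$map[geno$map$marker %in% ord, ],
                 ld_groups = members[ord]),
            class = "genotype_matrix")
}

#' Ordinary-least-squares residuals against a covariate design
#'
#' @param P phenotype vector or segregants x genes matrix.
#' @param G covariate design: data.frame (factors expanded to dummies) or
#'   numeric matrix; an intercept is always included.
#' @return residuals with the same shape as \code{P}, orthogonal to every
#'   design column.  Rank-deficient designs have aliased columns dropped
#'   with a warning.
#' @export
residualize <- function(P, G = NULL) {
  W <- design_matrix(G, n = NROW(P))
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    warning("rank-deficient covariate design; dropping aliased columns")
  }
  res <- qr.resid(qrW, as.matrix(P))
  if (is.null(dim(P))) as.vector(res) else res
}

# build a numeric design matrix (with intercept) from a covariate table
design_matrix <- function(G, n) {
  if (is.null(G)) return(matrix(1, n, 1))
  if (is.matrix(G)) {
    if (!any(apply(G, 2, function(v) all(v == v[1])))) G <- cbind(1, G)
    return(G)
  }
  G <- as.data.frame(G)
  G <- G[, setdiff(names(G), "segregant"), drop = FALSE]
  if (!is.null(G$batch)) G$batch <- factor(G$batch)
  stats::model.matrix(~ ., data = G)
}

#' Write the tables of a synthetic study to a directory
#'
#' Genotypes, marker map, expression, covariates and the truth ledger
#' (JSON) are written as plain-text TSV with a fixed float format so that a
#' read round-trip is bit-identical.  Positions are 1-based.
#'
#' @param study list as returned by [simulate_study()].
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gv <- data.table::as.data.table(study$geno$values, keep.rownames = "segregant")
  data.table::fwrite(gv, file.path(dir, "genotypes.tsv"), sep = "\t")
  data.table::fwrite(study$geno$map, file.path(dir, "marker_map.tsv"), sep = "\t")
  ev <- data.table::as.data.table(signif(study$expression$values, 10),
                                  keep.rownames = "segregant")
  data.table::fwrite(ev, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(study$expression$annotation,
                     file.path(dir, "gene_annotation.tsv"), sep = "\t")
  cv <- data.table::copy(study$covariates)
  cv$growth <- signif(cv$growth, 10)
  data.table::fwrite(cv, file.path(dir, "covariates.tsv"), sep = "\t")
  tr <- study$truth
  jsonlite::write_json(list(
    h2_true = as.list(tr$h2_true),
    effects = lapply(tr$effects, function(e)
      list(marker = e$marker, coef = e$coef)),
    hotspots = tr$hotspots, epistasis = tr$epistasis,
    seed = tr$seed), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read genotype tables written by [write_study()]
#'
#' @param dir directory holding genotypes.tsv and marker_map.tsv.
#' @param impute impute missing genotypes to the column mean?  Off by
#'   default (the segregant panels this targets are fully genotyped);
#'   intended for exploratory use only.
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes <- function(dir, impute = FALSE) {
  gv <- data.table::fread(file.path(dir, "genotypes.tsv"))
  seg <- gv$segregant
  X <- as.matrix(gv[, -1])
  rownames(X) <- seg
  if (anyNA(X)) {
    if (!impute) stop("missing genotypes (set impute = TRUE to mean-impute)")
    warning("mean-imputing missing genotypes")
    for (j in which(colSums(is.na(X)) > 0))
      X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
  }
  map <- data.table::fread(file.path(dir, "marker_map.tsv"))
  structure(list(values = X, map = map, ld_groups = NULL),
            class = "genotype_matrix")
}

#' Read an expression matrix written by [write_study()]
#' @param dir directory holding expression.tsv (+ gene_annotation.tsv).
#' @return an \code{expression_matrix}.
#' @export
read_expression <- function(dir) {
  ev <- data.table::fread(file.path(dir, "expression.tsv"))
  seg <- ev$segregant
  X <- as.matrix(ev[, -1])
  rownames(X) <- seg
  ann_path <- file.path(dir, "gene_annotation.tsv")
  ann <- if (file.exists(ann_path)) data.table::fread(ann_path) else NULL
  structure(list(values = X, annotation = ann), class = "expression_matrix")
}

#' Read a gene annotation from BED-like TSV or GFF3
#'
#' TSV must have columns gene, chrom, start, end, strand (1-based, closed
#' intervals).  For GFF3 only rows with type "gene" are used and the gene
#' id is taken from the ID= attribute.
#'
#' @param path file path.
#' @return data.table(gene, chrom, start, end, strand).
#' @export
read_annotation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##gff", first) || grepl("\tgene\t", paste(readLines(path, n = 50), collapse = "\n"))) {
    gff <- data.table::fread(path, skip = "#", header = FALSE,
                             col.names = c("chrom", "source", "type", "start",
                                           "end", "score", "strand", "phase", "attr"))
    gff <- gff[gff$type == "gene", ]
    gene <- sub(";.*", "", sub("^.*ID=", "", gff$attr))
    return(data.table::data.table(gene = gene, chrom = gff$chrom,
                                  start = gff$start, end = gff$end,
                                  strand = gff$strand))
  }
  data.table::fread(path, select = c("gene", "chrom", "start", "end", "strand"))
}
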