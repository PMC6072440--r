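#' Standard yeast chromosome scaffold
#'
#' Sixteen chromosomes with physical lengths matching the S. cerevisiae
#' reference and genetic lengths derived from a uniform recombination density
#' of 0.38 cM/kb (~46 Morgans genome-wide, typical for a yeast cross).
#'
#' @param cm_per_kb recombination density used to convert bp to Morgans.
#' @return data.frame with columns \code{name}, \code{length_bp},
#'   \code{morgans}.
#' @export
yeast_chromosomes <- function(cm_per_kb = 0.38) {
  len <- c(230218L, 813184L, 316620L, 1531933L, 576874L, 270161L,
           1090940L, 562643L, 439888L, 745751L, 666816L, 1078177L,
           924431L, 784333L, 1091291L, 948066L)
  nm <- paste0("chr", c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                        "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI"))
  data.frame(name = nm, length_bp = len,
             morgans = len * cm_per_kb / 1e5,
             stringsAsFactors = FALSE)
}

#' Describe a two-parent haploid cross design
#'
#' @param n_segregants number of haploid segregants (>= 2).
#' @param chromosomes data.frame with columns \code{name}, \code{length_bp},
#'   \code{morgans} (see [yeast_chromosomes()]).
#' @param n_markers total marker count, allocated to chromosomes in
#'   proportion to physical length (>= 2 per chromosome).  Ignored when
#'   \code{marker_positions} is given.
#' @param marker_positions optional named list of strictly increasing 1-based
#'   bp positions per chromosome.
#' @param seed integer seed recorded in the design; all randomness in
#'   [simulate_cross()] flows from it.
#' @return object of class \code{cross_design}.
#' @export
cross_design <- function(n_segregants = 1000, chromosomes = yeast_chromosomes(),
                         n_markers = 2000, marker_positions = NULL, seed = 1L) {
  stopifnot(n_segregants >= 2, all(chromosomes$morgans >= 0),
            all(chromosomes$length_bp > 0))
  if (is.null(marker_positions)) {
    prop <- chromosomes$length_bp / sum(chromosomes$length_bp)
    k <- pmax(2L, round(prop * n_markers))
    set.seed(seed)
    marker_positions <- lapply(seq_len(nrow(chromosomes)), function(i) {
      sort(sample.int(chromosomes$length_bp[i], k[i]))
    })
    names(marker_positions) <- chromosomes$name
  }
  for (cn in names(marker_positions)) {
    p <- marker_positions[[cn]]
    if (length(p) < 1 || any(diff(p) <= 0))
      stop("invalid design: marker positions must be strictly increasing on ", cn)
  }
  structure(list(n_segregants = as.integer(n_segregants),
                 chromosomes = chromosomes,
                 marker_positions = marker_positions,
                 seed = as.integer(seed)),
            class = "cross_design")
}

#' Simulate segregant genotypes for a cross design
#'
#' Each segregant chromosome is a mosaic of parental blocks: the crossover
#' count per chromosome is Poisson with mean equal to its genetic length in
#' Morgans and crossover locations are uniform on the genetic map (Haldane
#' model, no interference).  Marker genetic positions are linear in bp.
#' Alleles are coded BY = -1, RM = +1.
#'
#' @param design a [cross_design()].
#' @return object of class \code{genotype_matrix}: list with \code{values}
#'   (segregants x markers in -1/+1), \code{map} (data.table: marker, chrom,
#'   pos), and \code{ld_groups} (NULL until [collapse_perfect_ld()]).
#' @export
simulate_cross <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  set.seed(design$seed)
  n <- design$n_segregants
  chroms <- design$chromosomes
  blocks <- vector("list", nrow(chroms))
  maps <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    cn <- chroms$name[i]
    pos <- design$marker_positions[[cn]]
    k <- length(pos)
    gl <- chroms$morgans[i]
    # marker positions on the genetic map (Morgans), linear in bp
    gpos <- gl * pos / chroms$length_bp[i]
    X <- matrix(0L, n, k)
    ncx <- rpois(n, gl)
    start <- sample(c(-1L, 1L), n, replace = TRUE)
    for (s in seq_len(n)) {
      if (ncx[s] == 0L) {
        X[s, ] <- start[s]
      } else {
        cuts <- sort(runif(ncx[s], 0, gl))
        X[s, ] <- start[s] * ifelse(findInterval(gpos, cuts) %% 2L == 0L, 1L, -1L)
      }
    }
    colnames(X) <- paste0(cn, "_", pos)
    blocks[[i]] <- X
    maps[[i]] <- data.table::data.table(marker = colnames(X), chrom = cn, pos = pos)
  }
  values <- do.call(cbind, blocks)
  rownames(values) <- sprintf("seg_%04d", seq_len(n))
  structure(list(values = values,
                 map = data.table::rbindlist(maps),
                 ld_groups = NULL),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "segregants x", ncol(x$values),
      "markers on", length(unique(x$map$chrom)), "chromosomes\n")
  if (!is.null(x$ld_groups))
    cat("  perfect-LD collapsed;", length(x$ld_groups), "groups\n")
  invisible(x)
}

# marker column indices for one chromosome
marker_index <- function(geno, chromosome) {
  which(geno$map$chrom == chromosome)
}
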