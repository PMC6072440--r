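# Shared fixtures, built once per test run.  All sizes are deliberately
# small; statistical assertions use tolerances stated in the module
# contracts, never tuned to a particular draw.

.fix <- new.env()

# a small multi-chromosome synthetic study with the generator defaults
fix_study <- function() {
  if (is.null(.fix$study))
    .fix$study <- simulate_study(n_segregants = 300, n_markers = 300,
                                 n_genes = 60, seed = 101)
  .fix$study
}

# a single-chromosome cross for hotspot-style tests
fix_one_chrom <- function(n = 300, n_markers = 100, morgans = 4, seed = 11) {
  des <- cross_design(n, chromosomes = data.frame(
    name = "chrI", length_bp = 1000000L, morgans = morgans),
    n_markers = n_markers, seed = seed)
  simulate_cross(des)
}

# plant a hotspot: `frac`-strength effects of marker `hs` on `ng` traits
plant_hotspot <- function(X, hs, ng, b_range = c(0.15, 0.35), seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  b <- runif(ng, b_range[1], b_range[2]) * sample(c(-1, 1), ng, TRUE)
  P <- X[, hs] %*% t(b) + matrix(rnorm(n * ng), n, ng)
  colnames(P) <- sprintf("t%03d", seq_len(ng))
  list(P = P, b = b)
}

# trans score matrix straight from a trait block (scaled SVD scores)
scores_from <- function(P, m) {
  sv <- svd(scale(P), nu = m, nv = 0)
  sv$u %*% diag(sv$d[seq_len(m)], m)
}

# random +/-1 marker vector
rmarker <- function(n) sample(c(-1, 1), n, replace = TRUE)
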