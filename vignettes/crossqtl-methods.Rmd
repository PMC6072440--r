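---
title: "crossqtl: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossqtl: models, synthetic worlds and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, what the synthetic-data generator does
and does not emulate, and the choices made where the design was
genuinely open.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The design being analysed

A panel of haploid segregants from a biallelic two-parent cross, each
genotyped at a dense marker map and phenotyped by RNA-seq
(log2(TPM + 0.5)).  Genotypes are coded −1 for the first parent (BY)
and +1 for the second (RM), so a positive effect always means higher
expression with the RM allele.  Because segregants are haploids from a
single meiosis layer, allele frequencies are ~0.5 everywhere, linkage
decays with genetic distance, and markers never separated by
recombination are *perfectly* correlated — the package collapses those
to one representative (leftmost by position) and re-expands confidence
intervals over group members afterwards.

## Heritability

Per gene, after OLS removal of batch and growth covariates (a two-stage
procedure, not a joint fit — matching standard practice in these
panels), the model is `y = a + e`, `a ~ N(0, σ²_A A)`,
`e ~ N(0, σ²_E I)`.  The kinship `A = Gc Gc'/c` uses column-centred
genotypes with `c` set so the mean diagonal is 1, which makes σ²_A a
variance on the phenotype scale and h² = σ²_A/(σ²_A+σ²_E) well defined.
The fit is REML (the estimation lineage this follows defaults to REML;
ML would change h² by O(1/n)) via one spectral decomposition of A that
is shared across genes; the variance ratio is profiled on a log-spaced
grid and refined by bounded 1-D optimization (tolerance 1e-6).  The
two-component model adds `i ~ N(0, σ²_AA (A∘A))`, where the Hadamard
square is the natural kernel for additive×additive pairs, and is
maximized by Nelder–Mead over the variance-fraction simplex from five
starts — slower but robust for a 2-D bounded problem.

## Additive eQTL mapping

Mapping on a chromosome must not be confounded by genetic signal from
the rest of the genome.  Two complementary corrections are used:

* a **background screen**: three rounds of coarse genome scans on
  covariate-corrected expression; any per-chromosome max-LOD marker
  with LOD > 3.5 joins a per-gene set Z (≤3 per chromosome per gene);
* a **LOCO polygenic term**: when mapping chromosome c, each gene is
  residualized with a mixed model whose kinship excludes c's markers
  and whose fixed effects are the covariates plus the off-chromosome
  members of Z; the returned residual subtracts the fixed-effect fit
  and the BLUP `A_L(A_L + δI)⁻¹(y − Xβ)`, retaining on-chromosome
  signal.

The forward scan then repeats per chromosome: scan all active genes
(`LOD = −n·ln(1−r²)/(2 ln 10)`, algebraically identical to the
regression form `(n/2)log10(RSS₀/RSS₁)`), take each gene's max-LOD
marker, and test the round with the permutation-grid FDR: one segregant
permutation per run shared across genes (inter-gene correlation is
preserved, so the null counts inherit the real co-expression
structure), 1000 runs, and the threshold is the smallest grid value
(1.5–9 by 0.05) at which expected/observed < 5%.  Accepted genes are
residualized on their new peak ("replace R with e") and rescanned;
genes without a significant peak leave the chromosome.  We keep the
paper-style sequential residualization rather than refitting all peaks
jointly at each step; a joint refit is used afterwards for reporting
effect sizes (e.g. in `hotspot_targets` and cross-validation).  Ties at
the max are broken to the leftmost marker for determinism, and each
chromosome's result depends only on that chromosome's setup, so
processing order cannot change results.

A threshold grid value where *no* gene is observed above it cannot
produce detections; `fdr_threshold` therefore requires at least one
observed exceedance, which also makes a fully null study return "no
detections" rather than a vacuous threshold.

Confidence intervals are 1.5-LOD drops (smallest contiguous interval
whose exterior neighbours fall below peak−1.5), LD-extended.  An eQTL is
*local* when its CI overlaps the gene expanded 1000 bp upstream and
200 bp downstream (strand-aware, closed intervals); among several local
eQTLs of one gene the closest peak is flagged primary.  Held-out
variance explained in cross-validation is the squared correlation
between predicted and observed expression (1−SSE/SST is a switchable
alternative; the two differ only by calibration of the prediction
scale, and squared correlation is the more conservative, scale-free
choice).

## Hotspots (jQTLs)

Trans-eQTLs concentrate at hotspot loci affecting many genes; mapping
them jointly across genes sharpens localization.  The steps:

1. **Residual factors**: per gene with ≥1 eQTL, remove covariates,
   eQTL fixed effects and the genome-wide polygenic BLUP; SVD of the
   scaled residual matrix; retain up to 20 left-singular vectors whose
   singular values beat a column-permutation null.  One permuted copy
   gives a ~50% false-retention rate under the null (the top observed
   and permuted singular values are exchangeable draws), so the cutoff
   is the max over 19 permuted copies (~5% false retention).
2. **Trans matrix L** per chromosome: genes with a significant linkage
   to the chromosome that do not reside on it, residualized (OLS, as
   printed — no polygenic term at this stage) on covariates, factors
   and off-chromosome peaks; SVD; components beating the same
   permutation rule are kept as scores (left-singular vectors ×
   singular values; unscaled eigenvectors are a switch).
3. **Scan**: the multivariate LOD `(n/2)log10(|RSS₀|/|RSS|)` is
   computed for every marker via the rank-one determinant identity
   `det(RSS₀ − uu') = det(RSS₀)(1 − u'RSS₀⁻¹u)`, which makes the scan
   O(m²·markers) instead of O(m³·markers) and reduces exactly to the
   univariate formula at m = 1.  Iterative peak subtraction continues
   while the max exceeds the 99% quantile of 100 permutation maxima
   (rows of L permuted jointly).
4. **Refinement**: each peak is dropped from the joint model and its
   chromosome rescanned with the other peaks as covariates; peaks
   moving > 75 kb are spurious by-products of flanking loci and are
   removed.
5. **Ghost test** (peaks with LOD > 200): the best two-locus model with
   both loci outside ±10 markers of the peak is compared with the best
   one-locus model; the peak is replaced when the observed difference
   exceeds the 99% permutation quantile by more than 10 LOD.  The
   phenomenon requires close linkage — two unlinked hotspots simply
   form two peaks.
6. **Bootstrap CI**: 1000 segregant resamples, refitting with the other
   peaks as covariates and recording the argmax in an 80-marker window;
   the central 95% of bootstrap peak positions, LD-extended.  Hotspots
   peaking within 5 kb of the chromosome's mapped ends are flagged
   subtelomeric.

Target genes per hotspot come from a targeted forward scan restricted
to the hotspot markers plus one local candidate per gene, under the
same 5%-FDR machinery, with signed coefficients from a final joint
regression.

## Epistasis

Marker pairs are tested on residuals that already exclude covariates,
detected additive eQTLs and the polygenic BLUP.  The pair statistic is
the LOD of the *product term over the marginal model* (both nested
models contain both marginal effects) — the source analyses do not
print their statistic, and this choice guarantees purely additive
signal cannot masquerade as interaction.  The marker set is pruned at
|r| > 0.99 (greedy worst-pair elimination); same-chromosome pairs
within 20 collapsed-marker indices are excluded, and 2D peaks are
extracted greedily with the same ±20 radius (the extraction rule is
unprinted in the source; symmetry with the exclusion radius is the
natural choice).  FDR uses 5 permutations at 10% for the full scan and
10 permutations for the additive-pair F-tests — few permutations
suffice because each permutation contributes an entire genome×genome
scan of null pairs.

## Allele-specific expression

In an F1 hybrid both alleles share one nucleus, so allelic imbalance
isolates cis-acting variation.  Counts are balanced between parental
genomes by multivariate hypergeometric downsampling, genes with < 20
reads are dropped, and imbalance is tested with an exact two-sided
binomial test against 0.5, Bonferroni-corrected.  Overdispersion uses a
beta-binomial parameterized by (p, ρ) with α = p(1−ρ)/ρ,
β = (1−p)(1−ρ)/ρ — variance n·p(1−p)(1+(n−1)ρ), exactly binomial at
ρ = 0 — maximized over ρ with p fixed at 0.5.  Power simulations draw
1000 beta-binomial datasets per (coverage, fold-change) cell.  Genes
with one zero count get a 0.5 pseudo-count for fold changes and are
flagged (the source's handling is unstated).  Effect-size comparisons
use SMA regression, the symmetric line fit appropriate when both axes
carry error.

## The synthetic world

`simulate_cross` draws crossovers as Poisson with the chromosome's
genetic length and uniform locations (Haldane: no interference — the
analyses only consume observed genotypes, so interference would change
nothing downstream), on 16 chromosomes with real yeast physical lengths
and 0.38 cM/kb.  `simulate_truth`/`plant_expression` state the
generator's world once:

* ~Poisson(6) eQTLs per gene, capped at 21; effect variances from a
  symmetric Dirichlet(0.8) split — median per-eQTL effect ~2% of
  variance;
* per-gene heritability Beta-distributed with mean 0.26 (capped 0.95);
  20% of genetic variance is polygenic background drawn on the kinship;
* a local eQTL for 75% of genes (placed at the marker nearest the
  gene); other eQTLs hit one of 8 hotspot markers with probability 0.5
  (hotspot target fractions 5–40%), else a uniform marker;
* 13 round-robin batches with N(0, 0.3²) shifts, a growth covariate
  affecting 30% of genes, 5% of genes carrying one epistatic pair at
  2.2% of variance, ASE overdispersion ρ = 0.005;
* noise is scaled per gene so the realized genetic-variance fraction
  equals the target h² exactly (the truth ledger stores both).

What it does **not** emulate: read-level count noise (phenotypes are
Gaussian on the log scale, so heritability attenuation from shallow
sequencing is out of scope), genotyping error, segregation distortion,
crossover interference, and structural variation.  A green recovery
test therefore establishes that the algorithms work under the stated
statistical structure, not that they are robust to artifacts upstream
of the genotype/expression matrices.

## Numerical choices and degenerate inputs

* Zero-variance markers scan as LOD 0 with a warning; rank-deficient
  covariate designs drop aliased columns with a warning; missing
  genotypes are rejected (the design is fully genotyped).
* REML is profiled over δ = σ²_E/σ²_A on a 41-point log grid
  (1e-6–1e6) with golden-section refinement; h² is reported as
  1/(1+δ̂).  Non-PSD kinships beyond −1e-8·n are errors.
* The interaction scan's closed-form Gram algebra exploits x² = 1 for
  ±1 genotypes; catastrophic cancellation for near-perfect
  interactions is floored at RSS·1e-12.
* Permutation seeds derive from one explicit seed; every simulation
  output records its seed.  All tie-breaks (max LOD, marker removal)
  go to the leftmost index.

## Known limitations

* The forward scan re-derives its permutation threshold each round;
  with very few active genes the threshold estimate is noisy and the
  procedure conservative (it stops).
* The greedy |r|-pruning and the 2D max-and-mask peak extraction are
  deterministic reimplementations of unprinted procedures; other
  reasonable conventions would shift marginal peaks slightly.
* Two-component REML uses dense Cholesky per evaluation (O(n³));
  practical to n of a few thousand, not beyond.
* The CLI accepts JSON configuration (no YAML parser is available in
  the supported dependency set).
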