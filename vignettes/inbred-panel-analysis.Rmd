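---
title: "Population structure and diversity analysis of inbred SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure and diversity analysis of inbred SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inbredpanel)
```

## The problem

Elite maize breeding germplasm is organized into heterotic groups — breeding
pools (Stiff Stalk, Non-Stiff Stalk, Iodent) whose between-pool hybrids show
heterosis. Genotyping-by-sequencing (GBS) panels of inbred lines make that
population structure measurable, but the raw call sets are awkward: two
platforms rarely type the same sites, missingness runs to 40% and is biased
toward lines distant from the reference genome, and inbreds still show a
trickle of heterozygous and third-allele calls that are mostly genotyping
error. This package implements the complete analysis stack such a panel
needs, end to end:

1. **Merge** two partially overlapping marker sets with full accounting.
2. **QC**: convert het/tertiary calls to missing, then drop sites by
   missingness and minor allele frequency (MAF).
3. **Impute** the remaining gaps with a forward-only Markov chain, and
   estimate accuracy by masking known calls.
4. **LD**: pairwise $r^2$ within chromosomes and smoothed decay curves.
5. **Structure**: PCA, Nei's genetic distance, Ward clustering, tree
   cutting, Newick export.
6. **Diversity**: per-locus Weir–Cockerham $\theta$ ($F_{ST}$), balanced
   unrelated subsampling, moving-window scans, top regions, candidate-gene
   queries.

A synthetic-panel generator with known ground truth turns each stage into a
quantitative parameter-recovery test, so the whole pipeline is exercised
without any external download.

## Models and estimators

### Genotype coding

Inbred lines are expected homozygous, so after QC each call is haploid-coded:
0 (major/reference allele), 2 (minor/alternate), or missing. Pre-QC matrices
additionally carry heterozygous (1) and tertiary (3) states so the QC
conversions are auditable. Sites are keyed by (chromosome, position),
1-based, with closed intervals throughout; BED export converts to 0-based
half-open on disk.

### QC rules and their order

The fixed order is: het → missing, tertiary → missing, then drop sites with
missing fraction above `site_missing_max` (default 0.172), then drop sites
with MAF below `maf_min` (default 0.05), with MAF and missingness recomputed
*after* the conversions. Running the conversions first is the only order
under which the site filters see the data they will actually ship, and it is
what makes the per-inbred missingness cap an emergent consequence rather
than a filter — the 30% per-individual figure is checked and reported, never
filtered on. The alternative (raw-call MAF) is available behind
`recompute_maf_after_conversion = FALSE`.

### Forward Markov imputation

The model is a first-order chain along each chromosome over states
$\{0, 2\}$: per-site marginal frequencies plus one $2 \times 2$ transition
table per adjacent site pair, estimated from lines non-missing at both sites
and smoothed with pseudocount 0.5. Decoding is deterministic greedy forward
argmax: scanning left to right, a missing call before the line's first
*observed* call on that chromosome takes the site-marginal argmax (an
all-missing line therefore receives per-site marginals); after an observed
anchor, each missing call takes the argmax of the transition row conditioned
on the most recent observed-or-imputed state. Ties break toward the major
allele, so imputation is fully reproducible without a seed. Forward-only
argmax (rather than forward–backward posterior decoding or sampling) is the
minimal model consistent with a single left-to-right pass, and it makes
accuracy estimation exactly repeatable.

Accuracy is estimated by the masked-data protocol: mask a fraction of cells
of a complete matrix (default 6.22%), refit the model *on the masked data*
(refitting on the truth would be optimistic — the real use case never sees
it), impute, score the masked cells, repeat (default 100 reps).

### LD

$r^2$ is the squared Pearson correlation of the two sites' haploid-coded
call vectors, which for homozygous lines equals the classical
haplotype-count $D^2 / (p_A p_a p_B p_b)$ — a test verifies the equivalence
by brute force. Pairs are computed within chromosomes only. Decay curves are
Nadaraya–Watson Gaussian-kernel regressions of $r^2$ on $\log_{10}$
distance (the natural axis for LD decay), evaluated per chromosome and
pooled; the pooled curve is a convex combination of the per-chromosome
estimates, so it always lies inside their envelope. The bandwidth defaults
to Silverman's rule on the pooled log-distances (floored at 0.05 to survive
degenerate distance sets); the reported summary $d_{0.2}$ is the first grid
distance at which the smoothed curve reaches 0.2. Pair counts are capped
(`max_pairs`, seeded uniform subsample, flagged in the output) because all
pairwise combinations grow quadratically.

### Nei distance and Ward clustering

Nei's standard genetic distance between lines $X$ and $Y$ is
$D = -\ln \left( J_{XY} / \sqrt{J_X J_Y} \right)$ with $J$ the mean
over loci of allele-frequency products; for a homozygous inbred the
per-locus "frequencies" are 0 or 1, so $J_X = J_Y = 1$ and $J_{XY}$ is the
fraction of matching loci. The square root over $J_X J_Y$ follows Nei's
(1972) definition. Mean-over-loci normalization makes $D$ invariant to
duplicating loci. Pairs sharing no allele anywhere have infinite distance
and are flagged; they must be resolved before clustering.

Ward clustering uses `stats::hclust`. The default dialect is the historical
`ward.D` — the Lance–Williams recurrence with Ward coefficients applied
directly to the supplied dissimilarities — because that is what classic
hclust-based pipelines feeding a (non-Euclidean) Nei matrix ran; `ward.D2`
is available by flag and the choice is recorded on the tree object. Tests
check the merge heights against an independent naive $O(n^3)$ re-scan
implementation. Tree cutting removes the $k - 1$ highest merges
(`stats::cutree`), with group numbers assigned by first appearance in leaf
order. The eigenvalue-elbow report of the PCA (largest second difference of
the scree profile) is advisory only: the number of groups is always the
analyst's decision, informed by PCA plots and prior knowledge.

Newick export writes branch lengths as parent height minus child height, so
leaf-to-leaf path lengths equal twice the cophenetic height; labels with
spaces or metacharacters are single-quoted. Round-trips through
`ape::read.tree` are tested.

### Weir–Cockerham $F_{ST}$, haploid form

Because QC removes heterozygotes and the lines are inbred, the diploid
a/b/c decomposition degenerates; the haploid form is the standard choice.
Per locus with $r$ groups, group sizes $n_i$ (non-missing lines) and
minor-allele frequencies $p_i$:

$$\bar p = \frac{\sum n_i p_i}{\sum n_i}, \qquad
n_c = \frac{\sum n_i - \sum n_i^2 / \sum n_i}{r - 1},$$

$$MSP = \frac{\sum n_i (p_i - \bar p)^2}{r - 1}, \qquad
MSG = \frac{\sum n_i p_i (1 - p_i)}{\sum (n_i - 1)},$$

$$\theta = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG}.$$

A locus needs at least two non-missing calls per group; loci monomorphic
across all groups are flagged undefined and excluded from the overall
summary. Two overall summaries are provided and the output names which was
used: the **simple average** of defined per-locus $\theta$ (the
conventional report for these panels, and the default) and the
**ratio-of-sums** $\sum (MSP - MSG) / \sum (MSP + (n_c - 1) MSG)$. They
differ systematically: per-locus $\theta$ is a ratio with a noisy
2-degree-of-freedom numerator when $r = 3$, and averaging such ratios is
biased downward. On Balding–Nichols panels simulated at $F = 0.15$ with
3 × 44 lines and 10,000 loci the simple average lands near 0.130 while the
ratio-of-sums recovers 0.148–0.150; parameter-recovery checks therefore use
the ratio form, while the simple average remains the default for
descriptive reporting. (This bias is also a plausible reason why two
different printed summaries of the same real comparison can disagree.)

Before estimation, the panel is reduced to a **balanced, maximally
unrelated** subsample: within each group, the closest pair is found and the
member with the smaller average distance to the rest removed (ties broken
lexicographically), repeating until the target count remains — so exact
duplicates are always eliminated first, and the removal roster is emitted
for audit. The target defaults to the size of the smallest group. The
procedure is deterministic; it is a greedy heuristic, not an exhaustive
max-min search, which is the price of auditability at panel scale.

Genome scans average $\theta$ over sliding windows of 70 consecutive
defined loci per chromosome (windows never span chromosome boundaries).
Top regions are formed by visiting windows in decreasing mean order and
merging any window that overlaps an already-formed region on the same
chromosome into it (union of spans; the region keeps the maximum window
mean); region size is last-marker minus first-marker position. The
candidate-gene query returns genes whose 1-based closed interval intersects
the closed window $[pos - 10\,000,\ pos + 10\,000]$ around each
high-$\theta$ SNP, with distance 0 inside the gene and the gap to the
nearer end otherwise.

## The synthetic panel generator

`simulate_panel()` emulates a structured inbred GBS panel at the
genotype-matrix level (sequencing reads, selection and real genetic maps
are out of scope):

* **Divergence.** Ancestral frequencies $p \sim U(0.1, 0.9)$; per-group
  frequencies from the Balding–Nichols
  $\mathrm{Beta}\!\left(p\frac{1-F}{F},\ (1-p)\frac{1-F}{F}\right)$
  distribution, so the expected $F_{ST}$ of the panel *is* the
  `divergence_F` parameter — this is what makes estimator recovery a
  quantitative acceptance surface.
* **Pedigree.** Founder haplotypes are independent Bernoulli draws from the
  group frequencies; descendant lines are made by crossing two same-group
  parents, recombining (Poisson crossover count per chromosome, default 2,
  uniform breakpoints — the simplest model that yields distance-decaying
  LD), and collapsing one gamete to a homozygous line, for
  `recycle_generations` rounds. Parent choice is geometrically biased
  (`elite_weight`, default 0.3) toward a few lines, emulating how
  commercial programs recycle key inbreds; uneven founder contribution
  skews within-group frequencies away from 50/50 and concentrates long
  shared haplotypes, which is what makes the default panel LD-rich. With
  `recycle_generations = 0` every line is an independent frequency draw —
  the configuration the recovery tests use, because drift during recycling
  legitimately pushes realized differentiation above the nominal $F$.
* **Missingness.** Per-individual rates
  $\mathcal N(0.0622, 0.03)$ plus `ref_bias_weight` (default 0.1) times the
  line's allele-sharing distance to a designated reference line, clamped to
  $[0, 0.95]$ — missingness is lower for reference-like lines, as
  reference-aligned GBS data show. Heterozygous (0.25%) and tertiary
  (0.1%) calls are injected uniformly at random; they exist to exercise the
  QC rules, nothing else.
* **Platforms.** The site union is split so that 17.2% of sites are shared
  and the rest divided privately between two platforms; individuals
  alternate between platforms. Merging the two platform matrices therefore
  reproduces the characteristic accounting of a two-source panel
  compilation (high missingness at platform-private sites).

Desk-scale defaults: 3 groups × 30 lines, 4 founders per group, 3 recycling
generations, 10 chromosomes × 500 sites over 200 Mb each,
$F = 0.15$, seed 1. These sizes keep every stage of the workflow and the
test suite in seconds-to-minutes on one CPU while leaving each statistical
signal (divergence, relatedness, LD, reference bias) comfortably
detectable; the recovery checks that need more loci (e.g. $\theta$ within
±0.02 of $F$) simulate 10,000 loci explicitly.

A second, single-purpose generator, `simulate_ld_panel()`, produces a
haplotype-copying panel whose true $r^2(d) = e^{-2d/\lambda}$ crosses 0.2
at exactly a designed distance (default 1 kbp, giving
$\lambda = 2000/\ln 5$); it calibrates the decay-curve estimator, whose
estimated crossing should land within roughly [0.6, 1.7] kbp at 5,000
pairs.

**What passing these tests does not show.** The generator draws site
frequencies independently (no ancestral haplotype sharing between groups),
injects genotyping error uniformly rather than depth-dependently, uses a
uniform recombination map, and has no selection. Recovery on this panel
demonstrates that the estimators are implemented correctly under their own
assumptions — not that any particular real panel satisfies those
assumptions.

## Numerical choices and degenerate inputs

* Ties in imputation argmax break toward the major allele (state 0);
  chromosomes with one site carry marginals only.
* All-missing sites get an undefined-MAF flag rather than an error; a
  filter configuration that removes every site raises a named error.
* Merge conflicts (same chromosome and position, different allele pair) are
  dropped and counted, never guessed.
* PCA of a constant matrix returns zero eigenvalues with a degenerate flag;
  percent-variance entries otherwise sum to 100 within $10^{-6}$.
* Identical individuals get Nei distance exactly 0 (numeric fuzz is
  clipped); disjoint-allele pairs get `Inf` and a flag.
* Report percentages round half away from zero at the printed precision,
  matching conventional summary-table style.
* `mask_genotypes()` masks exactly `round(fraction × non-missing cells)`
  cells and errors when that count is zero.

## Workflow layout

The `analysis/` directory holds six numbered drivers
(`01_simulate.R` … `06_diversity.R`) that run the whole study on the
synthetic panel and write tables under `results/`; each is a thin narrative
wrapper over the package functions, which is where all computation lives.
`run_pipeline()` offers the same chain as a single call with a manifest of
artifact checksums. The desk-scale driver panel keeps only ~600 of 5,000
sites after QC (platform-private sites are missing for half the panel, as
in any two-source merge), so `06_diversity.R` scales the moving-average
window to the surviving marker density instead of using the full-scale
70-SNP default.

## Known limitations

* The forward-only chain cannot use information to the right of a missing
  run; accuracy is bounded by adjacent-pair LD and is several points below
  what a forward–backward decoder could reach on the same panel.
* The greedy unrelated-subsample selection does not maximize the minimum
  within-group distance globally.
* `pairwise_r2` enumerates pairs per chromosome before subsampling, which
  is quadratic in sites-per-chromosome; it is intended for post-QC panels
  (thousands of sites per chromosome), not raw call sets.
* Region coalescing reports the seeding window's mean for a merged region;
  a span-weighted mean would differ.
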