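# inbredpanel

Population-structure and diversity analysis for panels of inbred
(expected-homozygous) lines genotyped at biallelic SNPs — the analysis
stack used to characterize maize heterotic groups from
genotyping-by-sequencing (GBS) data.

GBS call sets for inbred panels arrive as two or more platforms with
partially overlapping site sets, 40%+ missingness biased toward lines
distant from the reference genome, and residual heterozygous/third-allele
calls. This package takes such data from raw platform files to population
genetics results:

* **genotype I/O and merging** — HapMap-dialect and VCF 4.2 read/write, and
  a site-union merge of two platforms with full accounting (sites, common
  sites, missingness, heterozygosity per input and merged);
* **QC** — het/tertiary calls converted to missing, then site filters on
  missingness and minor allele frequency, with reports that recompute from
  the shipped matrix;
* **imputation** — a forward-only Markov chain over haploid-coded states
  {0, 2} (per-site marginals + adjacent-pair transition tables, greedy
  forward argmax decoding) with a masked-data accuracy protocol;
* **LD** — within-chromosome pairwise r², Gaussian-kernel decay curves on a
  log-distance axis, and the distance at which smoothed r² crosses 0.2;
* **structure** — PCA, Nei's standard genetic distance
  D = −ln(J_XY / √(J_X·J_Y)), Ward clustering (ward.D dialect by default),
  tree cutting into k groups, Newick export;
* **diversity** — per-locus Weir–Cockerham θ (haploid ANOVA form:
  θ = (MSP − MSG) / (MSP + (n_c − 1)·MSG)), balanced maximally-unrelated
  subsampling, 70-SNP moving-average genome scans, top differentiated
  regions, and ±10 kbp candidate-gene queries;
* **simulation** — a structured-panel generator (Balding–Nichols group
  divergence, elite-biased cross-and-self pedigrees, reference-biased
  missingness, two-platform split) whose ground truth makes every stage a
  parameter-recovery test.

## Worked example

```r
library(inbredpanel)

panel <- simulate_panel(sim_config(seed = 1))   # two platforms + truth
m <- merge_panels(panel$platform1, panel$platform2)
f <- apply_filters(m$gm, filter_config())       # MAF >= 0.05, missing <= 17.2%
gm <- impute_forward(f$gm, fit_markov(f$gm))

dm   <- nei_distance(gm)
tree <- ward_cluster(dm)
groups <- cut_tree(tree, 3)
table(groups, panel$truth$group_label[names(groups)])
#>       G1 G2 G3
#>     1 30  0  0
#>     2  0 30  0
#>     3  0  0 30

acc <- estimate_accuracy(panel$truth$complete, fraction = 0.0622,
                         reps = 100, seed = 1)
acc$mean_accuracy
#> [1] 0.8055527
```

The three simulated heterotic groups are recovered exactly by the k = 3 cut
of the Ward tree on the Nei distance matrix, and masked-data imputation
accuracy on the default LD-rich panel is ≈ 0.81 against a major-allele
baseline of ≈ 0.77.

The `analysis/` directory runs the same study as six numbered scripts
(`01_simulate.R` … `06_diversity.R`), writing tables under `results/`;
`run_pipeline(run_config(...))` performs the whole chain in one call and
emits a checksummed artifact manifest. See the vignette
(`vignettes/inbred-panel-analysis.Rmd`) for the models, estimator choices,
and the generator's design.

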