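#!/usr/bin/env Rscript
# Simulate the study panel: three diverged heterotic groups of inbred lines
# genotyped on two partially overlapping marker platforms, with structured
# missingness and residual het/tertiary calls. Writes the two platform VCFs
# and the ground truth used by later steps.

library(inbredpanel)

out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1)   # the package defaults are the study conditions
panel <- simulate_panel(cfg)

write_vcf(panel$platform1, file.path(out, "platform1.vcf"))
write_vcf(panel$platform2, file.path(out, "platform2.vcf"))
write.table(data.frame(individual = names(panel$truth$group_label),
                       group = panel$truth$group_label),
            file.path(out, "truth_groups.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_vcf(panel$truth$complete, file.path(out, "truth_complete.vcf"))

cat(sprintf(
  "Simulated %d lines in %d groups, %d sites on %d chromosomes.\n",
  nrow(panel$truth$complete$calls), cfg$n_groups,
  ncol(panel$truth$complete$calls), cfg$n_chrom))
k1 <- paste(panel$platform1$sites$chrom, panel$platform1$sites$pos)
k2 <- paste(panel$platform2$sites$chrom, panel$platform2$sites$pos)
cat(sprintf("Platforms: %d and %d sites, %d shared (%.1f%% of the union).\n",
            length(k1), length(k2), length(intersect(k1, k2)),
            100 * length(intersect(k1, k2)) / length(union(k1, k2))))
cat(sprintf("Observed missingness: %.2f%% (reference-biased by design).\n",
            100 * mean(is.na(panel$truth$observed$calls))))
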