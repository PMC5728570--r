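test_that("the simulator is deterministic and its truth is internally consistent", {
  cfg <- sim_config(n_chrom = 2, sites_per_chrom = 80, lines_per_group = 8,
                    seed = 42)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$platform1$calls, b$platform1$calls)
  expect_identical(a$platform2$calls, b$platform2$calls)
  expect_identical(a$truth$complete$calls, b$truth$complete$calls)

  truth <- a$truth
  expect_true(is_complete(truth$complete))
  expect_setequal(names(truth$group_label), individuals(truth$complete))
  expect_equal(sort(unique(truth$group_label)), c("G1", "G2", "G3"))
  # platforms partition the individuals
  expect_length(intersect(individuals(a$platform1), individuals(a$platform2)), 0)
  expect_setequal(c(individuals(a$platform1), individuals(a$platform2)),
                  individuals(truth$complete))
})

test_that("platform site overlap matches the configured fraction", {
  cfg <- sim_config(seed = 3)  # default: 5000 sites, overlap 0.172
  panel <- simulate_panel(cfg)
  k1 <- paste(panel$platform1$sites$chrom, panel$platform1$sites$pos)
  k2 <- paste(panel$platform2$sites$chrom, panel$platform2$sites$pos)
  shared <- length(intersect(k1, k2))
  union_n <- length(union(k1, k2))
  expect_lt(abs(shared / union_n - 0.172), 0.01)
})

test_that("degenerate simulator configs are rejected", {
  expect_error(sim_config(lines_per_group = 1, recycle_generations = 2),
               "lines_per_group")
  expect_error(sim_config(n_founders_per_group = 1, recycle_generations = 1),
               "n_founders_per_group")
  expect_error(sim_config(divergence_F = 1), "divergence_F")
  expect_error(sim_config(platform_overlap = 0), "platform_overlap")
})

test_that("theta on undiverged panels is near zero and recovers the simulated F", {
  cfg0 <- sim_config(lines_per_group = 30, recycle_generations = 0,
                     n_chrom = 10, sites_per_chrom = 1000, divergence_F = 0,
                     miss_rate_mean = 0, miss_rate_sd = 0,
                     ref_bias_weight = 0, het_rate = 0, tertiary_rate = 0,
                     seed = 3)
  p0 <- simulate_panel(cfg0)
  f0 <- fst_weir_cockerham(p0$truth$complete, p0$truth$group_label)
  expect_lt(abs(f0$overall), 0.01)

  cfg15 <- sim_config(lines_per_group = 44, recycle_generations = 0,
                      n_chrom = 10, sites_per_chrom = 1000,
                      divergence_F = 0.15, miss_rate_mean = 0,
                      miss_rate_sd = 0, ref_bias_weight = 0, het_rate = 0,
                      tertiary_rate = 0, seed = 7)
  p15 <- simulate_panel(cfg15)
  f15 <- fst_weir_cockerham(p15$truth$complete, p15$truth$group_label,
                            overall = "ratio")
  expect_lt(abs(f15$overall - 0.15), 0.02)
})

test_that("estimated theta increases with the simulated divergence F", {
  thetas <- vapply(c(0, 0.05, 0.15, 0.30), function(f) {
    cfg <- sim_config(lines_per_group = 30, recycle_generations = 0,
                      n_chrom = 4, sites_per_chrom = 500, divergence_F = f,
                      miss_rate_mean = 0, miss_rate_sd = 0,
                      ref_bias_weight = 0, het_rate = 0, tertiary_rate = 0,
                      seed = 11)
    p <- simulate_panel(cfg)
    fst_weir_cockerham(p$truth$complete, p$truth$group_label,
                       overall = "ratio")$overall
  }, 0)
  expect_true(all(diff(thetas) > 0))
})

test_that("lines sharing a parent are closer than random same-group pairs", {
  cfg <- sim_config(n_chrom = 4, sites_per_chrom = 400, lines_per_group = 20,
                    seed = 9)
  panel <- simulate_panel(cfg)
  truth <- panel$truth
  dm <- nei_distance(truth$complete)
  final <- truth$pedigree[truth$pedigree$generation ==
                            max(truth$pedigree$generation), ]
  final <- final[final$child %in% rownames(dm), ]
  sib_d <- c(); other_d <- c()
  for (g in unique(truth$group_label)) {
    kids <- final[final$child %in%
                    names(truth$group_label)[truth$group_label == g], ]
    for (i in seq_len(nrow(kids) - 1)) {
      for (j in seq(i + 1, nrow(kids))) {
        share <- length(intersect(unlist(kids[i, c("parent1", "parent2")]),
                                  unlist(kids[j, c("parent1", "parent2")])))
        d <- dm[kids$child[i], kids$child[j]]
        if (share > 0) sib_d <- c(sib_d, d) else other_d <- c(other_d, d)
      }
    }
  }
  expect_gt(length(sib_d), 5)
  expect_lt(median(sib_d), median(other_d))
})

test_that("adjacent sites show more LD than distant sites", {
  cfg <- sim_config(n_chrom = 4, sites_per_chrom = 300, seed = 13,
                    miss_rate_mean = 0, miss_rate_sd = 0, ref_bias_weight = 0,
                    het_rate = 0, tertiary_rate = 0)
  panel <- simulate_panel(cfg)
  gm <- panel$truth$complete
  lp <- pairwise_r2(gm, max_pairs = 5e4, seed = 1)
  near <- lp$pairs$r2[lp$pairs$dist < cfg$chrom_length_bp / 50]
  far <- lp$pairs$r2[lp$pairs$dist > cfg$chrom_length_bp / 2]
  expect_gt(length(near), 50)
  expect_gt(length(far), 50)
  expect_gt(mean(near), mean(far))
})

test_that("missingness correlates with distance to the reference line", {
  cfg <- sim_config(n_chrom = 4, sites_per_chrom = 400, lines_per_group = 20,
                    miss_rate_mean = 0.05, miss_rate_sd = 0.005,
                    ref_bias_weight = 0.3, seed = 21)
  panel <- simulate_panel(cfg)
  obs_miss <- rowMeans(is.na(panel$truth$observed$calls))
  d <- panel$truth$dist_to_ref[names(obs_miss)]
  expect_gt(cor(obs_miss, d, method = "spearman"), 0)
})

test_that("mask_genotypes masks the exact cell count and restores exactly", {
  gm <- make_gm(matrix(rep(c(0L, 2L), 50), 10, 10))
  m <- mask_genotypes(gm, 0.0622, seed = 4)
  expect_equal(nrow(m$mask), 6)  # round(0.0622 * 100)
  expect_equal(sum(is.na(m$gm$calls)), 6)
  restored <- m$gm
  restored$calls[m$mask] <- m$values
  expect_identical(restored$calls, gm$calls)

  expect_error(mask_genotypes(gm, 0.001, seed = 1), "nothing to mask")
  all_na <- make_gm(matrix(NA_integer_, 3, 3))
  expect_error(mask_genotypes(all_na, 0.5, seed = 1), "no non-missing")
  expect_error(mask_genotypes(gm, 1.2, seed = 1), "fraction")
})

test_that("the copying-model LD panel decays at its designed length scale", {
  gm <- simulate_ld_panel(n_lines = 300, n_sites = 200, seed = 8)
  lam <- attr(gm, "lambda_bp")
  # adjacent-pair empirical r^2 should track exp(-2d/lambda)
  pos <- gm$sites$pos
  x <- gm$calls
  r2 <- vapply(seq_len(ncol(x) - 1), function(j) {
    suppressWarnings(stats::cor(x[, j], x[, j + 1])^2)
  }, 0)
  d <- diff(pos)
  keep <- !is.na(r2) & d < lam
  expect_gt(cor(r2[keep], exp(-2 * d[keep] / lam)), 0.5)
})
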