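test_that("theta equals one at fixation and near zero without differentiation", {
  # 2 groups of 4, opposite fixed alleles: MSP = 2, MSG = 0, theta = 1
  calls <- rbind(matrix(2L, 4, 1), matrix(0L, 4, 1))
  rownames(calls) <- paste0("L", 1:8)
  gm <- make_gm(calls)
  labels <- rep(c("P1", "P2"), each = 4)
  names(labels) <- rownames(calls)
  fst <- fst_weir_cockerham(gm, labels)
  expect_equal(fst$loci$msp, 2)
  expect_equal(fst$loci$msg, 0)
  expect_equal(fst$loci$n_c, 4)
  expect_equal(fst$loci$theta, 1)
  expect_equal(fst$overall, 1)

  set.seed(14)
  calls <- matrix(2L * rbinom(200 * 50, 1, rep(runif(50, 0.2, 0.8),
                                               each = 200)), 200, 50)
  rownames(calls) <- paste0("L", 1:200)
  labels <- stats::setNames(rep(c("A", "B"), each = 100), rownames(calls))
  fst <- fst_weir_cockerham(make_gm(calls), labels)
  expect_lt(abs(fst$overall), 0.05)
})

test_that("per-locus theta matches a scalar oracle and ignores allele labels", {
  set.seed(26)
  calls <- matrix(sample(c(0L, 2L, NA), 30 * 40, TRUE,
                         prob = c(0.45, 0.45, 0.1)), 30, 40)
  rownames(calls) <- paste0("L", 1:30)
  labels <- stats::setNames(sample(c("A", "B", "C"), 30, TRUE),
                            rownames(calls))
  gm <- make_gm(calls)
  fst <- fst_weir_cockerham(gm, labels)
  oracle <- vapply(seq_len(ncol(calls)),
                   function(j) wc_theta_oracle(calls[, j], labels), 0)
  expect_equal(fst$loci$theta, oracle, tolerance = 1e-12)

  flip <- sample(40, 15)
  calls2 <- calls
  calls2[, flip] <- 2L - calls2[, flip]
  fst2 <- fst_weir_cockerham(make_gm(calls2), labels)
  expect_equal(fst2$loci$theta, fst$loci$theta, tolerance = 1e-12)
  expect_true(all(fst$loci$theta[fst$loci$defined] >= -1 &
                    fst$loci$theta[fst$loci$defined] <= 1))
})

test_that("monomorphic loci are flagged undefined and excluded from the mean", {
  calls <- cbind(rep(0L, 8), c(rep(2L, 4), rep(0L, 4)))
  rownames(calls) <- paste0("L", 1:8)
  labels <- stats::setNames(rep(c("A", "B"), each = 4), rownames(calls))
  fst <- fst_weir_cockerham(make_gm(calls), labels)
  expect_false(fst$loci$defined[1])
  expect_true(fst$loci$defined[2])
  expect_equal(fst$overall, fst$loci$theta[2])
  expect_error(fst_weir_cockerham(make_gm(calls), rep("A", 8)), "2 groups")
})

test_that("balanced-unrelated selection removes duplicates first and is deterministic", {
  set.seed(44)
  calls <- matrix(2L * rbinom(9 * 60, 1, 0.5), 9, 60)
  calls[2, ] <- calls[1, ]  # exact duplicate pair in group A
  rownames(calls) <- c(paste0("A", 1:5), paste0("B", 1:4))
  labels <- stats::setNames(rep(c("A", "B"), c(5, 4)), rownames(calls))
  dm <- nei_distance(make_gm(calls))
  sel <- select_balanced_unrelated(dm, labels, 4)
  expect_length(sel$keep, 8)
  # exactly one of the duplicate pair survives
  expect_equal(sum(c("A1", "A2") %in% sel$keep), 1)
  expect_equal(sel$roster$closest_pair_dist[1], 0)
  # identity when target equals group size
  sel2 <- select_balanced_unrelated(dm, labels, 4)
  expect_identical(sel$keep, sel2$keep)
  expect_setequal(sel$keep[startsWith(sel$keep, "B")], paste0("B", 1:4))
  expect_error(select_balanced_unrelated(dm, labels, 5), "group B")
})

test_that("the smallest group can drive the balanced target", {
  set.seed(45)
  calls <- matrix(2L * rbinom(18 * 80, 1, 0.5), 18, 80)
  rownames(calls) <- sprintf("L%02d", 1:18)
  labels <- stats::setNames(rep(c("A", "B", "C"), c(5, 6, 7)),
                            rownames(calls))
  dm <- nei_distance(make_gm(calls))
  target <- min(table(labels))
  sel <- select_balanced_unrelated(dm, labels, target)
  expect_equal(as.vector(table(labels[sel$keep])), rep(5L, 3))
})

test_that("window scans average consecutive loci and respect chromosomes", {
  fst <- structure(list(loci = data.frame(
    chrom = c("1", "1", "1", "2", "2"),
    pos = c(100, 200, 300, 100, 200),
    theta = c(0.1, 0.2, 0.6, 0.3, 0.3),
    defined = TRUE
  )), class = "fst_result")
  scan <- fst_window_scan(fst, window_snps = 3)
  expect_equal(nrow(scan$windows), 1)       # chrom 2 too short
  expect_equal(scan$windows$mean_theta, 0.3)
  expect_equal(scan$windows$start_pos, 100)
  expect_equal(scan$windows$end_pos, 300)
  expect_equal(scan$skipped, "2")

  const <- structure(list(loci = data.frame(
    chrom = "1", pos = 1:10 * 100, theta = 0.25, defined = TRUE
  )), class = "fst_result")
  sc <- fst_window_scan(const, window_snps = 4)
  expect_true(all(abs(sc$windows$mean_theta - 0.25) < 1e-12))
  expect_equal(nrow(sc$windows), 7)
})

test_that("top regions coalesce overlapping windows and size by marker span", {
  scan <- structure(list(windows = data.frame(
    chrom = c("1", "1", "1", "2"),
    start_pos = c(100, 150, 400, 50),
    end_pos = c(200, 260, 500, 80),
    mean_theta = c(0.5, 0.45, 0.3, 0.4)
  ), window_snps = 3, skipped = character(0)), class = "fst_scan")
  regions <- top_regions(scan, 3)
  expect_equal(nrow(regions), 3)
  # windows 1 and 2 overlap -> one region spanning their union at max mean
  expect_equal(regions$first_marker[1], 100)
  expect_equal(regions$last_marker[1], 260)
  expect_equal(regions$mean_theta[1], 0.5)
  expect_equal(regions$region_size, regions$last_marker - regions$first_marker)

  # equal-mean non-overlapping windows order deterministically by position
  tie <- structure(list(windows = data.frame(
    chrom = c("2", "1"), start_pos = c(10, 10), end_pos = c(20, 20),
    mean_theta = c(0.4, 0.4)
  ), window_snps = 3, skipped = character(0)), class = "fst_scan")
  r2 <- top_regions(tie, 2)
  expect_equal(r2$chrom, c("1", "2"))
  expect_warning(top_regions(tie, 5), "available")
})

test_that("candidate gene search honors the closed 10 kb boundary", {
  fst <- structure(list(loci = data.frame(
    chrom = "2", pos = 50000, theta = 0.8, defined = TRUE
  )), class = "fst_result")
  ann <- data.frame(
    chrom = "2",
    start = c(49000, 30000, 25000, 70000),
    end = c(51000, 40000, 39999, 75000),
    gene_id = c("inside", "at_boundary", "past_boundary", "right_far"),
    description = NA_character_
  )
  hits <- candidate_genes(fst, ann, half_window = 10000, theta_min = 0.6)
  expect_setequal(hits$gene_id, c("inside", "at_boundary"))
  expect_equal(hits$distance_bp[hits$gene_id == "inside"], 0)
  expect_equal(hits$distance_bp[hits$gene_id == "at_boundary"], 10000)

  ann$chrom <- c("2", "2", "2", "99")
  expect_warning(candidate_genes(fst, ann, theta_min = 0.6), "skipped")
})

test_that("regions convert to BED's 0-based half-open intervals", {
  regions <- data.frame(chrom = "7", first_marker = 101, last_marker = 200,
                        region_size = 99, mean_theta = 0.5)
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(regions, path)
  bed <- utils::read.table(path)
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 200)
})

test_that("GFF3 gene annotations load through the standard reader", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste("2", "src", "gene", "49000", "51000", ".", "+", ".",
          "ID=GRMZM2G000001;description=test gene", sep = "\t"),
    paste("2", "src", "exon", "49100", "49500", ".", "+", ".",
          "Parent=GRMZM2G000001", sep = "\t")
  ), path)
  ann <- read_gene_table(path)
  expect_equal(nrow(ann), 1)
  expect_equal(ann$gene_id, "GRMZM2G000001")
  expect_equal(ann$start, 49000)
})
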