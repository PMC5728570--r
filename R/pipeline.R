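# End-to-end orchestration: simulate (or read) a two-platform panel,
# merge, QC, impute, then the three downstream analyses (LD decay,
# structure, F_ST scan). Every stage writes its artifacts under one output
# directory and the run ends with a manifest of files, stage parameters,
# seeds and content checksums; identical configs reproduce identical
# checksums.

#' Pipeline run configuration
#'
#' @param out_dir output directory.
#' @param seed master seed; stage seeds derive from it.
#' @param sim arguments for [sim_config()] (used when no input files are
#'   given).
#' @param input1,input2 optional paths to two platform files (HapMap
#'   `.hmp.txt` or VCF); when set, simulation is skipped.
#' @param stages character vector of stages to run, a subset of
#'   `c("sim", "merge", "qc", "impute", "ld", "structure", "fst")` in
#'   dependency order.
#' @param filter arguments for [filter_config()].
#' @param ld_params list: `max_dist`, `max_pairs`.
#' @param k number of groups to cut the tree into.
#' @param fst_params list: `window_snps`, `n_regions`, `target_per_group`
#'   (NULL = size of the smallest group), `theta_min`, `annotation`
#'   (optional gene-table path).
#' @param report_digits decimal places for report percentages.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       sim = list(),
                       input1 = NULL, input2 = NULL,
                       stages = c("sim", "merge", "qc", "impute", "ld",
                                  "structure", "fst"),
                       filter = list(),
                       ld_params = list(max_dist = Inf, max_pairs = 2e5),
                       k = 3,
                       fst_params = list(window_snps = 70, n_regions = 4,
                                         target_per_group = NULL,
                                         theta_min = 0.6,
                                         annotation = NULL),
                       report_digits = 2) {
  known <- c("sim", "merge", "qc", "impute", "ld", "structure", "fst")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input1 = input1, input2 = input2,
                 stages = intersect(known, stages), filter = filter,
                 ld_params = ld_params, k = k, fst_params = fst_params,
                 report_digits = report_digits),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns a manifest
#' listing every artifact with its stage, seed and md5 checksum. A
#' downstream stage whose input still contains missing calls (e.g. `ld`
#' requested while `impute` is disabled) stops with an error naming the
#' unmet dependency.
#'
#' @param config a [run_config()].
#' @return data.frame manifest (also written to `manifest.tsv`), with one
#'   row per artifact: `file`, `stage`, `seed`, `md5`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  note <- function(file, stage) {
    artifacts[[length(artifacts) + 1]] <<- data.frame(
      file = basename(file), stage = stage, seed = config$seed,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE
    )
  }
  p <- function(...) file.path(config$out_dir, ...)
  stages <- config$stages
  truth <- NULL
  gm1 <- gm2 <- NULL

  if ("sim" %in% stages) {
    sim_args <- config$sim
    sim_args$seed <- config$seed
    panel <- simulate_panel(do.call(sim_config, sim_args))
    gm1 <- panel$platform1
    gm2 <- panel$platform2
    truth <- panel$truth
    write_vcf(gm1, p("platform1.vcf")); note(p("platform1.vcf"), "sim")
    write_vcf(gm2, p("platform2.vcf")); note(p("platform2.vcf"), "sim")
    utils::write.table(
      data.frame(individual = names(truth$group_label),
                 group = truth$group_label),
      p("truth_groups.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    note(p("truth_groups.tsv"), "sim")
  } else if (!is.null(config$input1)) {
    read1 <- if (grepl("\\.vcf(\\.gz)?$", config$input1)) read_vcf
             else read_hapmap
    gm1 <- read1(config$input1)
    if (!is.null(config$input2)) {
      read2 <- if (grepl("\\.vcf(\\.gz)?$", config$input2)) read_vcf
               else read_hapmap
      gm2 <- read2(config$input2)
    }
  } else if (length(intersect(stages, c("merge", "qc", "impute", "ld",
                                        "structure", "fst"))) > 0) {
    stop("no input: enable the 'sim' stage or provide `input1`")
  }

  gm <- gm1
  if ("merge" %in% stages) {
    if (is.null(gm2)) stop("merge stage needs two inputs")
    m <- merge_panels(gm1, gm2)
    gm <- m$gm
    write_merge_report(m$report, p("merge_report.tsv"))
    note(p("merge_report.tsv"), "merge")
  }

  if ("qc" %in% stages) {
    f <- apply_filters(gm, do.call(filter_config, config$filter))
    gm <- f$gm
    write_filter_report(f$report, p("qc_report.tsv"))
    note(p("qc_report.tsv"), "qc")
    write_vcf(gm, p("filtered.vcf")); note(p("filtered.vcf"), "qc")
  }

  if ("impute" %in% stages) {
    model <- fit_markov(gm)
    gm <- impute_forward(gm, model)
    write_vcf(gm, p("imputed.vcf")); note(p("imputed.vcf"), "impute")
  }

  downstream <- intersect(stages, c("ld", "structure", "fst"))
  if (length(downstream) > 0 && !is_complete(gm)) {
    stop("stage(s) ", paste(downstream, collapse = ", "),
         " require a fully imputed matrix but missing calls remain; ",
         "enable the 'impute' stage")
  }

  if ("ld" %in% stages) {
    lp <- pairwise_r2(gm, max_dist = config$ld_params$max_dist,
                      max_pairs = config$ld_params$max_pairs,
                      seed = config$seed)
    dc <- decay_curve(lp)
    write_ld_tables(lp, dc, p("ld"))
    note(p("ld", "ld_pairs.tsv"), "ld")
    note(p("ld", "ld_decay.tsv"), "ld")
  }

  groups <- NULL
  dm <- NULL
  if ("structure" %in% stages || "fst" %in% stages) {
    dm <- nei_distance(gm)
  }
  if ("structure" %in% stages) {
    pca <- pca_genotypes(gm)
    scores <- data.frame(individual = rownames(pca$scores),
                         pca$scores[, seq_len(min(10, ncol(pca$scores))),
                                    drop = FALSE])
    utils::write.table(scores, p("pca_scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(p("pca_scores.tsv"), "structure")
    utils::write.table(
      data.frame(component = seq_along(pca$eigenvalues),
                 eigenvalue = pca$eigenvalues, pct_var = pca$pct_var),
      p("pca_eigenvalues.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    note(p("pca_eigenvalues.tsv"), "structure")
    tree <- ward_cluster(dm)
    write_newick(tree, p("tree.nwk")); note(p("tree.nwk"), "structure")
    groups <- cut_tree(tree, config$k)
    utils::write.table(
      data.frame(individual = names(groups), group = groups),
      p("groups.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    note(p("groups.tsv"), "structure")
  }

  if ("fst" %in% stages) {
    if (is.null(groups)) {
      stop("fst stage needs group labels; enable the 'structure' stage")
    }
    fp <- config$fst_params
    target <- fp$target_per_group
    if (is.null(target)) target <- min(table(groups))
    sel <- select_balanced_unrelated(dm, groups, target)
    utils::write.table(sel$roster, p("fst_removed_roster.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(p("fst_removed_roster.tsv"), "fst")
    sub <- gm[sel$keep, ]
    fst <- fst_weir_cockerham(sub, groups[sel$keep])
    utils::write.table(fst$loci, p("fst_loci.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(p("fst_loci.tsv"), "fst")
    scan <- fst_window_scan(fst, fp$window_snps)
    regions <- top_regions(scan, fp$n_regions)
    utils::write.table(regions, p("fst_regions.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    note(p("fst_regions.tsv"), "fst")
    write_regions_bed(regions, p("fst_regions.bed"))
    note(p("fst_regions.bed"), "fst")
    if (!is.null(fp$annotation)) {
      ann <- read_gene_table(fp$annotation)
      hits <- candidate_genes(fst, ann, theta_min = fp$theta_min)
      utils::write.table(hits, p("candidate_genes.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      note(p("candidate_genes.tsv"), "fst")
    }
  }

  manifest <- do.call(rbind, artifacts)
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
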