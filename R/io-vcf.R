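# VCF 4.2 read/write. Reading goes through vcfR; writing emits a minimal
# sites-only VCF with GT fields. Diploid GT codes on disk map to the
# haploid-coded internal calls: 0/0 = major, 1/1 = minor, 0/1 = het, any
# allele index >= 2 = tertiary, ./. = missing.

#' Write a genotype matrix as VCF 4.2
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  has_ter <- apply(gm$calls == 3L, 2, any, na.rm = TRUE)
  alt_field <- ifelse(has_ter, paste(s$alt, third_base(s$ref, s$alt), sep = ","),
                      s$alt)
  gt_of <- function(j) {
    calls <- gm$calls[, j]
    out <- rep("./.", length(calls))
    out[!is.na(calls) & calls == 0L] <- "0/0"
    out[!is.na(calls) & calls == 2L] <- "1/1"
    out[!is.na(calls) & calls == 1L] <- "0/1"
    out[!is.na(calls) & calls == 3L] <- "2/2"
    out
  }
  geno <- vapply(seq_len(ncol(gm$calls)), gt_of, character(nrow(gm$calls)))
  if (nrow(gm$calls) == 1) geno <- matrix(geno, nrow = 1)
  geno <- t(geno)
  body <- cbind(s$chrom, s$pos, sprintf("S%s_%d", s$chrom, s$pos),
                s$ref, alt_field, ".", "PASS", ".", "GT", geno)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=inbredpanel",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$calls)), collapse = "\t"),
    apply(body, 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF file into a genotype matrix
#'
#' Uses vcfR for parsing. Only the GT field is consulted; records with a
#' single ALT allele are biallelic, and genotypes referencing a third or
#' higher allele on multi-allelic records load as tertiary calls.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt1 <- vapply(strsplit(fix[, "ALT"], ",", fixed = TRUE), `[`, "", 1)
  ref <- fix[, "REF"]
  if (any(nchar(ref) != 1 | nchar(alt1) != 1) ||
      !all(c(ref, alt1) %in% c("A", "C", "G", "T"))) {
    bad <- which(nchar(ref) != 1 | nchar(alt1) != 1 |
                   !(ref %in% c("A", "C", "G", "T")) |
                   !(alt1 %in% c("A", "C", "G", "T")))[1]
    stop("record ", bad, ": non-ACGT SNP alleles (REF=", ref[bad],
         ", ALT=", fix[bad, "ALT"], ")")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  code_gt <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    out[g %in% c("0/0", "0")] <- 0L
    out[g %in% c("1/1", "1")] <- 2L
    out[g %in% c("0/1", "1/0")] <- 1L
    ter <- !is.na(g) & grepl("^[0-9]+(/[0-9]+)?$", g) & is.na(out) &
      vapply(strsplit(g, "/", fixed = TRUE),
             function(a) any(suppressWarnings(as.integer(a)) >= 2), NA)
    out[which(ter)] <- 3L
    out
  }
  calls <- t(matrix(code_gt(as.vector(gt)), nrow = nrow(gt), ncol = ncol(gt)))
  rownames(calls) <- colnames(gt)
  genotype_matrix(calls, data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt1, stringsAsFactors = FALSE
  ))
}
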