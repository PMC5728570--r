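# HapMap tab-separated genotype format (the dialect emitted by GBS
# pipelines such as TASSEL): 11 metadata columns then one single-letter
# IUPAC call column per individual, N = missing. No installed R package
# reads this dialect, so the parser lives here.

HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")

IUPAC_HET <- c("AC" = "M", "AG" = "R", "AT" = "W",
               "CG" = "S", "CT" = "Y", "GT" = "K")

het_code <- function(ref, alt) {
  key <- paste0(pmin(ref, alt), pmax(ref, alt))
  unname(IUPAC_HET[key])
}

third_base <- function(ref, alt) {
  vapply(seq_along(ref),
         function(i) setdiff(c("A", "C", "G", "T"), c(ref[i], alt[i]))[1],
         "")
}

#' Write a genotype matrix as HapMap-format text
#'
#' Homozygous calls are written as the allele base, heterozygotes as the
#' IUPAC ambiguity code of the site's allele pair, missing as `N`, and
#' tertiary calls as a base outside the site's allele pair.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  het <- het_code(s$ref, s$alt)
  ter <- third_base(s$ref, s$alt)
  code_to_letter <- function(j) {
    calls <- gm$calls[, j]
    out <- rep("N", length(calls))
    out[!is.na(calls) & calls == 0L] <- s$ref[j]
    out[!is.na(calls) & calls == 2L] <- s$alt[j]
    out[!is.na(calls) & calls == 1L] <- het[j]
    out[!is.na(calls) & calls == 3L] <- ter[j]
    out
  }
  geno <- vapply(seq_len(ncol(gm$calls)), code_to_letter,
                 character(nrow(gm$calls)))
  if (nrow(gm$calls) == 1) geno <- matrix(geno, nrow = 1)
  geno <- t(geno)  # sites x individuals
  meta <- cbind(
    sprintf("S%s_%d", s$chrom, s$pos),
    paste(s$ref, s$alt, sep = "/"),
    s$chrom, s$pos, "+", "NA", "NA", "NA", "NA", "NA", "NA"
  )
  header <- c(HAPMAP_COLS, rownames(gm$calls))
  lines <- c(
    paste(header, collapse = "\t"),
    apply(cbind(meta, geno), 1, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a HapMap-format genotype file
#'
#' @param path file path.
#' @return a [genotype_matrix()]. Calls matching neither the site's allele
#'   pair nor its heterozygous IUPAC code are loaded as tertiary; `N` is
#'   missing. Malformed lines raise an error naming the line number.
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 12 || header[1] != "rs#") {
    stop("line 1: malformed HapMap header (expected 'rs#' and >= 1 ",
         "individual column)")
  }
  inds <- header[-seq_len(11)]
  n_site <- length(lines) - 1
  calls <- matrix(NA_integer_, length(inds), n_site,
                  dimnames = list(inds, NULL))
  chrom <- character(n_site); pos <- integer(n_site)
  ref <- character(n_site); alt <- character(n_site)
  for (k in seq_len(n_site)) {
    fields <- strsplit(lines[k + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop("line ", k + 1, ": expected ", length(header), " fields, got ",
           length(fields))
    }
    alleles <- strsplit(fields[2], "/", fixed = TRUE)[[1]]
    if (length(alleles) != 2 || !all(alleles %in% c("A", "C", "G", "T"))) {
      stop("line ", k + 1, ": non-ACGT or non-biallelic alleles field '",
           fields[2], "'")
    }
    chrom[k] <- fields[3]
    pos[k] <- as.integer(fields[4])
    ref[k] <- alleles[1]; alt[k] <- alleles[2]
    g <- fields[-seq_len(11)]
    code <- rep(3L, length(g))          # default: tertiary
    code[g == alleles[1]] <- 0L
    code[g == alleles[2]] <- 2L
    code[g == het_code(alleles[1], alleles[2])] <- 1L
    code[g == "N"] <- NA_integer_
    calls[, k] <- code
  }
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    stop("duplicate site (chromosome, position): ",
         key[anyDuplicated(key)][1])
  }
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
}
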