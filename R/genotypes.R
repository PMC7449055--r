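#' Construct a genotype matrix
#'
#' @param sample_ids character vector of sample names.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (biallelic; multi-nucleotide substitutions such as `AA>GC` allowed).
#' @param dosage samples x markers matrix of alternative-allele counts in
#'   `{0, 1, 2}` (NA for missing).
#' @return a `genotype_matrix` object.
#' @export
genotype_matrix <- function(sample_ids, markers, dosage) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(sample_ids),
            ncol(dosage) == nrow(markers),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers)),
            all(dosage %in% c(0, 1, 2) | is.na(dosage)))
  rownames(dosage) <- sample_ids
  colnames(dosage) <- markers$id
  structure(list(sample_ids = sample_ids,
                 markers = as.data.frame(markers), dosage = dosage),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$markers), "markers;", sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Read genotype dosages from a VCF
#'
#' Dosage is the count of alternative alleles in the GT field; phased and
#' unphased calls are handled alike. Malformed or missing GT values become
#' NA (counted in a message). Multiallelic records are skipped with a
#' warning by default.
#'
#' @param path VCF file (plain or bgzipped).
#' @param region optional `"chrom:start-end"` filter applied after reading.
#' @param skip_multiallelic drop records with >1 ALT allele (default TRUE).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, region = NULL, skip_multiallelic = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(fix))
  multi <- grepl(",", fix$ALT)
  if (any(multi) && skip_multiallelic) {
    warning(sum(multi), " multiallelic record(s) skipped")
    keep <- keep & !multi
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    stopifnot(length(m) == 4)
    pos <- as.integer(fix$POS)
    keep <- keep & fix$CHROM == m[2] & pos >= as.integer(m[3]) &
      pos <= as.integer(m[4])
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  alt_count <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".") || !all(al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  }
  dosage <- t(apply(gt, 1, function(row) vapply(row, alt_count, integer(1))))
  if (nrow(fix) == 1) dosage <- matrix(dosage, nrow = 1)
  n_bad <- sum(is.na(dosage)) - sum(is.na(gt))
  if (n_bad > 0) message(n_bad, " malformed GT value(s) set to missing")
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  genotype_matrix(
    sample_ids = colnames(gt),
    markers = data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT),
    dosage = t(dosage))
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Emits unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`) reconstructed from
#' dosages. The output is a minimal but valid VCF 4.2 file that round-trips
#' through [read_genotypes()].
#'
#' @param gm a [genotype_matrix()].
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  gt_code <- c("0/0", "0/1", "1/1")
  m <- gm$markers
  for (j in seq_len(nrow(m))) {
    d <- gm$dosage[, j]
    g <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    writeLines(paste(c(m$chrom[j], m$pos[j], m$id[j], m$ref[j], m$alt[j],
                       ".", "PASS", ".", "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}
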