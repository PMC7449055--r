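#' Read aligned reads as per-read block tables
#'
#' Converts each alignment record into its set of aligned reference blocks:
#' gaps between blocks are skipped reference (splices). Deletions shorter
#' than `min_intron` never split a block; after block extraction any
#' remaining between-block gap shorter than `min_intron` is merged back into
#' a single block (the conventional aligner minimum intron size).
#'
#' Unmapped reads are never emitted; secondary alignments and duplicates are
#' excluded by default.
#'
#' @param path SAM or BAM file. SAM text is converted to BAM on the fly.
#' @param region optional `"chrom:start-end"` restriction (requires an
#'   index; one is created for the converted/temporary BAM automatically).
#' @param sample_id sample label attached to every read; defaults to the
#'   file name without extension.
#' @param min_intron gaps >= this many bases are kept as splices; shorter
#'   gaps are merged (default 20).
#' @param keep_secondary,keep_duplicates include secondary/duplicate records.
#' @return a `read_blocks` data.frame: one row per aligned block, columns
#'   `sample_id`, `read_id`, `chrom`, `start`, `end` (1-based inclusive),
#'   sorted by read then start.
#' @export
read_alignments <- function(path, region = NULL, sample_id = NULL,
                            min_intron = 20L, keep_secondary = FALSE,
                            keep_duplicates = FALSE) {
  if (is.null(sample_id))
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
  } else {
    bam <- path
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (keep_secondary) NA else FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(flag = flag, what = "qname")
  } else {
    Rsamtools::ScanBamParam(flag = flag, what = "qname",
                            which = GenomicRanges::GRanges(region))
  }
  aln <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = FALSE)
  if (length(aln) == 0)
    return(data.frame(sample_id = character(0), read_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0)))
  blk <- GenomicAlignments::grglist(aln)
  ul <- unlist(blk, use.names = FALSE)
  df <- data.frame(
    sample_id = sample_id,
    read_id = rep(S4Vectors::mcols(aln)$qname, S4Vectors::elementNROWS(blk)),
    chrom = as.character(GenomicRanges::seqnames(ul)),
    start = GenomicRanges::start(ul),
    end = GenomicRanges::end(ul))
  merge_short_gaps(df, min_intron)
}

# Merge consecutive blocks of the same read separated by < min_intron bases.
merge_short_gaps <- function(blocks, min_intron) {
  if (nrow(blocks) == 0) return(blocks)
  blocks <- blocks[order(blocks$sample_id, blocks$read_id, blocks$start), ]
  same <- c(FALSE, blocks$read_id[-1] == blocks$read_id[-nrow(blocks)] &
                   blocks$sample_id[-1] == blocks$sample_id[-nrow(blocks)])
  gap <- c(NA_integer_, blocks$start[-1] - blocks$end[-nrow(blocks)] - 1L)
  absorb <- same & !is.na(gap) & gap < min_intron
  grp <- cumsum(!absorb)
  out <- data.frame(
    sample_id = blocks$sample_id[!absorb],
    read_id = blocks$read_id[!absorb],
    chrom = blocks$chrom[!absorb],
    start = blocks$start[!absorb],
    end = tapply(blocks$end, grp, max)[as.character(unique(grp))])
  rownames(out) <- NULL
  out$end <- as.integer(out$end)
  out
}

#' Write a read-block table as SAM
#'
#' Emits one single-end record per read with a CIGAR built from its blocks
#' (`M` segments separated by `N` gaps). Intended for the synthetic-data
#' generator; the output round-trips through [read_alignments()].
#'
#' @param reads a `read_blocks` data.frame (see [read_alignments()]).
#' @param path output `.sam` path.
#' @param chrom_len named integer vector of reference lengths for the
#'   `@SQ` header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_len) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ch in names(chrom_len))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, as.integer(chrom_len[[ch]])),
               con)
  if (nrow(reads) == 0) return(invisible(path))
  reads <- reads[order(reads$read_id, reads$start), ]
  sp <- split(seq_len(nrow(reads)), reads$read_id)
  ord <- order(vapply(sp, function(i) reads$start[i[1]], numeric(1)))
  recs <- vapply(sp[ord], function(i) {
    st <- reads$start[i]; en <- reads$end[i]
    w <- en - st + 1L
    cig <- paste0(w[1], "M")
    if (length(i) > 1) {
      gaps <- st[-1] - en[-length(i)] - 1L
      cig <- paste0(cig, paste0(gaps, "N", w[-1], "M", collapse = ""))
    }
    seq <- strrep("A", sum(w))
    paste(reads$read_id[i[1]], 0L, reads$chrom[i[1]], st[1], 60L, cig,
          "*", 0L, 0L, seq, "*", sep = "\t")
  }, character(1))
  writeLines(recs, con)
  invisible(path)
}
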