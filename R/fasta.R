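#' Extract a genomic region from a FASTA file
#'
#' @param path FASTA file (may contain several contigs).
#' @param chrom contig name.
#' @param start,end 1-based inclusive bounds; must lie within the contig.
#' @return uppercase sequence string of length `end - start + 1`.
#' @export
read_fasta_region <- function(path, chrom, start, end) {
  if (end < start) stop("end < start")
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!chrom %in% names(seqs)) stop("contig '", chrom, "' not in ", path)
  len <- length(seqs[[chrom]])
  if (start < 1 || end > len)
    stop("region ", start, "-", end, " outside contig '", chrom,
         "' (length ", len, ")")
  toupper(as.character(Biostrings::subseq(seqs[[chrom]], start, end)))
}
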