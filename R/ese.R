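#' Exonic splice enhancer (ESE) hexamer panel
#'
#' @param hexamers character vector of 6-mers over `{A, C, G, T}`;
#'   duplicates are dropped, case is normalised to upper.
#' @return character vector of class `ese_panel`.
#' @export
ese_panel <- function(hexamers) {
  hexamers <- unique(toupper(hexamers))
  if (length(hexamers) && !all(grepl("^[ACGT]{6}$", hexamers)))
    stop("panel members must be 6-mers over A/C/G/T")
  structure(hexamers, class = "ese_panel")
}

#' Read an ESE hexamer panel from a text file
#'
#' One 6-mer per line; blank lines and `#` comments are ignored.
#'
#' @param path panel file.
#' @return an [ese_panel()].
#' @export
read_ese_panel <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ese_panel(lines[nzchar(lines)])
}

#' Scan a sequence for ESE panel hexamers
#'
#' Every window whose 6-mer is a panel member yields one hit; windows
#' containing `N` never match. Scanning is strand-naive on the sequence as
#' given; to scan the other strand, pass its reverse complement explicitly.
#'
#' @param sequence character string over `{A, C, G, T, N}`.
#' @param panel an [ese_panel()].
#' @param genomic_start optional genomic position of the sequence's first
#'   base, used to fill `genomic_start` per hit.
#' @return data.frame of hits sorted by position: `motif`, `start` (1-based
#'   offset in `sequence`), `genomic_start` (NA unless provided).
#' @export
scan_ese <- function(sequence, panel, genomic_start = NA_integer_) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) stop("sequence must be over A/C/G/T/N")
  L <- nchar(sequence)
  empty <- data.frame(motif = character(0), start = integer(0),
                      genomic_start = integer(0))
  if (L < 6 || length(panel) == 0) return(empty)
  starts <- seq_len(L - 5L)
  kmers <- substring(sequence, starts, starts + 5L)
  hit <- kmers %in% unclass(panel)
  data.frame(motif = kmers[hit], start = starts[hit],
             genomic_start = if (is.na(genomic_start))
                               rep(NA_integer_, sum(hit))
                             else genomic_start + starts[hit] - 1L)
}

#' Apply a same-length substitution variant to a sequence
#'
#' @param sequence character string.
#' @param at 1-based offset of the variant's first base in `sequence`.
#' @param ref,alt allele strings of equal length (SNPs and MNPs; indels are
#'   rejected).
#' @return the edited sequence.
#' @export
apply_variant <- function(sequence, at, ref, alt) {
  if (nchar(ref) != nchar(alt) || nchar(ref) < 1)
    stop("only same-length substitution variants are supported")
  obs <- substr(sequence, at, at + nchar(ref) - 1L)
  if (obs != ref)
    stop("reference allele mismatch at offset ", at, ": expected '", ref,
         "', observed '", obs, "'")
  paste0(substr(sequence, 1, at - 1L), alt,
         substr(sequence, at + nchar(ref), nchar(sequence)))
}

#' ESE motifs created or destroyed by a substitution variant
#'
#' Scans both alleles of a sequence and compares the hits whose 6-base
#' window intersects the variant span. Hits present only with the reference
#' allele are `lost`; hits present only with the alternative allele are
#' `gained`. Swapping the alleles swaps the two sets.
#'
#' @param sequence reference-allele sequence.
#' @param at 1-based offset of the variant in `sequence`.
#' @param ref,alt equal-length allele strings.
#' @param panel an [ese_panel()].
#' @param genomic_start optional genomic position of base 1 of `sequence`.
#' @return list with `lost` and `gained` hit data.frames, `n_overlap_ref`
#'   and `n_overlap_alt` (counts of variant-overlapping hits per allele),
#'   and the per-allele full hit tables `hits_ref`, `hits_alt`.
#' @export
variant_motif_delta <- function(sequence, at, ref, alt, panel,
                                genomic_start = NA_integer_) {
  seq_alt <- apply_variant(sequence, at, ref, alt)
  span <- c(at, at + nchar(ref) - 1L)
  overlapping <- function(hits)
    hits[hits$start <= span[2] & hits$start + 5L >= span[1], , drop = FALSE]
  hr <- scan_ese(sequence, panel, genomic_start)
  ha <- scan_ese(seq_alt, panel, genomic_start)
  or_ <- overlapping(hr); oa <- overlapping(ha)
  key <- function(h) paste(h$motif, h$start)
  list(lost = or_[!key(or_) %in% key(oa), , drop = FALSE],
       gained = oa[!key(oa) %in% key(or_), , drop = FALSE],
       n_overlap_ref = nrow(or_), n_overlap_alt = nrow(oa),
       hits_ref = hr, hits_alt = ha)
}
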