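#' Construct a gene model from exon intervals
#'
#' A gene model holds the exon/intron structure of one gene on a named
#' chromosome and strand. Exons are stored sorted by genomic start;
#' overlapping or book-ended exons (e.g. from the union of several
#' transcripts) are merged with a warning. Introns are derived as exactly the
#' gaps between consecutive exons, so `nrow(introns) == nrow(exons) - 1`.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (1-based inclusive).
#' @return an object of class `gene_model`: a list with `gene_id`, `chrom`,
#'   `strand`, `exons`, `introns` and (optionally, see
#'   [add_alternative_donor()]) `alt_donor`.
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"), exons) {
  strand <- match.arg(strand)
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)), nrow(exons) >= 1,
            all(exons$end >= exons$start))
  exons <- exons[order(exons$start, exons$end), c("start", "end"), drop = FALSE]
  merged <- exons[1, , drop = FALSE]
  for (i in seq_len(nrow(exons))[-1]) {
    k <- nrow(merged)
    if (exons$start[i] <= merged$end[k] + 1L) {
      if (exons$start[i] <= merged$end[k])
        warning("overlapping exons merged for gene ", gene_id)
      merged$end[k] <- max(merged$end[k], exons$end[i])
    } else {
      merged <- rbind(merged, exons[i, ])
    }
  }
  rownames(merged) <- NULL
  n <- nrow(merged)
  introns <- if (n > 1) {
    data.frame(start = merged$end[-n] + 1L, end = merged$start[-1] - 1L)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = merged, introns = introns, alt_donor = NULL),
            class = "gene_model")
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "on", x$chrom, paste0("(", x$strand, "):"),
      nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  if (!is.null(x$alt_donor))
    cat("  alternative 5' donor:", x$alt_donor$alt_exon[2], "vs reference",
        x$alt_donor$ref_exon[2], paste0("(", x$alt_donor$removed_bp,
        " bp intronified)"), "\n")
  invisible(x)
}

#' Gene span of a model
#' @param model a [gene_model()].
#' @return integer vector `c(start, end)` covering all exons and introns.
#' @export
gene_span <- function(model) {
  c(min(model$exons$start), max(model$exons$end))
}

#' Splice junction table of a gene model
#'
#' One row per intron, indexed in transcription order (on the minus strand
#' transcription order is the reverse of genomic order, and the donor exon is
#' the higher-coordinate one).
#'
#' @param model a [gene_model()].
#' @return data.frame with columns `index` (1-based intron number in
#'   transcription order), `donor_exon_end`, `acceptor_exon_start` (genomic
#'   positions of the last aligned exon base on the donor side and the first
#'   on the acceptor side), `intron_start`, `intron_end`.
#' @export
junctions <- function(model) {
  introns <- model$introns
  n <- nrow(introns)
  if (n == 0)
    return(data.frame(index = integer(0), donor_exon_end = integer(0),
                      acceptor_exon_start = integer(0),
                      intron_start = integer(0), intron_end = integer(0)))
  if (model$strand == "+") {
    data.frame(index = seq_len(n),
               donor_exon_end = introns$start - 1L,
               acceptor_exon_start = introns$end + 1L,
               intron_start = introns$start, intron_end = introns$end)
  } else {
    data.frame(index = rev(seq_len(n)),
               donor_exon_end = introns$end + 1L,
               acceptor_exon_start = introns$start - 1L,
               intron_start = introns$start, intron_end = introns$end)
  }
}

#' Read a gene model from a GTF/GFF or BED12 file
#'
#' GTF/GFF exon records for `gene_id` are collected and merged across
#' transcripts (exon union, as for a single-transcript reference annotation).
#' BED12 lines are expanded from their block structure; the BED `name` field
#' is matched against `gene_id`.
#'
#' @param path GTF/GFF3 (`.gtf`, `.gff`, `.gff3`) or BED (`.bed`) file.
#' @param gene_id gene (or BED name) to extract.
#' @return a [gene_model()].
#' @export
read_gene_model <- function(path, gene_id) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    gr <- gr[gr$name == gene_id]
    if (length(gr) == 0) stop("gene '", gene_id, "' not found in ", path)
    blocks <- gr$blocks[[1]]
    exons <- data.frame(
      start = GenomicRanges::start(gr)[1] + IRanges::start(blocks) - 1L,
      end = GenomicRanges::start(gr)[1] + IRanges::end(blocks) - 1L)
    chrom <- as.character(GenomicRanges::seqnames(gr))[1]
    strand <- as.character(GenomicRanges::strand(gr))[1]
  } else {
    gr <- rtracklayer::import(path)
    keep <- !is.na(gr$gene_id) & gr$gene_id == gene_id
    if (!is.null(gr$type)) keep <- keep & as.character(gr$type) == "exon"
    gr <- gr[keep]
    if (length(gr) == 0) stop("gene '", gene_id, "' not found in ", path)
    exons <- data.frame(start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr))
    chrom <- as.character(GenomicRanges::seqnames(gr))[1]
    strand <- as.character(GenomicRanges::strand(gr))[1]
  }
  if (!strand %in% c("+", "-")) strand <- "+"
  gene_model(gene_id, chrom, strand, exons)
}

#' Write a gene model to GTF
#'
#' Emits one exon record per exon with `gene_id` and `transcript_id`
#' attributes, so that [read_gene_model()] round-trips the model exactly.
#'
#' @param model a [gene_model()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gtf <- function(model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(model$exons$start, model$exons$end),
    strand = model$strand)
  gr$type <- "exon"
  gr$source <- "junctionqtl"
  gr$gene_id <- model$gene_id
  gr$transcript_id <- paste0(model$gene_id, ".t1")
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Annotate a gene model with an alternative 5' splice donor event
#'
#' Describes an event in which an alternative donor site inside one exon
#' truncates it early, "intronifying" the remainder of the exon
#' (`ref_exon`). The removed span is reported in codons when it is divisible
#' by 3; otherwise a frame-shift flag is set.
#'
#' @param model a [gene_model()].
#' @param alt_exon `c(start, end)` of the exon portion retained by the
#'   alternative form (1-based inclusive).
#' @param ref_exon `c(start, end)` of the exon portion present only in the
#'   reference form (spliced out by the alternative donor).
#' @return the model with an `alt_donor` element: `alt_exon`, `ref_exon`,
#'   `removed_bp`, `removed_codons` (NA if frame-shifting), `frame_shift`,
#'   and `intron_index` of the downstream junction the event shares its
#'   acceptor with.
#' @export
add_alternative_donor <- function(model, alt_exon, ref_exon) {
  stopifnot(length(alt_exon) == 2, length(ref_exon) == 2)
  host <- which(model$exons$start <= min(alt_exon, ref_exon) &
                model$exons$end >= max(alt_exon, ref_exon))
  if (length(host) != 1)
    stop("alt/ref intervals do not fall within a single exon of the model")
  # transcription order: on + the alternative portion is genomically left
  upstream_ok <- if (model$strand == "+") alt_exon[2] < ref_exon[1]
                 else alt_exon[1] > ref_exon[2]
  if (!(upstream_ok || all(alt_exon == ref_exon)))
    stop("alt_exon must end upstream (in transcription order) of ref_exon")
  removed_bp <- if (all(alt_exon == ref_exon)) 0L
                else as.integer(ref_exon[2] - ref_exon[1] + 1L)
  frame_shift <- removed_bp %% 3L != 0L
  jn <- junctions(model)
  # downstream junction in transcription order bordering the host exon
  intron_index <- if (model$strand == "+") {
    i <- which(jn$intron_start == model$exons$end[host] + 1L)
    if (length(i)) jn$index[i] else NA_integer_
  } else {
    i <- which(jn$intron_end == model$exons$start[host] - 1L)
    if (length(i)) jn$index[i] else NA_integer_
  }
  model$alt_donor <- list(
    alt_exon = as.integer(alt_exon), ref_exon = as.integer(ref_exon),
    removed_bp = removed_bp,
    removed_codons = if (frame_shift) NA_integer_ else removed_bp %/% 3L,
    frame_shift = frame_shift, intron_index = intron_index)
  model
}
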