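#' Classify one read at one splice junction
#'
#' A read is **spliced** at a junction when one of its between-block gaps
#' matches the intron interval exactly and the flanking blocks anchor the
#' donor and acceptor exons by at least `min_anchor` bases (it "bridges" the
#' junction). It is **unspliced** when a single block runs across the
#' donor-side exon-intron boundary with at least `min_anchor` aligned bases
#' on each side (from the 3' end of the preceding exon into the intron).
#' Everything else is **other**. On the minus strand the donor boundary is
#' the genomically right one. With `both_boundaries = TRUE` a block crossing
#' the acceptor-side boundary also counts as unspliced.
#'
#' @param blocks data.frame of the read's aligned blocks (`start`, `end`,
#'   1-based inclusive, sorted, non-overlapping).
#' @param junction one row of [junctions()].
#' @param min_anchor minimum aligned bases on each side (default 1).
#' @param strand strand of the gene model (`"+"` or `"-"`).
#' @param both_boundaries also count acceptor-side crossings as unspliced.
#' @return `"spliced"`, `"unspliced"` or `"other"`.
#' @export
classify_read <- function(blocks, junction, min_anchor = 1L, strand = "+",
                          both_boundaries = FALSE) {
  stopifnot(nrow(blocks) >= 1, all(blocks$end >= blocks$start))
  is <- junction$intron_start; ie <- junction$intron_end
  o <- order(blocks$start)
  st <- blocks$start[o]; en <- blocks$end[o]
  n <- length(st)
  if (n > 1) {
    gs <- en[-n] + 1L; ge <- st[-1] - 1L
    wl <- en[-n] - st[-n] + 1L; wr <- en[-1] - st[-1] + 1L
    if (any(gs == is & ge == ie & wl >= min_anchor & wr >= min_anchor))
      return("spliced")
  }
  cross_left <- any(st <= is - min_anchor & en >= is + min_anchor - 1L)
  cross_right <- any(st <= ie - min_anchor + 1L & en >= ie + min_anchor)
  donor_cross <- if (strand == "+") cross_left else cross_right
  acceptor_cross <- if (strand == "+") cross_right else cross_left
  if (donor_cross || (both_boundaries && acceptor_cross)) return("unspliced")
  "other"
}

#' Vectorised classification of many reads at one junction
#'
#' Applies the [classify_read()] rules to every read of a read-block table
#' at once.
#'
#' @param reads a `read_blocks` data.frame (see [read_alignments()]).
#' @inheritParams classify_read
#' @return one row per distinct read: `sample_id`, `read_id`, `class`, and
#'   `neighbourhood` (whether the read overlaps the intron extended by one
#'   base on each side — the reads [count_junctions()] tallies).
#' @export
classify_reads <- function(reads, junction, min_anchor = 1L,
                           strand = "+",
                           both_boundaries = FALSE) {
  key <- paste(reads$sample_id, reads$read_id, sep = "\r")
  o <- order(key, reads$start)
  key <- key[o]; st <- reads$start[o]; en <- reads$end[o]
  n <- length(key)
  first <- !duplicated(key)
  ids <- which(first)
  is <- junction$intron_start; ie <- junction$intron_end

  same <- c(FALSE, key[-1] == key[-n])
  gap_ok <- same & (c(0L, en[-n]) + 1L == is) & (st - 1L == ie) &
    (c(0L, en[-n] - st[-n] + 1L) >= min_anchor) &
    (en - st + 1L >= min_anchor)
  cross_l <- st <= is - min_anchor & en >= is + min_anchor - 1L
  cross_r <- st <= ie - min_anchor + 1L & en >= ie + min_anchor
  donor <- if (strand == "+") cross_l else cross_r
  accept <- if (strand == "+") cross_r else cross_l
  unspl_blk <- donor | (both_boundaries & accept)
  nb <- en >= is - 1L & st <= ie + 1L

  grp <- cumsum(first)
  spliced <- tabulate(grp[gap_ok], nbins = length(ids)) > 0
  unspliced <- tabulate(grp[unspl_blk], nbins = length(ids)) > 0 & !spliced
  neighbour <- tabulate(grp[nb], nbins = length(ids)) > 0
  data.frame(sample_id = reads$sample_id[o][ids],
             read_id = reads$read_id[o][ids],
             class = ifelse(spliced, "spliced",
                            ifelse(unspliced, "unspliced", "other")),
             neighbourhood = neighbour)
}

#' Count spliced/unspliced/other reads at every junction
#'
#' Tallies, per sample and junction, the junction-bridging (spliced) reads,
#' the donor-boundary-crossing (unspliced) reads, and the remaining reads
#' overlapping the junction neighbourhood (the intron extended by one base
#' on each side). A read contributes at most once per junction, but may be
#' counted at several junctions (e.g. a read with two exact splice gaps is
#' spliced at both).
#'
#' @param reads a `read_blocks` data.frame (see [read_alignments()]).
#' @param model a [gene_model()].
#' @inheritParams classify_read
#' @return data.frame with one row per sample x junction: `sample_id`,
#'   `junction` (transcription-order intron index), `n_spliced`,
#'   `n_unspliced`, `n_other`.
#' @export
count_junctions <- function(reads, model, min_anchor = 1L,
                            both_boundaries = FALSE) {
  jn <- junctions(model)
  samples <- unique(reads$sample_id)
  if (nrow(reads) == 0) {
    warning("empty read stream: zero junction count table")
    samples <- character(0)
  }
  if (length(samples) == 0)
    return(data.frame(sample_id = character(0), junction = integer(0),
                      n_spliced = integer(0), n_unspliced = integer(0),
                      n_other = integer(0)))
  out <- vector("list", nrow(jn))
  for (k in seq_len(nrow(jn))) {
    cl <- classify_reads(reads, jn[k, ], min_anchor,
                         model$strand, both_boundaries)
    cl <- cl[cl$neighbourhood, , drop = FALSE]
    tab <- table(factor(cl$sample_id, levels = samples),
                 factor(cl$class, levels = c("spliced", "unspliced", "other")))
    out[[k]] <- data.frame(sample_id = samples,
                           junction = jn$index[k],
                           n_spliced = as.integer(tab[, "spliced"]),
                           n_unspliced = as.integer(tab[, "unspliced"]),
                           n_other = as.integer(tab[, "other"]))
  }
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$junction), , drop = FALSE]
}

#' Splicing-efficiency ratio
#'
#' Ratio of junction-bridging (spliced, "exonic") reads to donor-boundary
#' crossing (unspliced, "intronic") reads at a junction, a read-based proxy
#' for the rate of intron removal. A pseudocount keeps the ratio finite at
#' low depth; with `pseudocount = 0` a zero unspliced count yields NA.
#'
#' @param n_spliced,n_unspliced non-negative counts (vectorised).
#' @param pseudocount added to numerator and denominator (default 0.5).
#' @return `(n_spliced + pseudocount) / (n_unspliced + pseudocount)`.
#' @export
efficiency_ratio <- function(n_spliced, n_unspliced, pseudocount = 0.5) {
  if (any(n_spliced < 0) || any(n_unspliced < 0))
    stop("negative read counts")
  out <- (n_spliced + pseudocount) / (n_unspliced + pseudocount)
  out[n_unspliced + pseudocount == 0] <- NA_real_
  out
}

#' Percentage of gene reads mapping to an intron
#'
#' 100 x (reads with >= 1 base overlapping the intron interval) / (reads
#' with >= 1 base overlapping the gene span), per sample. A read counts once
#' regardless of how many of its blocks overlap.
#'
#' @param reads a `read_blocks` data.frame.
#' @param model a [gene_model()].
#' @param intron_index transcription-order intron number (see [junctions()]).
#' @return named numeric vector of percentages per sample (NA where a sample
#'   has no gene reads).
#' @export
intron_read_pct <- function(reads, model, intron_index) {
  jn <- junctions(model)
  j <- jn[jn$index == intron_index, ]
  if (nrow(j) != 1) stop("no intron with index ", intron_index)
  span <- gene_span(model)
  key <- paste(reads$sample_id, reads$read_id, sep = "\r")
  in_gene <- reads$end >= span[1] & reads$start <= span[2]
  in_intron <- reads$end >= j$intron_start & reads$start <= j$intron_end
  samples <- unique(reads$sample_id)
  n_gene <- tapply(key[in_gene], reads$sample_id[in_gene],
                   function(k) length(unique(k)))
  n_intr <- tapply(key[in_intron], reads$sample_id[in_intron],
                   function(k) length(unique(k)))
  out <- 100 * ifelse(is.na(n_intr[samples]), 0, n_intr[samples]) /
    as.numeric(n_gene[samples])
  names(out) <- samples
  out
}

#' Percent spliced in (PSI) for an alternative donor event
#'
#' `100 * n_ref_spliced / (n_ref_spliced + n_alt_spliced)`: the percentage
#' of event-informative spliced reads using the reference donor. NA when no
#' informative reads exist.
#'
#' @param n_ref_spliced,n_alt_spliced non-negative counts (vectorised).
#' @return percentage in `[0, 100]`.
#' @export
compute_psi <- function(n_ref_spliced, n_alt_spliced) {
  stopifnot(all(n_ref_spliced >= 0), all(n_alt_spliced >= 0))
  tot <- n_ref_spliced + n_alt_spliced
  out <- 100 * n_ref_spliced / tot
  out[tot == 0] <- NA_real_
  out
}

# Reference and alternative splice gaps implied by a model's alt-donor
# event, as 1-based inclusive genomic intervals.
alt_donor_gaps <- function(model) {
  ad <- model$alt_donor
  if (is.null(ad)) stop("gene model has no alternative donor annotation")
  jn <- junctions(model)
  j <- jn[jn$index == ad$intron_index, ]
  if (model$strand == "+") {
    list(ref = c(j$intron_start, j$intron_end),
         alt = c(ad$alt_exon[2] + 1L, j$intron_end))
  } else {
    list(ref = c(j$intron_start, j$intron_end),
         alt = c(j$intron_start, ad$alt_exon[1] - 1L))
  }
}

#' Count reference- and alternative-donor spliced reads
#'
#' For a model carrying an [add_alternative_donor()] annotation, counts per
#' sample the reads whose splice gap matches the reference intron exactly
#' and those matching the alternative-donor gap (donor inside the host exon,
#' same acceptor).
#'
#' @inheritParams count_junctions
#' @return data.frame per sample: `sample_id`, `n_ref_spliced`,
#'   `n_alt_spliced`, `psi`.
#' @export
count_alt_donor <- function(reads, model, min_anchor = 1L) {
  gaps <- alt_donor_gaps(model)
  count_gap <- function(gap) {
    key <- paste(reads$sample_id, reads$read_id, sep = "\r")
    o <- order(key, reads$start)
    key <- key[o]; st <- reads$start[o]; en <- reads$end[o]
    n <- length(key)
    same <- c(FALSE, key[-1] == key[-n])
    hit <- same & (c(0L, en[-n]) + 1L == gap[1]) & (st - 1L == gap[2]) &
      (c(0L, en[-n] - st[-n] + 1L) >= min_anchor) &
      (en - st + 1L >= min_anchor)
    tapply(hit, reads$sample_id[o], function(h) sum(h))
  }
  samples <- unique(reads$sample_id)
  nr <- count_gap(gaps$ref)[samples]
  na_ <- count_gap(gaps$alt)[samples]
  nr[is.na(nr)] <- 0; na_[is.na(na_)] <- 0
  data.frame(sample_id = samples,
             n_ref_spliced = as.integer(nr),
             n_alt_spliced = as.integer(na_),
             psi = compute_psi(as.integer(nr), as.integer(na_)))
}

#' Normalise a count matrix (median-of-ratios + log2)
#'
#' A variance-stabilising monotone transform for downstream linear-model
#' association: per-sample size factors are estimated by the median-of-ratios
#' method (median across genes of the ratio of a sample's count to the
#' gene's geometric mean; genes containing a zero count are excluded from
#' the median, matching the reference implementation of the method), and
#' values are `log2(count / size_factor + 1)`. When `batch` labels are
#' supplied each gene is mean-centred within batch and shifted back to its
#' grand mean.
#'
#' @param counts samples x genes matrix of non-negative counts.
#' @param batch optional per-sample batch labels.
#' @return list with `values` (samples x genes matrix) and `size_factors`.
#' @export
normalize_expression <- function(counts, batch = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  loggeo <- colMeans(log(counts))          # -Inf for genes with any zero
  sf <- vapply(seq_len(nrow(counts)), function(i) {
    r <- log(counts[i, ]) - loggeo
    exp(stats::median(r[is.finite(loggeo) & counts[i, ] > 0]))
  }, numeric(1))
  if (nrow(counts) == 1) sf <- 1
  vals <- log2(counts / sf + 1)
  if (!is.null(batch)) {
    stopifnot(length(batch) == nrow(counts))
    for (g in seq_len(ncol(vals))) {
      grand <- mean(vals[, g])
      bm <- stats::ave(vals[, g], batch)
      vals[, g] <- vals[, g] - bm + grand
    }
  }
  list(values = vals, size_factors = sf)
}

#' Per-sample splicing phenotype table
#'
#' Runs the junction counters over a read table and assembles the phenotype
#' table used for association: alternative-donor PSI (when the model carries
#' the event), per-junction splicing-efficiency ratios, per-junction
#' intron-read percentages, and a log2 gene read count as the expression
#' value (normalise across genes separately with [normalize_expression()]
#' when a multi-gene count matrix is available).
#'
#' @inheritParams count_junctions
#' @param pseudocount passed to [efficiency_ratio()].
#' @return data.frame per sample: `sample_id`, `psi`, `eff_<j>`,
#'   `intronpct_<j>` for each junction `j`, `n_gene_reads`, `expr`.
#' @export
junction_phenotypes <- function(reads, model, min_anchor = 1L,
                                pseudocount = 0.5, both_boundaries = FALSE) {
  cnt <- count_junctions(reads, model, min_anchor, both_boundaries)
  samples <- unique(reads$sample_id)
  jn <- junctions(model)
  out <- data.frame(sample_id = samples)
  if (!is.null(model$alt_donor)) {
    ad <- count_alt_donor(reads, model, min_anchor)
    out$psi <- ad$psi[match(samples, ad$sample_id)]
  }
  for (j in sort(jn$index)) {
    cj <- cnt[cnt$junction == j, ]
    m <- match(samples, cj$sample_id)
    out[[paste0("eff_", j)]] <-
      efficiency_ratio(cj$n_spliced[m], cj$n_unspliced[m], pseudocount)
    out[[paste0("intronpct_", j)]] <-
      intron_read_pct(reads, model, j)[samples]
  }
  span <- gene_span(model)
  key <- paste(reads$sample_id, reads$read_id, sep = "\r")
  ing <- reads$end >= span[1] & reads$start <= span[2]
  ng <- tapply(key[ing], reads$sample_id[ing], function(k) length(unique(k)))
  out$n_gene_reads <- as.integer(ng[samples])
  out$n_gene_reads[is.na(out$n_gene_reads)] <- 0L
  out$expr <- log2(out$n_gene_reads + 1)
  rownames(out) <- NULL
  out
}
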