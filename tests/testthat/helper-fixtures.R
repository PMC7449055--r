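# Shared fixtures, built in code.

# Two-intron toy gene: exons (100,199), (300,399), (500,599).
toy_model <- function(strand = "+") {
  gene_model("toygene", "chrT", strand,
             data.frame(start = c(100L, 300L, 500L),
                        end = c(199L, 399L, 599L)))
}

# One read from block start/end vectors.
toy_read <- function(starts, ends, sample_id = "s1", read_id = "r1") {
  data.frame(sample_id = sample_id, read_id = read_id, chrom = "chrT",
             start = as.integer(starts), end = as.integer(ends))
}

# Stack several reads (lists of c(starts, ends) pairs) into a read table.
toy_reads <- function(..., sample_id = "s1") {
  rl <- list(...)
  do.call(rbind, lapply(seq_along(rl), function(i)
    toy_read(rl[[i]]$starts, rl[[i]]$ends, sample_id,
             paste0("r", i))))
}

# Small simulation config for fast tests.
small_config <- function(...) {
  sim_config(n_animals = 30, n_markers = 12, junction_depth = 80,
             bg_depth = 200, n_exons = 15, seed = 42, ...)
}

fixture_panel <- function() {
  read_ese_panel(system.file("extdata", "ese_panel_synthetic.txt",
                             package = "junctionqtl"))
}

# 23-nt reconstructed exon-8 context, reference (K, AA) allele; the
# dinucleotide variant sits at offset 15-16.
k_context <- "CCTGCCCTGCCAAGAAGGGCTGC"
k_variant_at <- 15L
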