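#' Run the full simulate-phenotype-associate-report pipeline
#'
#' End-to-end driver: simulates a cohort (reads, genotypes, covariates),
#' derives the junction phenotype table, runs association scans for the
#' focal-junction efficiency, intron-read percentage, PSI and expression
#' phenotypes (plus a conditional expression scan on the causal marker),
#' scans the shipped exon context for allele-specific ESE disruption,
#' analyses a simulated mini-gene qPCR plate, and writes everything as TSV
#' plus a `summary.json` and a `run.log`.
#'
#' @param config a YAML file path or a list. Recognised keys: `seed`,
#'   `sim` (overrides passed to [sim_config()]), `min_anchor`,
#'   `pseudocount`, `alpha`, `condition_on`, `focal`, `ese_panel`,
#'   `ese_context` (paths; default to the shipped synthetic fixtures).
#' @param outdir output directory (created if needed).
#' @param dry_run validate the configuration and input paths without
#'   computing or writing anything.
#' @return (invisibly) a list with the in-memory results: `phenotypes`,
#'   `scans`, `conditional`, `ese`, `qpcr`, `summary`.
#' @export
run_pipeline <- function(config = list(), outdir, dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(seed = 1L, sim = list(), min_anchor = 1L,
                   pseudocount = 0.5, alpha = 0.05,
                   condition_on = "K232A_sim", focal = "K232A_sim",
                   ese_panel = system.file("extdata",
                     "ese_panel_synthetic.txt", package = "junctionqtl"),
                   ese_context = system.file("extdata",
                     "exon8_context_synthetic.fa", package = "junctionqtl"))
  config <- utils::modifyList(defaults, config)
  for (key in c("ese_panel", "ese_context"))
    if (!file.exists(config[[key]]))
      stop("stage config: input path does not exist: ", config[[key]])
  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  if (dry_run) return(invisible(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("junctionqtl ", as.character(utils::packageVersion("junctionqtl")),
          " on R ", as.character(getRversion()))
  logline("seed ", cfg$seed, "; n_animals ", cfg$n_animals, "; n_markers ",
          cfg$n_markers)
  wtsv <- function(d, name) utils::write.table(
    d, file.path(outdir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  stage <- "simulate"
  res <- try({
    sim <- simulate_reads(cfg)
    covar <- simulate_covariates(cfg)

    stage <- "phenotypes"
    pheno <- junction_phenotypes(sim$reads, sim$model,
                                 min_anchor = config$min_anchor,
                                 pseudocount = config$pseudocount)
    pheno <- merge(pheno, covar, by = "sample_id")
    wtsv(pheno, "phenotypes.tsv")
    logline("phenotypes for ", nrow(pheno), " animals, ",
            nrow(junctions(sim$model)), " junctions")

    stage <- "associate"
    covX <- covar[, c("cohort", "ancestry_nz_hf", "ancestry_us_hf",
                      "heterosis")]
    rownames(covX) <- covar$sample_id
    focal_j <- cfg$focal_junction
    pcols <- c(eff = paste0("eff_", focal_j),
               intronpct = paste0("intronpct_", focal_j),
               psi = "psi", expr = "expr")
    scans <- list()
    for (nm in names(pcols)) {
      y <- stats::setNames(pheno[[pcols[[nm]]]], pheno$sample_id)
      scans[[nm]] <- scan_markers(y, sim$genotypes, covX,
                                  focal = config$focal)
      wtsv(scans[[nm]], paste0("assoc_", nm, ".tsv"))
    }
    yexpr <- stats::setNames(pheno$expr, pheno$sample_id)
    conditional <- scan_markers(yexpr, sim$genotypes, covX,
                                condition_on = config$condition_on,
                                focal = config$focal)
    wtsv(conditional, "conditional_assoc.tsv")
    n_markers <- sum(!is.na(scans$eff$p))
    logline("scans complete: ", n_markers, " markers tested per phenotype")

    stage <- "ese"
    panel <- read_ese_panel(config$ese_panel)
    ctx <- Biostrings::readDNAStringSet(config$ese_context)
    seq_k <- as.character(ctx[[1]])
    at <- as.integer(sub(".*variant_at=([0-9]+).*", "\\1", names(ctx)[1]))
    delta <- variant_motif_delta(seq_k, at, "AA", "GC", panel)
    ese_tab <- rbind(
      if (nrow(delta$hits_ref))
        cbind(allele = "K", delta$hits_ref,
              overlaps_variant = delta$hits_ref$start <= at + 1 &
                delta$hits_ref$start + 5 >= at),
      if (nrow(delta$hits_alt))
        cbind(allele = "A", delta$hits_alt,
              overlaps_variant = delta$hits_alt$start <= at + 1 &
                delta$hits_alt$start + 5 >= at))
    if (is.null(ese_tab))
      ese_tab <- data.frame(allele = character(0), motif = character(0),
                            start = integer(0), genomic_start = integer(0),
                            overlaps_variant = logical(0))
    wtsv(ese_tab, "ese.tsv")
    logline("ese: ", delta$n_overlap_ref, " variant-overlapping hits (K), ",
            delta$n_overlap_alt, " (A)")

    stage <- "qpcr"
    plate <- simulate_qpcr_plate(cfg)
    qtab <- qpcr_splicing_table(plate, n_tests = 12)
    wtsv(qtab, "qpcr.tsv")

    stage <- "report"
    class_sum <- lapply(pcols, function(col) {
      genotype_class_summary(pheno[[col]],
                             sim$genotypes$dosage[pheno$sample_id,
                                                  "K232A_sim"])
    })
    summary <- list(
      seed = cfg$seed,
      n_markers = n_markers,
      bonferroni = list(
        junction_scan = bonferroni_threshold(config$alpha,
                                             n_markers *
                                               nrow(junctions(sim$model))),
        single_scan = bonferroni_threshold(config$alpha, n_markers),
        qpcr = bonferroni_threshold(config$alpha, 12)),
      top_markers = lapply(scans, function(s)
        s[which(s$rank == 1), c("marker", "pos", "p", "beta")]),
      causal_rank = lapply(scans, function(s)
        s$rank[s$marker == "K232A_sim"]),
      conditional_min_p = min(conditional$p, na.rm = TRUE),
      genotype_class_summaries = class_sum,
      ese = list(k_overlapping = delta$n_overlap_ref,
                 a_overlapping = delta$n_overlap_alt,
                 lost = delta$lost$motif),
      qpcr = qtab)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    logline("report written")
    list(phenotypes = pheno, scans = scans, conditional = conditional,
         ese = ese_tab, qpcr = qtab, summary = summary)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    logline("FAILED at stage ", stage, ": ", attr(res, "condition")$message)
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  }
  invisible(res)
}
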