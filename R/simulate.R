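#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a cohort of dairy
#' cattle segregating a biallelic dinucleotide substitution (dosage counts
#' the expression-*decreasing* alternative allele, so dosage 0 is the
#' high-expression homozygote), LD neighbours copied from the causal
#' haplotype with a per-marker flip probability, genotype-dependent intron
#' retention at a focal junction, genotype-dependent alternative-donor
#' usage, genotype-dependent total expression, and triplicate mini-gene
#' qPCR plates for two plasmid alleles.
#'
#' Class means default to the cohort values the generator is anchored to:
#' high-expression-allele frequency 0.51; focal intron-read percentages
#' 1.16 / 1.53 / 1.94 for dosage 0/1/2; reference-donor PSI 94.1 / 94.5 /
#' 96.4; transformed expression 9.628 / 9.436 / 9.244 (residual SD 0.25,
#' back-derived from class standard errors at the class sizes implied by
#' n = 375 and the allele frequency); cohort sizes 21/183/171; qPCR true
#' splicing ratios per junction from the mini-gene experiment.
#'
#' @param n_animals cohort size.
#' @param k_allele_freq frequency of the reference (high-expression) allele.
#' @param n_markers markers in the simulated interval (causal included).
#' @param ld_flip range of the per-haplotype allele flip probability used
#'   to generate LD partners of the causal marker.
#' @param intron_pct_means expected percentage of gene reads mapping to the
#'   focal intron, by dosage 0/1/2.
#' @param psi_means expected reference-donor PSI by dosage 0/1/2.
#' @param expr_means,expr_sd transformed-expression class means (dosage
#'   0/1/2) and residual SD.
#' @param cohort_sizes relative sizes of the three sequencing cohorts.
#' @param cohort_expr_effect additive expression offset per cohort.
#' @param junction_depth expected junction-bridging reads per junction.
#' @param bg_depth expected exon-body reads per animal.
#' @param read_len simulated read length (single-end).
#' @param n_exons exons in the toy gene model.
#' @param focal_junction transcription-order intron index carrying the
#'   genotype-dependent retention effect (others stay at
#'   `baseline_intron_pct`).
#' @param baseline_intron_pct intron-read percentage at non-focal junctions.
#' @param boundary_fraction fraction of intronic reads crossing the donor
#'   boundary (the rest lie inside the intron body).
#' @param bio_sd per-animal biological jitter SD (log scale) applied as a
#'   mean-preserving lognormal factor to the retention and
#'   alternative-donor-usage rates.
#' @param overdispersion negative-binomial size for read totals.
#' @param qpcr list of mini-gene plate settings: `junctions`, true
#'   per-junction splicing `ratios_k`/`ratios_a`, true `unspliced_k`/
#'   `unspliced_a` expression, `n_preps` preparations x `n_wells` wells,
#'   `cq_sd` cycle noise, `ratio_bio_sd` and `tf_sd` lognormal biological /
#'   transfection variation, amplification `efficiency`, `dilutions`.
#' @param seed integer master seed; every sub-simulation derives its own
#'   named stream from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_animals = 375,
                       k_allele_freq = 0.51,
                       n_markers = 200,
                       ld_flip = c(0.10, 0.45),
                       intron_pct_means = c(1.16, 1.53, 1.94),
                       psi_means = c(94.1, 94.5, 96.4),
                       expr_means = c(9.628, 9.436, 9.244),
                       expr_sd = 0.25,
                       cohort_sizes = c(21, 183, 171),
                       cohort_expr_effect = c(0, 0.08, -0.08),
                       junction_depth = 600,
                       bg_depth = 1500,
                       read_len = 100,
                       n_exons = 15,
                       focal_junction = 8,
                       baseline_intron_pct = 0.5,
                       boundary_fraction = 0.4,
                       bio_sd = 0.2,
                       overdispersion = 20,
                       qpcr = list(),
                       seed = 1L) {
  qp <- utils::modifyList(list(
    junctions = c(3, 5, 7, 13),
    ratios_k = c(0.253, 143.18, 28.49, 92.90),
    ratios_a = c(0.173, 133.52, 5.55, 90.92),
    unspliced_k = c(0.092, 0.286, 0.216, 0.821),
    unspliced_a = c(0.0842, 0.180, 0.234, 0.503),
    n_preps = 3, n_wells = 3, cq_sd = 0.15, ratio_bio_sd = 0.08,
    tf_sd = 0.15, efficiency = 0.95, dilutions = 5^-(0:4)), qpcr)
  cfg <- list(n_animals = n_animals, k_allele_freq = k_allele_freq,
              n_markers = n_markers, ld_flip = ld_flip,
              intron_pct_means = intron_pct_means, psi_means = psi_means,
              expr_means = expr_means, expr_sd = expr_sd,
              cohort_sizes = cohort_sizes,
              cohort_expr_effect = cohort_expr_effect,
              junction_depth = junction_depth, bg_depth = bg_depth,
              read_len = read_len, n_exons = n_exons,
              focal_junction = focal_junction,
              baseline_intron_pct = baseline_intron_pct,
              boundary_fraction = boundary_fraction,
              bio_sd = bio_sd, overdispersion = overdispersion,
              qpcr = qp, seed = as.integer(seed))
  stopifnot(cfg$k_allele_freq > 0, cfg$k_allele_freq < 1,
            cfg$boundary_fraction > 0, cfg$boundary_fraction <= 1,
            all(cfg$intron_pct_means > 0), cfg$junction_depth > 0)
  structure(cfg, class = "sim_config")
}

# Deterministic named sub-seed from the master seed, kept below 2^31.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Toy gene model used by the read simulator
#'
#' A plus-strand gene with `n_exons` exons (intron lengths cycle through a
#' fixed set, all longer than the read length) and an alternative 5' donor
#' annotated inside the exon upstream of the focal junction: the first 9
#' exon bases are retained by the alternative form and the remaining exon
#' bases (a multiple of 3) are intronified, mirroring the geometry of an
#' in-frame alternative donor event.
#'
#' @param config a [sim_config()].
#' @return a [gene_model()] with an alt-donor annotation.
#' @export
simulate_gene_model <- function(config) {
  exon_w <- c(200L, rep(150L, config$n_exons - 2L), 200L)
  intron_w <- rep(c(180L, 250L, 320L, 150L, 400L),
                  length.out = config$n_exons - 1L)
  starts <- integer(config$n_exons)
  starts[1] <- 1000L
  for (i in seq_len(config$n_exons - 1L))
    starts[i + 1] <- starts[i] + exon_w[i] + intron_w[i]
  exons <- data.frame(start = starts, end = starts + exon_w - 1L)
  model <- gene_model("SIMGENE1", "chr14_sim", "+", exons)
  host <- config$focal_junction      # + strand: exon index upstream of intron
  s <- model$exons$start[host]; e <- model$exons$end[host]
  add_alternative_donor(model, alt_exon = c(s, s + 8L),
                        ref_exon = c(s + 9L, e))
}

#' Simulate genotypes at a causal marker and its LD neighbours
#'
#' The causal marker (`K232A_sim`, a dinucleotide AA>GC substitution) is
#' drawn at Hardy-Weinberg proportions for the configured allele frequency;
#' every other marker copies the causal haplotypes with a per-marker flip
#' probability drawn uniformly from `config$ld_flip`, yielding a spread of
#' LD. Dosage counts alternative (GC) alleles.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()]; the causal column is `K232A_sim`.
#' @export
simulate_genotypes <- function(config) {
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_animals; m <- config$n_markers
  alt_freq <- 1 - config$k_allele_freq
  h1 <- stats::rbinom(n, 1, alt_freq)
  h2 <- stats::rbinom(n, 1, alt_freq)
  eps <- stats::runif(m, config$ld_flip[1], config$ld_flip[2])
  pos <- sort(sample(1302265:2302265, m))
  causal_idx <- which.min(abs(pos - 1802265))
  pos[causal_idx] <- 1802265L
  dosage <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    if (j == causal_idx) {
      dosage[, j] <- h1 + h2
    } else {
      f1 <- stats::rbinom(n, 1, eps[j]); f2 <- stats::rbinom(n, 1, eps[j])
      dosage[, j] <- as.integer(xor(h1, f1)) + as.integer(xor(h2, f2))
    }
  }
  ids <- sprintf("rs_sim%04d", seq_len(m))
  ids[causal_idx] <- "K232A_sim"
  ref <- rep("A", m); alt <- rep("G", m)
  ref[causal_idx] <- "AA"; alt[causal_idx] <- "GC"
  genotype_matrix(sprintf("animal%03d", seq_len(n)),
                  data.frame(id = ids, chrom = "chr14_sim", pos = pos,
                             ref = ref, alt = alt),
                  dosage)
}

#' Simulate sample covariates
#'
#' Three sequencing cohorts (sizes proportional to the configured cohort
#' sizes), three ancestry proportions drawn from a Dirichlet and summing to
#' one, and a heterosis fraction in `[0, 1]`.
#'
#' @param config a [sim_config()].
#' @return data.frame per animal: `sample_id`, `cohort`,
#'   `ancestry_nz_hf`, `ancestry_us_hf`, `ancestry_jersey`, `heterosis`.
#' @export
simulate_covariates <- function(config) {
  set.seed(derive_seed(config$seed, "covariates"))
  n <- config$n_animals
  sizes <- round(config$cohort_sizes / sum(config$cohort_sizes) * n)
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  cohort <- factor(rep(paste0("cohort", seq_along(sizes)), sizes))
  g <- matrix(stats::rgamma(3 * n, shape = 2), n, 3)
  anc <- g / rowSums(g)
  data.frame(sample_id = sprintf("animal%03d", seq_len(n)),
             cohort = cohort,
             ancestry_nz_hf = anc[, 1], ancestry_us_hf = anc[, 2],
             ancestry_jersey = anc[, 3],
             heterosis = stats::rbeta(n, 2, 5))
}

# Expected read-count composition for one animal. The expected intron-read
# percentages (focal genotype-dependent, baseline elsewhere) are converted
# into absolute expected counts: with exonic expectation E and intronic
# fractions p_j, total T solves T = E / (1 - sum(p_j)).
expected_composition <- function(config, dosage, depth_mult = 1) {
  n_j <- config$n_exons - 1L
  pct <- rep(config$baseline_intron_pct, n_j)
  pct[config$focal_junction] <- config$intron_pct_means[dosage + 1L]
  p <- pct / 100
  E <- (config$bg_depth + n_j * config$junction_depth) * depth_mult
  total <- E / (1 - sum(p))
  list(pct = pct, total = total,
       junction_spliced = rep(config$junction_depth * depth_mult, n_j),
       intron_reads = total * p,
       unspliced = total * p * config$boundary_fraction,
       intron_body = total * p * (1 - config$boundary_fraction),
       bg = config$bg_depth * depth_mult)
}

#' Simulate aligned reads for a cohort, with a truth table
#'
#' Per animal, reads are generated junction by junction: junction-bridging
#' spliced reads (reference or alternative donor at the focal junction,
#' chosen by the genotype-dependent PSI), donor-boundary-crossing unspliced
#' reads and intron-body reads at genotype-dependent rates, plus
#' exon-body background reads at negative-binomial depth scaled by the
#' genotype-dependent expression. Every read's true kind and the class the
#' junction classifier is expected to assign at its own junction are
#' recorded.
#'
#' @param config a [sim_config()].
#' @param model a [gene_model()] from [simulate_gene_model()] (default).
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()]
#'   (default).
#' @param animals optional subset of animal indices to simulate (e.g.
#'   `1:10` for a classifier round-trip at reduced cohort size).
#' @return list: `reads` (a `read_blocks` data.frame), `truth$reads`
#'   (per read: `sample_id`, `read_id`, `junction`, `kind`,
#'   `expected_class`), `truth$animals` (per animal: dosage, jittered
#'   retention/PSI probabilities, expression, depth multiplier), plus the
#'   `model` and `genotypes` used.
#' @export
simulate_reads <- function(config, model = simulate_gene_model(config),
                           genotypes = simulate_genotypes(config),
                           animals = seq_len(config$n_animals)) {
  set.seed(derive_seed(config$seed, "reads"))
  jn <- junctions(model)
  jn <- jn[order(jn$index), ]
  exons <- model$exons
  L <- config$read_len
  causal <- genotypes$dosage[, "K232A_sim"]
  gaps <- alt_donor_gaps(model)
  ad <- model$alt_donor
  blocks <- list(); truths <- list(); anim <- list()
  for (i in animals) {
    d <- causal[i]
    sid <- genotypes$sample_ids[i]
    expr <- config$expr_means[d + 1L] + stats::rnorm(1, 0, config$expr_sd)
    mult <- 2^(expr - mean(config$expr_means))
    comp <- expected_composition(config, d, mult)
    scale_ret <- exp(stats::rnorm(length(comp$pct), 0, config$bio_sd) -
                       config$bio_sd^2 / 2)
    p_ret <- pmin(comp$pct / 100 * scale_ret, 0.99)
    alt_rate <- (1 - config$psi_means[d + 1L] / 100) *
      exp(stats::rnorm(1, 0, config$bio_sd) - config$bio_sd^2 / 2)
    psi <- 1 - pmin(alt_rate, 0.99)
    bs <- list(); ts <- list()
    for (k in seq_len(nrow(jn))) {
      j <- jn$index[k]
      is <- jn$intron_start[k]; ie <- jn$intron_end[k]
      de <- is - 1L; as2 <- ie + 1L
      don_w <- exons$end[k] - exons$start[k] + 1L
      acc_w <- exons$end[k + 1] - exons$start[k + 1] + 1L
      n_s <- stats::rpois(1, comp$junction_spliced[k])
      n_u <- stats::rpois(1, comp$unspliced[k] * scale_ret[k])
      n_b <- stats::rpois(1, comp$intron_body[k] * scale_ret[k])
      if (n_s > 0) {
        use_alt <- if (j == ad$intron_index)
          stats::runif(n_s) > psi else rep(FALSE, n_s)
        a <- sample(seq_len(min(L - 1L, don_w)), n_s, replace = TRUE)
        # reference-donor spliced reads
        ri <- which(!use_alt)
        if (length(ri)) {
          bs[[length(bs) + 1]] <- cbind(
            id = rep(ri, 2),
            start = c(de - a[ri] + 1L, rep(as2, length(ri))),
            end = c(rep(de, length(ri)),
                    pmin(as2 + (L - a[ri]) - 1L, as2 + acc_w - 1L)),
            junction = j, kindcode = 1L)
        }
        ai <- which(use_alt)
        if (length(ai)) {
          alt_w <- ad$alt_exon[2] - ad$alt_exon[1] + 1L
          aa <- pmin(a[ai], alt_w)
          bs[[length(bs) + 1]] <- cbind(
            id = rep(max(c(0L, ri)) + seq_along(ai), 2),
            start = c(gaps$alt[1] - aa, rep(gaps$alt[2] + 1L, length(ai))),
            end = c(rep(gaps$alt[1] - 1L, length(ai)),
                    pmin(gaps$alt[2] + (L - aa), gaps$alt[2] + acc_w)),
            junction = j, kindcode = 2L)
        }
      }
      if (n_u > 0) {
        a <- sample(seq_len(min(L - 1L, don_w)), n_u, replace = TRUE)
        bs[[length(bs) + 1]] <- cbind(
          id = n_s + seq_len(n_u),
          start = de - a + 1L, end = de - a + L,
          junction = j, kindcode = 3L)
      }
      if (n_b > 0) {
        st <- is + sample.int(max(1L, ie - is + 1L - L + 1L), n_b,
                              replace = TRUE) - 1L
        bs[[length(bs) + 1]] <- cbind(
          id = n_s + n_u + seq_len(n_b),
          start = st, end = pmin(st + L - 1L, ie),
          junction = j, kindcode = 4L)
      }
    }
    n_bg <- stats::rnbinom(1, mu = comp$bg, size = config$overdispersion)
    if (n_bg > 0) {
      w <- exons$end - exons$start + 1L
      ex <- sample(nrow(exons), n_bg, replace = TRUE, prob = w)
      st <- exons$start[ex] +
        (sample.int(max(w), n_bg, replace = TRUE) - 1L) %% w[ex]
      bs[[length(bs) + 1]] <- cbind(
        id = seq_len(n_bg), start = st,
        end = pmin(st + L - 1L, exons$end[ex]),
        junction = NA_integer_, kindcode = 5L)
    }
    b <- do.call(rbind, bs)
    read_key <- paste0(ifelse(is.na(b[, "junction"]), "bg",
                              paste0("j", b[, "junction"])),
                       "_", b[, "kindcode"], "_", b[, "id"])
    blocks[[length(blocks) + 1]] <- data.frame(
      sample_id = sid, read_id = paste0(sid, "_", read_key),
      chrom = model$chrom, start = as.integer(b[, "start"]),
      end = as.integer(b[, "end"]))
    first <- !duplicated(read_key)
    kinds <- c("spliced", "alt_spliced", "unspliced", "intron_body",
               "exon_body")
    expected <- c("spliced", "other", "unspliced", "other", "other")
    truths[[length(truths) + 1]] <- data.frame(
      sample_id = sid, read_id = paste0(sid, "_", read_key[first]),
      junction = as.integer(b[first, "junction"]),
      kind = kinds[b[first, "kindcode"]],
      expected_class = expected[b[first, "kindcode"]])
    anim[[length(anim) + 1]] <- data.frame(
      sample_id = sid, dosage = d, expr = expr, depth_mult = mult,
      psi_true = 100 * psi,
      t(stats::setNames(100 * p_ret, paste0("p_ret_", seq_along(p_ret)))))
  }
  list(reads = do.call(rbind, blocks),
       truth = list(reads = do.call(rbind, truths),
                    animals = do.call(rbind, anim)),
       model = model, genotypes = genotypes)
}

#' Fast count-level cohort simulation
#'
#' Generates, for every animal, the junction count phenotypes at the focal
#' junction directly at the count level (identical expectations to
#' [simulate_reads()], without materialising reads): spliced and unspliced
#' focal-junction counts, intron-read percentage, reference/alternative
#' donor PSI counts, and the transformed expression phenotype with cohort
#' effects. Intended for association-scale simulation studies.
#'
#' @param config a [sim_config()].
#' @param pseudocount passed to [efficiency_ratio()].
#' @return list: `pheno` data.frame (per animal: `sample_id`, `dosage`,
#'   `eff_focal`, `intronpct_focal`, `psi`, `expr`), `genotypes`,
#'   `covariates`, and `truth` (configured class means).
#' @export
simulate_cohort_counts <- function(config, pseudocount = 0.5) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  set.seed(derive_seed(config$seed, "counts"))
  n <- config$n_animals
  d <- genotypes$dosage[, "K232A_sim"]
  cohort_eff <- config$cohort_expr_effect[as.integer(covariates$cohort)]
  expr <- config$expr_means[d + 1L] + cohort_eff +
    stats::rnorm(n, 0, config$expr_sd)
  mult <- 2^(expr - mean(config$expr_means))
  n_j <- config$n_exons - 1L
  pct_focal <- config$intron_pct_means[d + 1L]
  jit <- exp(stats::rnorm(n, 0, config$bio_sd) - config$bio_sd^2 / 2)
  p_ret <- pmin(pct_focal / 100 * jit, 0.99)
  alt_jit <- exp(stats::rnorm(n, 0, config$bio_sd) - config$bio_sd^2 / 2)
  psi_p <- 1 - pmin((1 - config$psi_means[d + 1L] / 100) * alt_jit, 0.99)
  E <- (config$bg_depth + n_j * config$junction_depth) * mult
  p_other <- (n_j - 1) * config$baseline_intron_pct / 100
  total <- E / (1 - p_other - pct_focal / 100)
  n_s <- stats::rpois(n, config$junction_depth * mult)
  n_u <- stats::rpois(n, total * p_ret * config$boundary_fraction)
  n_body <- stats::rpois(n, total * p_ret * (1 - config$boundary_fraction))
  other_reads <- stats::rnbinom(n, mu = E + total * p_other,
                                size = config$overdispersion)
  realized_total <- other_reads + n_u + n_body
  n_ref <- stats::rbinom(n, n_s, psi_p)
  pheno <- data.frame(
    sample_id = genotypes$sample_ids, dosage = d,
    eff_focal = efficiency_ratio(n_s, n_u, pseudocount),
    intronpct_focal = 100 * (n_u + n_body) / realized_total,
    psi = compute_psi(n_ref, n_s - n_ref),
    expr = expr)
  list(pheno = pheno, genotypes = genotypes, covariates = covariates,
       truth = list(intron_pct_means = config$intron_pct_means,
                    psi_means = config$psi_means,
                    expr_means = config$expr_means))
}

#' Simulate a mini-gene qPCR plate
#'
#' Standard-curve wells at serial 5x dilutions for every assay, plus
#' experimental triplicate wells for two plasmid alleles whose true
#' spliced:unspliced ratios per junction are configured. Cq values are
#' generated from the true quantities through each assay's amplification
#' efficiency with Gaussian cycle noise; per-sample lognormal factors model
#' biological ratio variation and transfection efficiency (the latter is
#' shared with the reference assays, so normalisation cancels it).
#'
#' @param config a [sim_config()]; plate settings under `config$qpcr`.
#' @return a plate data.frame in the [read_qpcr_plate()] layout, with
#'   attribute `truth` (configured true ratios per junction and allele).
#' @export
simulate_qpcr_plate <- function(config) {
  qp <- config$qpcr
  set.seed(derive_seed(config$seed, "qpcr"))
  slope <- -1 / log10(1 + qp$efficiency)
  assays <- data.frame(
    assay_id = c(paste0("j", rep(qp$junctions, each = 2),
                        c("_spliced", "_unspliced")), "EIF3K", "GFP"),
    assay_role = c(rep(c("spliced", "unspliced"), length(qp$junctions)),
                   "reference", "reference"),
    junction = c(rep(qp$junctions, each = 2), NA, NA))
  assays$intercept <- stats::runif(nrow(assays), 22, 28)
  rows <- list()
  for (a in seq_len(nrow(assays))) {
    cq <- assays$intercept[a] + slope * log10(qp$dilutions) +
      stats::rnorm(length(qp$dilutions), 0, qp$cq_sd)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = "pool", allele = NA_character_,
      assay_id = assays$assay_id[a], assay_role = assays$assay_role[a],
      junction = assays$junction[a],
      well = paste0("std", seq_along(qp$dilutions)),
      cq = cq, dilution = qp$dilutions)
  }
  for (allele in c("K", "A")) {
    ratios <- if (allele == "K") qp$ratios_k else qp$ratios_a
    unspl <- if (allele == "K") qp$unspliced_k else qp$unspliced_a
    for (s in seq_len(qp$n_preps)) {
      sid <- paste0(allele, "_prep", s)
      tf <- exp(stats::rnorm(1, 0, qp$tf_sd))
      # one biological draw per preparation: the unspliced level and the
      # sample's splicing ratio; the spliced level is their product, so the
      # per-sample ratio CV is ratio_bio_sd (plus cycle noise), matching
      # the across-sample spread of the anchored experiment
      ru_s <- unspl * exp(stats::rnorm(length(unspl), 0, qp$ratio_bio_sd))
      r_s <- ratios * exp(stats::rnorm(length(ratios), 0, qp$ratio_bio_sd))
      for (a in seq_len(nrow(assays))) {
        role <- assays$assay_role[a]
        if (role == "reference") {
          q <- tf
        } else {
          ji <- match(assays$junction[a], qp$junctions)
          q <- tf * if (role == "spliced") ru_s[ji] * r_s[ji] else ru_s[ji]
        }
        cq <- assays$intercept[a] + slope * log10(q) +
          stats::rnorm(qp$n_wells, 0, qp$cq_sd)
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, allele = allele,
          assay_id = assays$assay_id[a], assay_role = role,
          junction = assays$junction[a],
          well = paste0("w", seq_len(qp$n_wells)),
          cq = cq, dilution = NA_real_)
      }
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  attr(plate, "truth") <- data.frame(
    junction = qp$junctions, ratio_k = qp$ratios_k, ratio_a = qp$ratios_a)
  plate
}
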