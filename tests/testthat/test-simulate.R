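test_that("simulation is reproducible from the master seed", {
  cfg <- small_config()
  expect_identical(simulate_genotypes(cfg)$dosage,
                   simulate_genotypes(cfg)$dosage)
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  expect_identical(simulate_qpcr_plate(cfg)$cq, simulate_qpcr_plate(cfg)$cq)
  r1 <- simulate_reads(cfg, animals = 1:2)
  r2 <- simulate_reads(cfg, animals = 1:2)
  expect_identical(r1$reads, r2$reads)
  # different seeds decouple
  cfg2 <- small_config(); cfg2$seed <- 43L
  expect_false(identical(simulate_genotypes(cfg)$dosage,
                         simulate_genotypes(cfg2)$dosage))
})

test_that("zero flip probability yields perfect LD with the causal marker", {
  cfg <- small_config(ld_flip = c(0, 0))
  gm <- simulate_genotypes(cfg)
  causal <- gm$dosage[, "K232A_sim"]
  r2 <- apply(gm$dosage, 2, ld_r2, g2 = causal)
  expect_true(all(abs(r2 - 1) < 1e-12, na.rm = TRUE))
})

test_that("allele frequency and Hardy-Weinberg proportions are honoured", {
  freqs <- numeric(50)
  hwe_p <- numeric(50)
  for (s in 1:50) {
    cfg <- sim_config(n_animals = 375, n_markers = 2, seed = 1000 + s)
    d <- simulate_genotypes(cfg)$dosage[, "K232A_sim"]
    freqs[s] <- mean(d) / 2
    n <- tabulate(d + 1L, 3)
    p <- mean(d) / 2
    expected <- 375 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    hwe_p[s] <- suppressWarnings(chisq.test(n, p = expected / 375)$p.value)
  }
  expect_equal(mean(freqs), 1 - 0.51, tolerance = 0.03)
  expect_gte(mean(hwe_p > 0.01), 0.95)
})

test_that("covariate ancestry proportions sum to one; cohorts sized as configured", {
  cfg <- sim_config(n_animals = 375, seed = 2)
  cov <- simulate_covariates(cfg)
  expect_equal(cov$ancestry_nz_hf + cov$ancestry_us_hf + cov$ancestry_jersey,
               rep(1, 375))
  expect_equal(as.integer(table(cov$cohort)), c(21, 183, 171))
  expect_true(all(cov$heterosis >= 0 & cov$heterosis <= 1))
})

test_that("generator truth classes match the classifier on every read", {
  cfg <- small_config()
  sim <- simulate_reads(cfg, animals = 1:3)
  jn <- junctions(sim$model)
  truth <- sim$truth$reads
  mismatches <- 0L
  for (k in seq_len(nrow(jn))) {
    cl <- classify_reads(sim$reads, jn[k, ],
                                                   min_anchor = 1L,
                                                   strand = "+")
    key <- paste(cl$sample_id, cl$read_id)
    tkey <- paste(truth$sample_id, truth$read_id)
    own <- !is.na(truth$junction) & truth$junction == jn$index[k]
    got <- cl$class[match(tkey[own], key)]
    mismatches <- mismatches + sum(got != truth$expected_class[own])
    # reads from other junctions must never be called spliced/unspliced here
    other <- cl$class[match(tkey[!own], key)]
    mismatches <- mismatches + sum(other != "other", na.rm = TRUE)
  }
  expect_equal(mismatches, 0L)
})

test_that("degenerate retention settings drive the phenotypes to their limits", {
  cfg <- small_config(intron_pct_means = c(1e-6, 1e-6, 1e-6),
                      baseline_intron_pct = 1e-6)
  sim <- simulate_reads(cfg, animals = 1:3)
  ph <- junction_phenotypes(sim$reads, sim$model)
  expect_true(all(ph$intronpct_8 == 0))
  expect_true(all(ph[, grep("^intronpct_", names(ph))] == 0))
})

test_that("per-genotype phenotype means recover the configured truth", {
  cfg <- sim_config(n_animals = 450, seed = 11)
  cc <- simulate_cohort_counts(cfg)
  ph <- cc$pheno
  for (d in 0:2) {
    sel <- ph$dosage == d
    # intron-read percentage against configured class mean, within 2 SE
    m <- mean(ph$intronpct_focal[sel])
    se <- sd(ph$intronpct_focal[sel]) / sqrt(sum(sel))
    expect_lt(abs(m - cfg$intron_pct_means[d + 1]), 2.5 * se + 0.02)
    # expression class means
    me <- mean(ph$expr[sel])
    see <- sd(ph$expr[sel]) / sqrt(sum(sel))
    expect_lt(abs(me - cfg$expr_means[d + 1]), 3 * see + 0.02)
  }
  # PSI medians ordered with genotype and near configured values
  med <- tapply(ph$psi, ph$dosage, median)
  expect_true(all(diff(med) > 0))
  expect_equal(as.numeric(med), cfg$psi_means, tolerance = 0.02)
})

test_that("read-level and count-level generators agree on class means", {
  cfg <- sim_config(n_animals = 40, junction_depth = 300, bg_depth = 800,
                    seed = 3)
  sim <- simulate_reads(cfg)
  ph <- junction_phenotypes(sim$reads, sim$model)
  d <- sim$genotypes$dosage[ph$sample_id, "K232A_sim"]
  # genotype ordering of the focal-junction retention phenotype
  cm <- tapply(ph$intronpct_8, d, mean)
  if (all(0:2 %in% d)) expect_true(cm["0"] < cm["2"])
  expect_equal(mean(ph$intronpct_8),
               mean(cfg$intron_pct_means[d + 1]) , tolerance = 0.35)
})

test_that("cohort expression offsets are absorbed by the cohort covariate", {
  cfg <- sim_config(n_animals = 300, n_markers = 60, seed = 17,
                    cohort_expr_effect = c(0, 0.6, -0.6),
                    intron_pct_means = c(1.5, 1.5, 1.5),
                    expr_means = c(9.4, 9.4, 9.4))  # no genotype effect
  cc <- simulate_cohort_counts(cfg)
  y <- setNames(cc$pheno$expr, cc$pheno$sample_id)
  covX <- cc$covariates[, c("cohort", "heterosis"), drop = FALSE]
  rownames(covX) <- cc$covariates$sample_id
  with_cov <- scan_markers(y, cc$genotypes, covX)
  expect_gt(ks.test(with_cov$p, "punif")$p.value, 0.01)
  # the cohort term really captures variance: residual SD shrinks
  r_with <- lm(y ~ ., data = cbind(covX, y = y))
  r_wo <- lm(y ~ heterosis, data = cbind(covX, y = y))
  expect_lt(sigma(r_with), 0.8 * sigma(r_wo))
})
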