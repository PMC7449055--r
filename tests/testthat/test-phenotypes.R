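test_that("read classification matches the bridging/boundary definitions", {
  jn <- junctions(toy_model())[1, ]   # intron (200, 299)
  expect_equal(classify_read(data.frame(start = c(190, 300),
                                        end = c(199, 310)), jn), "spliced")
  expect_equal(classify_read(data.frame(start = 190, end = 210), jn),
               "unspliced")
  expect_equal(classify_read(data.frame(start = 205, end = 260), jn),
               "other")
  # anchor requirement: 5-base left anchor fails at min_anchor = 6
  r <- data.frame(start = c(195, 300), end = c(199, 330))
  expect_equal(classify_read(r, jn, min_anchor = 1), "spliced")
  expect_equal(classify_read(r, jn, min_anchor = 6), "other")
  # gap must match the intron exactly
  expect_equal(classify_read(data.frame(start = c(190, 301),
                                        end = c(199, 330)), jn), "other")
})

test_that("classification of tiling single-block reads matches an interval oracle", {
  jn <- junctions(toy_model())[1, ]
  for (anchor in c(1L, 6L)) {
    for (st in 150:331) {
      r <- data.frame(start = st, end = st + 19)
      got <- classify_read(r, jn, min_anchor = anchor)
      # oracle: a single block can only be unspliced (crossing the donor
      # boundary 199/200 with >= anchor bases each side) or other
      donor_side <- st <= 200 - anchor
      intron_side <- st + 19 >= 200 + anchor - 1
      want <- if (donor_side && intron_side) "unspliced" else "other"
      expect_equal(got, want, info = paste("start", st, "anchor", anchor))
    }
  }
})

test_that("minus-strand classification mirrors the donor boundary", {
  jn <- junctions(toy_model("-"))
  j1 <- jn[jn$index == 1, ]           # genomic intron (400, 499), donor at 500
  expect_equal(classify_read(data.frame(start = 480, end = 510), j1,
                             strand = "-"), "unspliced")
  expect_equal(classify_read(data.frame(start = 380, end = 410), j1,
                             strand = "-"), "other")
  expect_equal(classify_read(data.frame(start = 380, end = 410), j1,
                             strand = "-", both_boundaries = TRUE),
               "unspliced")
})

test_that("junction counting tallies constructed fixtures and double-spliced reads", {
  spliced <- lapply(1:10, function(i)
    list(starts = c(180 + i, 300), ends = c(199, 309 + i)))
  boundary <- lapply(1:2, function(i)
    list(starts = 190 + i, ends = 210 + i))
  within <- list(list(starts = 220, ends = 260))
  # one read spliced across both introns
  double <- list(list(starts = c(190, 300, 500), ends = c(199, 399, 520)))
  reads <- do.call(toy_reads, c(spliced, boundary, within, double))
  cnt <- count_junctions(reads, toy_model())
  j1 <- cnt[cnt$junction == 1, ]
  expect_equal(j1$n_spliced, 11L)     # 10 + the double-spliced read
  expect_equal(j1$n_unspliced, 2L)
  expect_equal(j1$n_other, 1L)
  j2 <- cnt[cnt$junction == 2, ]
  expect_equal(j2$n_spliced, 1L)
  expect_warning(count_junctions(reads[0, ], toy_model()), "empty")
})

test_that("classification is invariant under a constant coordinate shift", {
  jn <- junctions(toy_model())[1, ]
  set.seed(3)
  for (i in 1:50) {
    st <- sample(150:320, 1)
    r <- data.frame(start = c(st, st + 40), end = c(st + 19, st + 59))
    shift <- 12345L
    jns <- jn
    jns[c("donor_exon_end", "acceptor_exon_start",
          "intron_start", "intron_end")] <-
      jn[c("donor_exon_end", "acceptor_exon_start",
           "intron_start", "intron_end")] + shift
    expect_equal(classify_read(r, jn),
                 classify_read(r + shift, jns))
  }
})

test_that("efficiency ratio handles pseudocounts, guards and monotonicity", {
  expect_equal(efficiency_ratio(28, 2, 0), 14)
  expect_equal(efficiency_ratio(0, 0, 0.5), 1)
  expect_true(is.na(efficiency_ratio(100, 0, 0)))
  expect_error(efficiency_ratio(-1, 2), "negative")
  # strictly increasing in spliced, decreasing in unspliced
  expect_true(all(diff(efficiency_ratio(0:20, 5)) > 0))
  expect_true(all(diff(efficiency_ratio(5, 0:20)) < 0))
})

test_that("PSI arithmetic and complementarity", {
  expect_equal(compute_psi(941, 59), 94.1)
  expect_equal(compute_psi(0, 10), 0)
  expect_equal(compute_psi(10, 0), 100)
  expect_true(is.na(compute_psi(0, 0)))
  set.seed(1)
  a <- rpois(20, 50); b <- rpois(20, 5)
  ok <- a + b > 0
  expect_equal(compute_psi(a, b)[ok] + compute_psi(b, a)[ok],
               rep(100, sum(ok)))
})

test_that("intron read percentage counts distinct overlapping reads", {
  reads <- do.call(toy_reads, c(
    lapply(1:19, function(i) list(starts = 210 + i, ends = 240 + i)),
    lapply(1:81, function(i) list(starts = 100 + i %% 50,
                                  ends = 130 + i %% 50))))
  pct <- intron_read_pct(reads, toy_model(), 1)
  expect_equal(unname(pct["s1"]), 100 * 19 / 100)
  expect_equal(unname(intron_read_pct(reads, toy_model(), 2)["s1"]), 0)
  expect_error(intron_read_pct(reads, toy_model(), 99), "no intron")
})

test_that("median-of-ratios size factors match the independent oracle", {
  # proportional samples: factor-2 library sizes, identical normalised values
  a <- c(10, 20, 30, 40)
  two <- rbind(s1 = a, s2 = 2 * a)
  nz <- normalize_expression(two)
  expect_equal(nz$size_factors[2] / nz$size_factors[1], 2)
  expect_equal(nz$values[1, ], nz$values[2, ])
  # single sample
  expect_equal(normalize_expression(matrix(1:5, 1))$size_factors, 1)
  # random NB counts vs hand-computed median-of-ratios
  set.seed(9)
  cnt <- matrix(rnbinom(5 * 60, mu = 50, size = 5), nrow = 5)
  cnt[, 1] <- 0                      # all-zero gene must drop out
  got <- normalize_expression(cnt)$size_factors
  loggeo <- colMeans(log(cnt))
  want <- apply(cnt, 1, function(row)
    exp(median((log(row) - loggeo)[is.finite(loggeo) & row > 0])))
  expect_equal(got, want)
  skip_if_not_installed("DESeq2")
  ds <- DESeq2::estimateSizeFactorsForMatrix(t(cnt))
  expect_equal(unname(got), unname(ds), tolerance = 1e-10)
})

test_that("batch mean-centering removes batch offsets", {
  set.seed(2)
  base <- matrix(rpois(40, 100), nrow = 8, ncol = 5)
  batch <- rep(c("a", "b"), each = 4)
  shifted <- base
  shifted[batch == "b", ] <- shifted[batch == "b", ] * 4
  v <- normalize_expression(shifted, batch = batch)$values
  for (g in 1:5)
    expect_equal(mean(v[batch == "a", g]), mean(v[batch == "b", g]))
})

test_that("count conservation: classes partition the junction neighbourhood", {
  cfg <- small_config()
  sim <- simulate_reads(cfg, animals = 1:3)
  cnt <- count_junctions(sim$reads, sim$model)
  jn <- junctions(sim$model)
  for (k in seq_len(nrow(jn))) {
    nb_lo <- jn$intron_start[k] - 1L
    nb_hi <- jn$intron_end[k] + 1L
    ov <- sim$reads[sim$reads$end >= nb_lo & sim$reads$start <= nb_hi, ]
    n_ov <- tapply(paste(ov$sample_id, ov$read_id), ov$sample_id,
                   function(x) length(unique(x)))
    cj <- cnt[cnt$junction == jn$index[k], ]
    tot <- cj$n_spliced + cj$n_unspliced + cj$n_other
    names(tot) <- cj$sample_id
    expect_equal(tot[names(n_ov)], n_ov,
                 ignore_attr = TRUE)
  }
})

test_that("alternative donor counting recovers reference/alternative reads", {
  cfg <- small_config()
  sim <- simulate_reads(cfg, animals = 1:4)
  ad <- count_alt_donor(sim$reads, sim$model)
  truth <- sim$truth$reads
  focal <- sim$model$alt_donor$intron_index
  for (s in ad$sample_id) {
    ts <- truth[truth$sample_id == s & !is.na(truth$junction) &
                  truth$junction == focal, ]
    expect_equal(ad$n_ref_spliced[ad$sample_id == s],
                 sum(ts$kind == "spliced"))
    expect_equal(ad$n_alt_spliced[ad$sample_id == s],
                 sum(ts$kind == "alt_spliced"))
  }
})
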