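#' Fit a single-marker association model
#'
#' Least-squares fit of `y ~ intercept + X + g` with a two-sided t-test on
#' the dosage coefficient, treating dosage as quantitative (additive).
#' Samples with missing `y` or `g` are dropped pairwise. When
#' `random_group` is supplied, a single random intercept is added and the
#' variance ratio `lambda = var(group) / var(residual)` is estimated by
#' profiled restricted maximum likelihood over one dimension; fixed effects
#' are then the GLS solution at the REML optimum.
#'
#' The variance explained by the marker is reported as
#' `100 * (SSE_reduced - SSE_full) / SSE_reduced`, i.e. relative to the
#' total variance of the covariate-adjusted phenotype (fixed-effects path
#' only; NA under REML, where the decomposition is not uniquely defined).
#'
#' @param y numeric phenotype vector.
#' @param g dosage vector in `{0, 1, 2}` (NA allowed).
#' @param X optional covariate matrix or data.frame (no intercept column;
#'   factors are expanded via [stats::model.matrix()]).
#' @param random_group optional grouping labels for the random intercept.
#' @return list with `beta`, `se`, `p`, `var_explained_pct`, `n`, `lambda`
#'   (REML variance ratio, NA for the fixed-effects fit) and `reason`
#'   (NA; `"monomorphic"` for a skipped constant marker; `"aliased"`, with
#'   `p = 1`, for a marker whose dosage is fully explained by the
#'   covariates, e.g. perfect LD with a conditioned marker).
#' @export
fit_marker_model <- function(y, g, X = NULL, random_group = NULL) {
  stopifnot(length(y) == length(g))
  W <- covariate_matrix(X, length(y))
  keep <- !is.na(y) & !is.na(g) & stats::complete.cases(W)
  y <- y[keep]; g <- g[keep]; W <- W[keep, , drop = FALSE]
  miss <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
               var_explained_pct = NA_real_, n = length(y),
               lambda = NA_real_, reason = NA_character_)
  if (length(unique(g)) < 2) {
    miss$reason <- "monomorphic"
    return(miss)
  }
  qrW <- qr(W)
  if (qrW$rank < ncol(W))
    stop("rank-deficient covariates: ",
         paste(colnames(W)[-seq_len(qrW$rank)], collapse = ", "))
  # marker fully explained by the covariates (e.g. perfect LD with a
  # conditioned marker): no independent information, report p = 1
  g_res <- qr.resid(qrW, g)
  if (sum(g_res^2) < 1e-10 * sum((g - mean(g))^2)) {
    miss$p <- 1
    miss$reason <- "aliased"
    return(miss)
  }
  if (is.null(random_group)) {
    fit_full <- stats::lm.fit(cbind(W, g = g), y)
    df <- length(y) - fit_full$rank
    sse_full <- sum(fit_full$residuals^2)
    sse_red <- sum(qr.resid(qrW, y)^2)
    XtXi <- chol2inv(qr.R(fit_full$qr))
    beta <- fit_full$coefficients[["g"]]
    se <- sqrt(sse_full / df * XtXi[fit_full$rank, fit_full$rank])
    tval <- beta / se
    list(beta = beta, se = se,
         p = 2 * stats::pt(-abs(tval), df),
         var_explained_pct = 100 * (sse_red - sse_full) / sse_red,
         n = length(y), lambda = NA_real_, reason = NA_character_)
  } else {
    grp <- factor(random_group[keep])
    fm <- reml_single_group(y, cbind(W, g = g), grp)
    k <- ncol(W) + 1L
    tval <- fm$beta[k] / fm$se[k]
    df <- length(y) - k
    list(beta = fm$beta[[k]], se = fm$se[[k]],
         p = 2 * stats::pt(-abs(tval), df),
         var_explained_pct = NA_real_, n = length(y),
         lambda = fm$lambda, reason = NA_character_)
  }
}

# Intercept + expanded covariates.
covariate_matrix <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  X <- as.data.frame(X)
  stopifnot(nrow(X) == n)
  stats::model.matrix(~ ., data = X)
}

# Profiled REML for y = W b + Z u + e with u ~ N(0, s2 * lambda I),
# e ~ N(0, s2 I); one-dimensional optimisation of lambda >= 0.
reml_single_group <- function(y, W, group, upper = 50) {
  Z <- stats::model.matrix(~ 0 + group)
  n <- length(y); p <- ncol(W)
  crit <- function(lambda) {
    V <- diag(n) + lambda * tcrossprod(Z)
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_W <- backsolve(cV, forwardsolve(t(cV), W))
    WtViW <- crossprod(W, Vi_W)
    beta <- solve(WtViW, crossprod(Vi_W, y))
    r <- y - W %*% beta
    Vi_r <- Vi_y - Vi_W %*% beta
    s2 <- sum(r * Vi_r) / (n - p)
    ld <- 2 * sum(log(diag(cV)))
    nll <- 0.5 * ((n - p) * log(s2) + ld +
                    determinant(WtViW, logarithm = TRUE)$modulus)
    list(nll = as.numeric(nll), beta = drop(beta), s2 = s2,
         cov = s2 * solve(WtViW))
  }
  opt <- stats::optimise(function(l) crit(l)$nll, c(0, upper))
  lambda <- if (crit(0)$nll <= opt$objective) 0 else opt$minimum
  f <- crit(lambda)
  list(lambda = lambda, beta = f$beta, se = sqrt(diag(f$cov)), s2 = f$s2)
}

#' Association scan across all markers of a genotype matrix
#'
#' Fits [fit_marker_model()] once per marker. With `condition_on`, that
#' marker's dosage is appended to the covariates and the conditioned marker
#' itself is reported as missing (reason `"conditioned"`). With `focal`, an
#' `r2_with_focal` column reports LD of each marker with the focal one.
#'
#' @param y named phenotype vector (names = sample ids) or plain vector in
#'   genotype-matrix sample order.
#' @param genotypes a [genotype_matrix()].
#' @param covariates optional covariate data.frame (rows in sample order or
#'   with matching rownames).
#' @param condition_on,focal optional marker ids.
#' @param random_group optional labels for the REML random intercept.
#' @return data.frame per marker: `marker`, `chrom`, `pos`, `beta`, `se`,
#'   `p`, `var_explained_pct`, `n`, `reason`, `rank` (see [rank_markers()])
#'   and optionally `r2_with_focal`.
#' @export
scan_markers <- function(y, genotypes, covariates = NULL,
                         condition_on = NULL, focal = NULL,
                         random_group = NULL) {
  D <- genotypes$dosage
  if (!is.null(names(y))) {
    common <- intersect(names(y), rownames(D))
    if (length(common) == 0) stop("no samples shared between phenotype and genotypes")
    y <- y[common]; D <- D[common, , drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[common, , drop = FALSE]
    if (!is.null(random_group) && !is.null(names(random_group)))
      random_group <- random_group[common]
  }
  X <- covariates
  if (!is.null(condition_on)) {
    stopifnot(condition_on %in% colnames(D))
    cond <- data.frame(cond_dosage = D[, condition_on])
    X <- if (is.null(X)) cond else cbind(as.data.frame(X), cond)
  }
  m <- genotypes$markers
  res <- lapply(seq_len(ncol(D)), function(j) {
    if (!is.null(condition_on) && m$id[j] == condition_on)
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  var_explained_pct = NA_real_, n = NA_integer_,
                  lambda = NA_real_, reason = "conditioned"))
    fit_marker_model(y, D[, j], X, random_group)
  })
  out <- data.frame(
    marker = m$id, chrom = m$chrom, pos = m$pos,
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    p = vapply(res, `[[`, numeric(1), "p"),
    var_explained_pct = vapply(res, `[[`, numeric(1), "var_explained_pct"),
    n = vapply(res, function(r) as.integer(r$n), integer(1)),
    reason = vapply(res, `[[`, character(1), "reason"))
  if (!is.null(focal)) {
    stopifnot(focal %in% colnames(D))
    out$r2_with_focal <- apply(D, 2, function(g) ld_r2(g, D[, focal]))
  }
  rank_markers(out)
}

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation over pairwise-complete observations;
#' invariant to swapping the ref/alt coding of either marker.
#'
#' @param g1,g2 dosage vectors.
#' @return value in `[0, 1]`, or NA when either marker is monomorphic or
#'   fewer than 3 complete pairs exist.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) return(NA_real_)
  stats::cor(g1[ok], g2[ok])^2
}

#' Kruskal-Wallis rank test of a phenotype across genotype classes
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]); the degenerate
#' all-tied case returns `H = 0, p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 non-empty groups).
#' @return list with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (length(unique(values)) == 1)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Per-genotype-class phenotype summary
#'
#' @param pheno numeric phenotype vector.
#' @param dosage dosage vector in `{0, 1, 2}`.
#' @return data.frame per observed class: `dosage`, `n`, `mean`, `se`
#'   (standard error of the mean), `median`. Empty classes are omitted.
#' @export
genotype_class_summary <- function(pheno, dosage) {
  ok <- !is.na(pheno) & !is.na(dosage)
  pheno <- pheno[ok]; dosage <- dosage[ok]
  stopifnot(all(dosage %in% 0:2))
  cls <- sort(unique(dosage))
  do.call(rbind, lapply(cls, function(d) {
    v <- pheno[dosage == d]
    data.frame(dosage = d, n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)), median = stats::median(v))
  }))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

#' Rank association results by significance
#'
#' Ascending p-value; ties broken by genomic position, then marker id.
#' Results with missing p (monomorphic or conditioned markers) are unranked.
#'
#' @param results data.frame with columns `p`, `pos`, `marker`.
#' @return `results` with a `rank` column (1-based; NA where p is missing).
#' @export
rank_markers <- function(results) {
  ranked <- which(!is.na(results$p))
  o <- ranked[order(results$p[ranked], results$pos[ranked],
                    results$marker[ranked])]
  results$rank <- NA_integer_
  results$rank[o] <- seq_along(o)
  results
}
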