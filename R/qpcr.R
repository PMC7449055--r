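#' Read a qPCR plate table
#'
#' Expected CSV columns: `sample_id`, `allele` (`K`/`A`, blank for curve
#' wells), `assay_id`, `assay_role` (`spliced`, `unspliced`, `reference`),
#' `junction` (blank for reference assays), `well`, `cq`, `dilution`
#' (relative concentration for standard-curve wells, blank for experimental
#' wells).
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
read_qpcr_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "allele", "assay_id", "assay_role", "junction",
            "well", "cq", "dilution")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols))
    stop("plate is missing column(s): ", paste(missing_cols, collapse = ", "))
  stopifnot(all(plate$cq > 0, na.rm = TRUE),
            all(plate$dilution > 0, na.rm = TRUE))
  plate
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Cq on log10(relative concentration) over the
#' serial-dilution wells of one assay. Amplification efficiency is derived
#' as `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle, slope
#' -3.3219). Curves with non-negative slope or efficiency outside
#' (0.7, 1.2) are flagged invalid with a warning.
#'
#' @param cq quantification cycles of the curve wells.
#' @param dilution relative concentrations (e.g. `1, 1/5, 1/25, ...`);
#'   at least 3 distinct values.
#' @return list: `slope`, `intercept`, `efficiency`, `r_squared`, `valid`.
#' @export
fit_standard_curve <- function(cq, dilution) {
  ok <- !is.na(cq) & !is.na(dilution)
  cq <- cq[ok]; dilution <- dilution[ok]
  if (length(unique(dilution)) < 3)
    stop("need >= 3 distinct dilutions for a standard curve")
  fit <- stats::lm(cq ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  eff <- if (slope < 0) 10^(-1 / slope) - 1 else NA_real_
  valid <- !is.na(eff) && eff > 0.7 && eff < 1.2
  if (!valid)
    warning("standard curve flagged invalid (slope ", signif(slope, 4),
            ", efficiency ", signif(eff, 4), ")")
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       efficiency = eff, r_squared = r2, valid = valid)
}

#' Fit standard curves for every assay on a plate
#'
#' @param plate a plate table (see [read_qpcr_plate()]); curve wells are the
#'   rows with a non-missing `dilution`.
#' @return named list of [fit_standard_curve()] results, one per assay.
#' @export
fit_standard_curves <- function(plate) {
  curves <- plate[!is.na(plate$dilution), ]
  if (nrow(curves) == 0) stop("plate contains no standard-curve wells")
  lapply(split(curves, curves$assay_id),
         function(d) fit_standard_curve(d$cq, d$dilution))
}

#' Relative expression by the standard-curve method
#'
#' Each well's quantity is interpolated from its assay's standard curve,
#' `10^((cq - intercept) / slope)`; quantities are averaged over replicate
#' wells per sample x assay and divided by the geometric mean of that
#' sample's reference-assay quantities (endogenous control and transfection
#' control by default; restrict with `reference_assays`). Samples missing
#' any reference assay are dropped with a message.
#'
#' @param plate a plate table (experimental wells: `dilution` missing).
#' @param curves output of [fit_standard_curves()].
#' @param reference_assays assay ids to normalise by; defaults to all
#'   assays with `assay_role == "reference"`.
#' @return data.frame per sample x assay: `sample_id`, `allele`,
#'   `assay_id`, `assay_role`, `junction`, `quantity` (pre-normalisation
#'   mean), `rel_expr` (normalised).
#' @export
relative_expression <- function(plate, curves, reference_assays = NULL) {
  wells <- plate[is.na(plate$dilution), ]
  if (is.null(reference_assays))
    reference_assays <- unique(wells$assay_id[wells$assay_role == "reference"])
  stopifnot(length(reference_assays) >= 1)
  absent <- setdiff(unique(wells$assay_id), names(curves))
  if (length(absent))
    stop("no standard curve for assay(s): ", paste(absent, collapse = ", "))
  q <- vapply(seq_len(nrow(wells)), function(i) {
    cv <- curves[[wells$assay_id[i]]]
    10^((wells$cq[i] - cv$intercept) / cv$slope)
  }, numeric(1))
  jn <- ifelse(is.na(wells$junction), "", as.character(wells$junction))
  al <- ifelse(is.na(wells$allele), "", as.character(wells$allele))
  agg <- stats::aggregate(
    q, by = list(sample_id = wells$sample_id, allele = al,
                 assay_id = wells$assay_id, assay_role = wells$assay_role,
                 junction = jn),
    FUN = mean)
  names(agg)[names(agg) == "x"] <- "quantity"
  agg$junction <- suppressWarnings(as.numeric(agg$junction))
  refgeo <- vapply(split(agg, agg$sample_id), function(d) {
    rq <- d$quantity[d$assay_id %in% reference_assays]
    if (length(rq) < length(reference_assays)) return(NA_real_)
    exp(mean(log(rq)))
  }, numeric(1))
  agg$rel_expr <- agg$quantity / refgeo[agg$sample_id]
  dropped <- unique(agg$sample_id[is.na(agg$rel_expr)])
  if (length(dropped)) {
    message("dropping sample(s) missing reference assays: ",
            paste(dropped, collapse = ", "))
    agg <- agg[!agg$sample_id %in% dropped, ]
  }
  agg[order(agg$sample_id, agg$assay_id), ]
}

#' Per-sample splicing ratio from spliced and unspliced expression
#'
#' @param spliced_expr,unspliced_expr normalised expression values per
#'   sample (vectorised). Zero or missing unspliced expression yields NA.
#' @return `spliced_expr / unspliced_expr`.
#' @export
splicing_ratio_per_sample <- function(spliced_expr, unspliced_expr) {
  out <- spliced_expr / unspliced_expr
  out[!is.finite(out) | unspliced_expr <= 0] <- NA_real_
  out
}

#' Two-sample allele contrast
#'
#' Student's (pooled-variance) t-test by default, Welch by request, two
#' sided, with a Bonferroni-adjusted significance flag.
#'
#' @param values_k,values_a numeric vectors (>= 2 values each).
#' @param test `"student"` or `"welch"`.
#' @param n_tests Bonferroni family size for the significance flag.
#' @param alpha family-wise error rate.
#' @return list: `t`, `df`, `p`, `mean_k`, `mean_a`, `significant`.
#' @export
allele_contrast <- function(values_k, values_a,
                            test = c("student", "welch"), n_tests = 1,
                            alpha = 0.05) {
  test <- match.arg(test)
  values_k <- values_k[!is.na(values_k)]
  values_a <- values_a[!is.na(values_a)]
  if (length(values_k) < 2 || length(values_a) < 2)
    stop("need >= 2 values per allele group")
  df0 <- length(values_k) + length(values_a) - 2
  if (stats::sd(c(values_k, values_a)) == 0) {
    tt <- list(statistic = 0, parameter = df0, p.value = 1)
  } else if (stats::sd(values_k) == 0 && stats::sd(values_a) == 0) {
    # distinct constants per group (e.g. noise-free simulation): the
    # difference is exact
    tt <- list(statistic = sign(mean(values_k) - mean(values_a)) * Inf,
               parameter = df0, p.value = 0)
  } else {
    tt <- stats::t.test(values_k, values_a, var.equal = test == "student")
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_k = mean(values_k), mean_a = mean(values_a),
       significant = tt$p.value < bonferroni_threshold(alpha, n_tests))
}

#' Junction-level splicing summary of a mini-gene qPCR plate
#'
#' Full plate analysis: standard curves, relative expression, per-sample
#' splicing ratios, then per junction three measurement blocks (splicing
#' ratio, spliced expression, unspliced expression) with allele means, the
#' spread across samples, and the allele contrast p-value.
#'
#' @param plate a plate table (see [read_qpcr_plate()]).
#' @param n_tests Bonferroni family size (default 12: 3 measurement types x
#'   4 junctions).
#' @param test passed to [allele_contrast()].
#' @param reference_assays passed to [relative_expression()].
#' @return data.frame per junction x measurement: `junction`,
#'   `measurement`, `mean_k`, `sd_k`, `mean_a`, `sd_a`, `p`, `significant`.
#' @export
qpcr_splicing_table <- function(plate, n_tests = 12, test = "student",
                                reference_assays = NULL) {
  curves <- fit_standard_curves(plate)
  rel <- relative_expression(plate, curves, reference_assays)
  tgt <- rel[rel$assay_role %in% c("spliced", "unspliced"), ]
  wide <- stats::reshape(
    tgt[, c("sample_id", "allele", "junction", "assay_role", "rel_expr")],
    idvar = c("sample_id", "allele", "junction"),
    timevar = "assay_role", direction = "wide")
  names(wide) <- sub("^rel_expr\\.", "", names(wide))
  wide$ratio <- splicing_ratio_per_sample(wide$spliced, wide$unspliced)
  rows <- list()
  for (j in sort(unique(wide$junction))) {
    dj <- wide[wide$junction == j, ]
    for (meas in c("ratio", "spliced", "unspliced")) {
      vk <- dj[[meas]][dj$allele == "K"]
      va <- dj[[meas]][dj$allele == "A"]
      ct <- allele_contrast(vk, va, test = test, n_tests = n_tests)
      rows[[length(rows) + 1]] <- data.frame(
        junction = j, measurement = meas,
        mean_k = mean(vk, na.rm = TRUE), sd_k = stats::sd(vk, na.rm = TRUE),
        mean_a = mean(va, na.rm = TRUE), sd_a = stats::sd(va, na.rm = TRUE),
        p = ct$p, significant = ct$significant)
    }
  }
  do.call(rbind, rows)
}
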