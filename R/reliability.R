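#' Paired-samples t-test for dual-angle comparisons
#'
#' Two-sided paired t-test on per-site measurements taken under two imaging
#' conditions.  Differences are `values_1 - values_0`, so a positive t
#' means the second condition reads larger.  Degenerate inputs are handled
#' explicitly: all differences exactly zero gives `t = 0, p = 1` (flagged
#' `"zero_variance"`); identical nonzero differences give `p = 0` with the
#' same flag, since no finite t statistic exists.
#'
#' @param values_0 Numeric vector, condition 0 (e.g. alpha = 0 degrees).
#' @param values_1 Numeric vector of equal length, condition 1.
#' @return A list with `t`, `df`, `p`, `n`, `mean_diff`, `flag`.
#' @export
#' @examples
#' paired_t_test(c(1, 2, 3), c(2, 4, 6))
paired_t_test <- function(values_0, values_1) {
  if (!is.numeric(values_0) || !is.numeric(values_1) ||
      length(values_0) != length(values_1)) {
    stop_input("paired samples must be numeric vectors of equal length")
  }
  keep <- is.finite(values_0) & is.finite(values_1)
  values_0 <- values_0[keep]; values_1 <- values_1[keep]
  n <- length(values_0)
  if (n < 2L) stop_degenerate("paired t-test needs at least 2 complete pairs (got %d)", n)
  d <- values_1 - values_0
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1L, p = 1, n = n, mean_diff = 0,
                  flag = "zero_variance"))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1L, p = 0, n = n,
                mean_diff = mean(d), flag = "zero_variance"))
  }
  ht <- stats::t.test(values_1, values_0, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       n = n, mean_diff = mean(d), flag = "ok")
}

# Coerce reliability input to a sites x examiners x repeats array.
# Accepts a matrix (repeats = 1) or a 3D array.
as_reading_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L || !is.numeric(x)) {
    stop_input("readings must be a sites x examiners matrix or a sites x examiners x repeats array")
  }
  x
}

# Balanced two-way mean squares (sites x raters, one observation per cell)
# via the standard linear-model ANOVA decomposition.
twoway_ms <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   site = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; suppress the F-test warning emitted on
  # perfect (zero-residual) fits
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ site + rater, data = df)))
  list(msr = tab["site", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"],
       n = n, k = k)
}

#' Inter-examiner reliability: ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement intraclass
#' correlation coefficient for a sites-by-examiners grid, with the F-based
#' 95 % confidence interval of Shrout & Fleiss / McGraw & Wong.  Both sites
#' and examiners are treated as random samples, matching a blinded
#' multi-reader design.  When repeated reads are supplied (third array
#' dimension) they are averaged within examiner first, so the coefficient
#' describes agreement between examiners' single (averaged) readings.
#'
#' @param readings Sites x examiners numeric matrix, or a sites x examiners
#'   x repeats array.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list with `icc`, `ci_low`, `ci_high`, `n`, `k`, `flag`.  With
#'   no between-site variance the ICC is undefined and returned as `NaN`
#'   with flag `"no_between_site_variance"`.
#' @export
icc_inter <- function(readings, conf_level = 0.95) {
  arr <- as_reading_array(readings)
  mat <- apply(arr, c(1, 2), mean)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop_input("inter-examiner ICC needs >= 2 examiners (got %d)", k)
  if (n < 2L) stop_input("inter-examiner ICC needs >= 2 sites (got %d)", n)
  if (anyNA(mat)) stop_input("inter-examiner ICC requires a complete grid")
  if (stats::var(rowMeans(mat)) == 0 && twoway_ms(mat)$msr <= .Machine$double.eps) {
    return(list(icc = NaN, ci_low = NaN, ci_high = NaN, n = n, k = k,
                flag = "no_between_site_variance"))
  }
  ms <- twoway_ms(mat)
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  alpha <- 1 - conf_level
  # McGraw & Wong (1996) interval for the single-measure agreement ICC
  if (ms$mse > 0) {
    fj <- ms$msc / ms$mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (ms$msr - f_l * ms$mse) /
      (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    upper <- n * (f_u * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
  } else {
    lower <- upper <- icc          # perfect agreement: degenerate interval
  }
  list(icc = icc, ci_low = lower, ci_high = upper, n = n, k = k, flag = "ok")
}

oneway_ms <- function(mat) {
  n <- nrow(mat); r <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   site = factor(rep(seq_len(n), times = r)))
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ site, data = df)))
  list(msb = tab["site", "Mean Sq"], msw = tab["Residuals", "Mean Sq"],
       n = n, r = r)
}

icc_oneway <- function(mat, conf_level = 0.95) {
  n <- nrow(mat); r <- ncol(mat)
  if (anyNA(mat)) stop_input("intra-examiner ICC requires complete repeats")
  ms <- oneway_ms(mat)
  if (ms$msb <= .Machine$double.eps && ms$msw <= .Machine$double.eps) {
    return(list(icc = NaN, ci_low = NaN, ci_high = NaN, n = n, r = r,
                flag = "no_between_site_variance"))
  }
  icc <- (ms$msb - ms$msw) / (ms$msb + (r - 1) * ms$msw)
  alpha <- 1 - conf_level
  if (ms$msw > 0) {
    fobs <- ms$msb / ms$msw
    f_l <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (r - 1))
    f_u <- fobs * stats::qf(1 - alpha / 2, n * (r - 1), n - 1)
    lower <- (f_l - 1) / (f_l + r - 1)
    upper <- (f_u - 1) / (f_u + r - 1)
  } else {
    lower <- upper <- icc
  }
  list(icc = icc, ci_low = lower, ci_high = upper, n = n, r = r, flag = "ok")
}

#' Intra-examiner reliability: one-way single-measure ICC
#'
#' For each examiner, the one-way random-effects single-measure ICC across
#' that examiner's repeated blinded reads of the same sites, with its
#' F-based confidence interval; plus a pooled value averaged over examiners
#' (weighted by site count).
#'
#' @param readings Sites x examiners x repeats numeric array with >= 2
#'   repeats.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `per_examiner` (data frame of `examiner`, `icc`,
#'   `ci_low`, `ci_high`, `n`, `flag`) and `pooled`.
#' @export
icc_intra <- function(readings, conf_level = 0.95) {
  arr <- as_reading_array(readings)
  if (dim(arr)[3] < 2L) {
    stop_input("intra-examiner ICC needs >= 2 repeats per examiner (got %d)", dim(arr)[3])
  }
  per <- lapply(seq_len(dim(arr)[2]), function(e) {
    res <- icc_oneway(arr[, e, , drop = TRUE], conf_level = conf_level)
    data.frame(examiner = e, icc = res$icc, ci_low = res$ci_low,
               ci_high = res$ci_high, n = res$n, flag = res$flag,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- is.finite(per$icc)
  pooled <- if (any(ok)) {
    stats::weighted.mean(per$icc[ok], w = per$n[ok])
  } else {
    NaN
  }
  list(per_examiner = per, pooled = pooled)
}

#' Percent change between two condition means
#'
#' `100 * (mean_1 - mean_0) / mean_0`, rounded by default to 0.1 % to match
#' reporting conventions.
#'
#' @param mean_0 Baseline mean (nonzero).
#' @param mean_1 Comparison mean.
#' @param round Round the result to 0.1 (default `TRUE`); set `FALSE` for
#'   full precision.
#' @return Percent change.
#' @export
#' @examples
#' percent_change(7.0, 7.8)    # 11.4
#' percent_change(31.4, 31.6)  # 0.6
percent_change <- function(mean_0, mean_1, round = TRUE) {
  if (!is.numeric(mean_0) || !is.numeric(mean_1)) {
    stop_input("means must be numeric")
  }
  if (any(mean_0 == 0)) stop_degenerate("percent change undefined for a zero baseline mean")
  pc <- 100 * (mean_1 - mean_0) / mean_0
  if (round) round_report(pc) else pc
}

#' Predicted mean under uniform projection scaling
#'
#' If a projection change scales every vertical distance by the same factor,
#' the expected mean of any distance metric under the new condition is the
#' baseline mean times the scale ratio observed on another distance (such as
#' tooth length).  Used to check whether an observed bone-level inflation is
#' consistent with pure uniform elongation.
#'
#' @param mean_0 Baseline mean of the metric of interest (e.g. RBL in mm).
#' @param ref_0,ref_1 Means of a reference distance under the baseline and
#'   changed condition (e.g. tooth length at 0 and 30 degrees).
#' @return Predicted mean of the metric under the changed condition.
#' @export
#' @examples
#' scaled_mean_prediction(7.0, 22.1, 24.7)  # ~7.8 mm
scaled_mean_prediction <- function(mean_0, ref_0, ref_1) {
  if (!is_number(mean_0) || !is_number(ref_0) || !is_number(ref_1)) {
    stop_input("all arguments must be single finite numbers")
  }
  if (ref_0 <= 0) stop_degenerate("reference baseline mean must be > 0")
  mean_0 * ref_1 / ref_0
}

METRIC_LEVELS <- c("length", "rbl", "rel_rbl")

validate_readings <- function(readings) {
  need <- c("site", "examiner", "repeat", "angle", "metric", "value")
  if (!is.data.frame(readings) || !all(need %in% names(readings))) {
    stop_input("readings must be a long-format data frame with columns %s",
               paste(need, collapse = ", "))
  }
  if (nrow(readings) == 0L) stop_input("readings are empty")
  readings
}

#' Summarize a dual-angle study
#'
#' Reduces a long-format reading table (site, examiner, repeat, angle,
#' metric, value) to the study-summary layout: per metric the mean and SD of
#' per-site values at each angle, the paired t-test across angles (pairing
#' per-site means over examiners and repeats), and the percent change of the
#' means.  Sites present at only one angle are dropped with a message.
#'
#' @param readings Long-format data frame; `angle` must take exactly two
#'   distinct values.
#' @return A data frame of class `relrbl_study_summary` with one row per
#'   metric: `metric`, `mean_0`, `sd_0`, `mean_1`, `sd_1`, `n`, `t`, `df`,
#'   `p_value`, `percent_change`, `flag`, plus attributes `angles`.
#' @export
summarize_study <- function(readings) {
  readings <- validate_readings(readings)
  readings <- readings[is.finite(readings$value), , drop = FALSE]
  angles <- sort(unique(readings$angle))
  if (length(angles) != 2L) {
    stop_input("expected exactly 2 angle conditions, found %d", length(angles))
  }
  metrics <- intersect(METRIC_LEVELS, unique(readings$metric))
  rows <- lapply(metrics, function(m) {
    sub <- readings[readings$metric == m, , drop = FALSE]
    # per-site mean over examiners and repeats, per angle
    agg <- stats::aggregate(value ~ site + angle, data = sub, FUN = mean)
    w0 <- agg[agg$angle == angles[1], c("site", "value")]
    w1 <- agg[agg$angle == angles[2], c("site", "value")]
    common <- intersect(w0$site, w1$site)
    dropped <- length(union(w0$site, w1$site)) - length(common)
    if (dropped > 0L) {
      message(sprintf("metric '%s': dropped %d unpaired site(s)", m, dropped))
    }
    v0 <- w0$value[match(common, w0$site)]
    v1 <- w1$value[match(common, w1$site)]
    tt <- paired_t_test(v0, v1)
    data.frame(metric = m,
               mean_0 = mean(v0), sd_0 = stats::sd(v0),
               mean_1 = mean(v1), sd_1 = stats::sd(v1),
               n = length(common), t = tt$t, df = tt$df, p_value = tt$p,
               percent_change = percent_change(mean(v0), mean(v1), round = FALSE),
               flag = tt$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "angles") <- angles
  class(out) <- c("relrbl_study_summary", "data.frame")
  out
}

#' @export
print.relrbl_study_summary <- function(x, ...) {
  angles <- attr(x, "angles")
  cat(sprintf("Study summary: angle %s vs %s (N = %d sites)\n",
              format(angles[1]), format(angles[2]), x$n[1]))
  lab <- c(length = "Tooth length (mm)", rbl = "RBL (mm)", rel_rbl = "relRBL (%)")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-18s %6.1f (SD %4.1f) -> %6.1f (SD %4.1f)  change %+.1f %%  p = %s\n",
                lab[[x$metric[i]]],
                round_report(x$mean_0[i]), round_report(x$sd_0[i]),
                round_report(x$mean_1[i]), round_report(x$sd_1[i]),
                round_report(x$percent_change[i]),
                format.pval(x$p_value[i], digits = 3, eps = 1e-3)))
  }
  invisible(x)
}

# Long readings -> sites x examiners x repeats array for one metric,
# stacking the angle conditions as extra site rows (each image is read
# independently, so a site-at-angle is one reliability unit).
readings_to_array <- function(readings, metric) {
  sub <- readings[readings$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0L) stop_input("no readings for metric '%s'", metric)
  unit <- interaction(sub$site, sub$angle, drop = TRUE)
  ex <- sort(unique(sub$examiner))
  rep_ <- sort(unique(sub[["repeat"]]))
  arr <- array(NA_real_, dim = c(nlevels(unit), length(ex), length(rep_)),
               dimnames = list(levels(unit), ex, rep_))
  arr[cbind(as.integer(unit),
            match(sub$examiner, ex),
            match(sub[["repeat"]], rep_))] <- sub$value
  arr
}

#' Examiner reliability report for a study
#'
#' Computes inter-examiner ICC(2,1) and per-examiner (plus pooled)
#' intra-examiner one-way ICCs for each metric in a long-format reading
#' table.  Each site-at-angle combination is one reliability unit.
#'
#' @param readings Long-format data frame (site, examiner, repeat, angle,
#'   metric, value).
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return A data frame of class `relrbl_reliability` with one row per
#'   metric: inter ICC with CI, pooled intra ICC, and counts.
#' @export
reliability_report <- function(readings, conf_level = 0.95) {
  readings <- validate_readings(readings)
  metrics <- intersect(METRIC_LEVELS, unique(readings$metric))
  rows <- lapply(metrics, function(m) {
    arr <- readings_to_array(readings, m)
    arr <- arr[stats::complete.cases(matrix(arr, nrow = dim(arr)[1])), , ,
               drop = FALSE]
    inter <- if (dim(arr)[2] >= 2L) {
      icc_inter(arr, conf_level = conf_level)
    } else {
      warn_relrbl("metric '%s': fewer than 2 examiners, inter-ICC skipped", m)
      list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           n = dim(arr)[1], k = dim(arr)[2], flag = "skipped")
    }
    intra <- if (dim(arr)[3] >= 2L) {
      icc_intra(arr, conf_level = conf_level)
    } else {
      list(per_examiner = NULL, pooled = NA_real_)
    }
    data.frame(metric = m,
               icc_inter = inter$icc, inter_ci_low = inter$ci_low,
               inter_ci_high = inter$ci_high,
               icc_intra_pooled = intra$pooled,
               n_units = dim(arr)[1], n_examiners = dim(arr)[2],
               n_repeats = dim(arr)[3], flag = inter$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("relrbl_reliability", "data.frame")
  out
}

#' @export
print.relrbl_reliability <- function(x, ...) {
  cat("Examiner reliability (ICC)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s inter ICC(2,1) = %.2f (95%% CI %.2f-%.2f), intra (pooled) = %.2f  [n = %d units, %d examiners x %d reads]\n",
                x$metric[i], x$icc_inter[i], x$inter_ci_low[i],
                x$inter_ci_high[i], x$icc_intra_pooled[i],
                x$n_units[i], x$n_examiners[i], x$n_repeats[i]))
  }
  invisible(x)
}
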