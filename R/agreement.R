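# Method-comparison and observer-repeatability statistics: Pearson
# correlation, two-way consistency ICC with its F-based confidence
# interval, Bland-Altman bias and 95% limits of agreement (absolute and
# percentage), and the coefficient of repeatability.

#' Paired measurements
#'
#' @param a,b numeric vectors of the same length (>= 3), same units:
#'   measurement A and measurement B on the same subjects.
#' @param subjects optional subject identifiers.
#' @return a `paired_measurements` object.
#' @export
paired_measurements <- function(a, b, subjects = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired measurements")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("paired measurements must be finite")
  if (is.null(subjects)) subjects <- seq_along(a)
  if (length(subjects) != length(a))
    stop("subjects must match measurement length")
  structure(list(subjects = subjects, a = a, b = b),
            class = "paired_measurements")
}

as_pairs <- function(pairs, b = NULL, subjects = NULL) {
  if (inherits(pairs, "paired_measurements")) return(pairs)
  paired_measurements(pairs, b, subjects)
}

#' Pearson correlation of paired measurements
#'
#' Standard product-moment correlation with the two-sided p-value from the
#' t transform on n - 2 degrees of freedom.
#'
#' @param pairs a [paired_measurements()] (or vector `a` with `b` given).
#' @param b second measurement vector when `pairs` is a plain vector.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(pairs, b = NULL) {
  p <- as_pairs(pairs, b)
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(p$a, p$b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(p$a))
}

#' Reliability band for an ICC value
#'
#' Cut-points applied half-open: below 0.5 poor; 0.5 up to (but excluding)
#' 0.75 moderate; 0.75 up to (but excluding) 0.9 good; 0.9 and above
#' excellent.
#'
#' @param icc intraclass correlation estimate.
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
reliability_band <- function(icc) {
  if (!is.finite(icc)) return(NA_character_)
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Two-way consistency intraclass correlation, single measurement
#'
#' ICC from the two-way model (subjects and raters/methods both crossed),
#' consistency definition, single-measurement form — ICC(C,1) in the
#' McGraw-Wong taxonomy:
#' `(MS_subjects - MS_error) / (MS_subjects + (k - 1) * MS_error)`
#' where the mean squares come from the two-way ANOVA decomposition into
#' subject, rater and residual terms. Consistency ignores systematic
#' offsets between raters (the rater mean square does not enter). The 95%
#' confidence interval uses the standard F-distribution interval for this
#' form.
#'
#' @param mat numeric matrix, subjects in rows, raters/methods in columns;
#'   complete, >= 3 subjects, >= 2 raters.
#' @param conf confidence level for the interval.
#' @return list with `icc`, `ci` (length 2), `band`, `ms_subjects`,
#'   `ms_raters`, `ms_error`, `n`, `k`.
#' @export
icc_consistency <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (k < 2L) stop("need at least 2 raters")
  if (n < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(mat))) stop("incomplete or non-finite rating matrix")

  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  # a perfect fit (identical raters) triggers a harmless precision warning
  # in anova's F machinery; the degenerate case is handled explicitly below
  an <- suppressWarnings(stats::anova(stats::lm(y ~ subject + rater,
                                                data = df)))
  msr <- an["subject", "Mean Sq"]
  msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]

  if (mse <= .Machine$double.eps * max(msr, 1)) {
    # perfect consistency (zero residual): estimate and interval collapse
    return(list(icc = 1, ci = c(1, 1), band = "excellent",
                ms_subjects = msr, ms_raters = msc, ms_error = mse,
                n = n, k = k))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse)
  alpha <- 1 - conf
  Fobs <- msr / mse
  df1 <- n - 1; df2 <- (n - 1) * (k - 1)
  FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
  FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
  ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
  list(icc = icc, ci = ci, band = reliability_band(icc),
       ms_subjects = msr, ms_raters = msc, ms_error = mse, n = n, k = k)
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Differences are `b - a` (or pairwise percentage differences
#' `100 * (b - a) / mean(a, b)` when `percent = TRUE`); the bias is their
#' mean and the limits of agreement are `bias +/- 1.96 * sd` with the
#' sample (n - 1) standard deviation.
#'
#' @param pairs a [paired_measurements()] (or vector `a` with `b` given).
#' @param b second measurement vector when `pairs` is a plain vector.
#' @param percent compute on pairwise percentage differences?
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `percent`,
#'   `n`.
#' @export
bland_altman <- function(pairs, b = NULL, percent = FALSE) {
  p <- as_pairs(pairs, b)
  d <- if (percent) 100 * (p$b - p$a) / ((p$a + p$b) / 2) else p$b - p$a
  if (percent && any(p$a + p$b == 0))
    stop("percentage differences undefined where a + b = 0")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, percent = percent, n = length(d))
}

#' Coefficient of repeatability
#'
#' The value below which the absolute difference between two repeated
#' measurements is expected to fall with 95% probability. The default
#' `"sd"` form is `1.96 * sd(differences)` (sample sd); the `"anova"` form
#' is `1.96 * sqrt(2) * s_w` with the within-subject standard deviation
#' `s_w = sqrt(sum(d^2) / (2n))` from the one-way within-subject ANOVA for
#' two replicates, which additionally absorbs any systematic bias. Also
#' reported as a percentage of the grand mean of all measurements.
#'
#' @param pairs a [paired_measurements()] (or vector `a` with `b` given).
#' @param b second measurement vector when `pairs` is a plain vector.
#' @param method `"sd"` (default) or `"anova"`.
#' @return list with `cr`, `cr_percent_of_mean`, `grand_mean`, `method`.
#' @export
coefficient_of_repeatability <- function(pairs, b = NULL,
                                         method = c("sd", "anova")) {
  p <- as_pairs(pairs, b)
  method <- match.arg(method)
  d <- p$b - p$a
  cr <- switch(method,
               sd = 1.96 * stats::sd(d),
               anova = 1.96 * sqrt(2) * sqrt(sum(d^2) / (2 * length(d))))
  gm <- mean(c(p$a, p$b))
  pct <- if (abs(gm) < .Machine$double.eps) {
    warning("grand mean is zero: percentage coefficient undefined")
    NA_real_
  } else 100 * cr / gm
  list(cr = cr, cr_percent_of_mean = pct, grand_mean = gm, method = method)
}

#' Full agreement report for two measurement methods
#'
#' Bundles the whole comparison battery for matched per-subject results
#' from two methods (or two observers): means, Pearson correlation,
#' two-way consistency ICC with confidence interval and reliability band,
#' Bland-Altman bias and limits of agreement in absolute and percentage
#' form, coefficient of repeatability, and the paired two-sided t-test of
#' the method means.
#'
#' @param a,b numeric vectors of per-subject results, matched by position
#'   or by `subjects`.
#' @param subjects optional subject identifiers (must match between `a`
#'   and `b` by construction).
#' @param conf confidence level for the ICC interval.
#' @return an `agreement_report` list.
#' @export
compare_methods <- function(a, b, subjects = NULL, conf = 0.95) {
  p <- as_pairs(a, b, subjects)
  icc <- icc_consistency(cbind(p$a, p$b), conf = conf)
  ba <- bland_altman(p)
  bap <- bland_altman(p, percent = TRUE)
  cr <- coefficient_of_repeatability(p)
  tt <- stats::t.test(p$b - p$a)
  structure(list(
    n = length(p$a),
    mean_a = mean(p$a), sd_a = stats::sd(p$a),
    mean_b = mean(p$b), sd_b = stats::sd(p$b),
    pearson = pearson_r(p),
    icc = icc$icc, icc_ci = icc$ci, reliability_band = icc$band,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    sd_diff = ba$sd_diff,
    percent_bias = bap$bias, percent_loa_low = bap$loa_low,
    percent_loa_high = bap$loa_high,
    cr = cr$cr, cr_percent_of_mean = cr$cr_percent_of_mean,
    paired_t_p = tt$p.value),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> n =", x$n, "\n")
  cat(sprintf("  A: %.4g +/- %.4g   B: %.4g +/- %.4g\n",
              x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson$r, x$pearson$p))
  cat(sprintf("  ICC(C,1) = %.3f (95%% CI %.3f-%.3f), %s\n",
              x$icc, x$icc_ci[1], x$icc_ci[2], x$reliability_band))
  cat(sprintf("  bias = %.4g (LoA %.4g to %.4g)\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  CR = %.4g (%.1f%% of mean), paired t p = %.3g\n",
              x$cr, x$cr_percent_of_mean, x$paired_t_p))
  invisible(x)
}

#' @export
as.data.frame.agreement_report <- function(x, ...) {
  data.frame(n = x$n, mean_a = x$mean_a, sd_a = x$sd_a,
             mean_b = x$mean_b, sd_b = x$sd_b,
             pearson_r = x$pearson$r, pearson_p = x$pearson$p,
             icc = x$icc, icc_ci_low = x$icc_ci[1],
             icc_ci_high = x$icc_ci[2],
             reliability_band = x$reliability_band,
             bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
             sd_diff = x$sd_diff,
             percent_bias = x$percent_bias,
             percent_loa_low = x$percent_loa_low,
             percent_loa_high = x$percent_loa_high,
             cr = x$cr, cr_percent_of_mean = x$cr_percent_of_mean,
             paired_t_p = x$paired_t_p, stringsAsFactors = FALSE)
}

#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the bias
#' (solid) and 95% limits of agreement (dashed) drawn as horizontal lines.
#'
#' @param a,b paired measurement vectors.
#' @param percent plot percentage differences?
#' @param file optional PNG path; when given the plot is written to disk.
#' @param main plot title.
#' @return the [bland_altman()] statistics, invisibly.
#' @export
bland_altman_plot <- function(a, b, percent = FALSE, file = NULL,
                              main = "Bland-Altman") {
  p <- as_pairs(a, b)
  ba <- bland_altman(p, percent = percent)
  m <- (p$a + p$b) / 2
  d <- if (percent) 100 * (p$b - p$a) / m else p$b - p$a
  if (!is.null(file)) grDevices::png(file, width = 640, height = 480)
  graphics::plot(m, d, pch = 19, xlab = "Mean of methods",
                 ylab = if (percent) "Difference (%)" else "Difference",
                 main = main)
  graphics::abline(h = ba$bias, col = "blue", lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), col = "red", lty = 2)
  if (!is.null(file)) grDevices::dev.off()
  invisible(ba)
}
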