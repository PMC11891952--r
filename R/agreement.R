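#' Paired manual-vs-automated counts
#'
#' @param rater_a,rater_b Non-negative integer count vectors of equal length
#'   (>= 2): the manual and automated counts per image.
#' @param labels Optional image identifiers.
#' @return A tibble with columns `label`, `manual`, `automated`.
#' @export
paired_counts <- function(rater_a, rater_b, labels = NULL) {
  if (length(rater_a) != length(rater_b) || length(rater_a) < 2) {
    abort("need two equal-length count vectors of length >= 2.",
      class = "fc_invalid_input"
    )
  }
  if (any(c(rater_a, rater_b) < 0)) {
    abort("counts must be non-negative.", class = "fc_invalid_input")
  }
  if (is.null(labels)) labels <- as.character(seq_along(rater_a))
  tibble(label = labels, manual = as.numeric(rater_a), automated = as.numeric(rater_b))
}

# two-way (subjects x raters) ANOVA mean squares
two_way_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Two-way intraclass correlation (absolute agreement, average measures)
#'
#' The ICC of a subjects-by-raters table under the two-way random-effects
#' model with absolute agreement, average of the k raters' measurements —
#' ICC(A,k) in the McGraw-Wong taxonomy:
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' with MSR/MSC/MSE the row (subject), column (rater) and error mean
#' squares. The absolute-agreement form penalises a systematic bias between
#' raters, unlike the consistency form. The 95% CI follows the standard
#' F-based construction (single-measure bounds transformed by the
#' Spearman-Brown step-up), and the p-value is from `F = MSR / MSE` on
#' `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' A table with zero total variance (all values identical) has ICC defined
#' as 1 with a degenerate CI.
#'
#' @param data A data frame with columns `manual` and `automated` (as from
#'   [paired_counts()]), or a numeric matrix with one column per rater.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `fc_icc` with fields `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `model`, the mean squares, `n` and `k`. [tidy.fc_icc()]
#'   returns it as a one-row tibble.
#' @examples
#' icc_two_way(paired_counts(c(5, 2, 11, 59, 19, 51), c(5, 1, 9, 50, 19, 51)))
#' @export
icc_two_way <- function(data, conf_level = 0.95) {
  x <- if (is.matrix(data)) {
    data
  } else {
    if (!all(c("manual", "automated") %in% names(data))) {
      abort("`data` needs columns `manual` and `automated`.", class = "fc_invalid_input")
    }
    cbind(data$manual, data$automated)
  }
  if (nrow(x) < 2) abort("need >= 2 subjects.", class = "fc_invalid_input")
  ms <- two_way_ms(x)
  n <- ms$n; k <- ms$k
  model <- sprintf("two-way random, absolute agreement, average of %d raters", k)
  if (max(x) == min(x)) {
    out <- list(
      icc = 1, ci_low = 1, ci_high = 1, p_value = NA_real_, model = model,
      msr = ms$msr, msc = ms$msc, mse = ms$mse, n = n, k = k
    )
    return(structure(out, class = "fc_icc"))
  }
  icc_k <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / n)
  icc_1 <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)
  # McGraw-Wong CI for ICC(A,1), stepped up to average measures
  alpha <- 1 - conf_level
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (ms$msr - f_l * ms$mse) /
    (f_l * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  u1 <- n * (f_u * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f_u * ms$msr)
  step_up <- function(r1) k * r1 / (1 + (k - 1) * r1)
  f_stat <- ms$msr / ms$mse
  p <- pf(f_stat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  out <- list(
    icc = icc_k, ci_low = step_up(l1), ci_high = step_up(u1),
    p_value = p, model = model,
    msr = ms$msr, msc = ms$msc, mse = ms$mse, n = n, k = k,
    f_statistic = f_stat
  )
  structure(out, class = "fc_icc")
}

#' @export
print.fc_icc <- function(x, ...) {
  cat(sprintf(
    "ICC = %.3f, 95%% CI [%.3f, %.3f], p = %.2g (%s, n = %d)\n",
    x$icc, x$ci_low, x$ci_high, x$p_value, x$model, x$n
  ))
  invisible(x)
}

#' Tidy an ICC result
#'
#' @param x An `fc_icc` object.
#' @param ... Unused.
#' @return One-row tibble: icc, ci_low, ci_high, p_value, model, n, k.
#' @export
tidy.fc_icc <- function(x, ...) {
  tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    p_value = x$p_value, model = x$model, n = x$n, k = x$k
  )
}

#' Per-image absolute differences between raters
#'
#' The DIF column of a manual-vs-automated comparison:
#' `|manual - automated|` per image.
#'
#' @param data A data frame with `manual` and `automated` columns.
#' @return The input tibble with a `dif` column appended.
#' @examples
#' difference_column(paired_counts(c(59, 19), c(50, 19)))$dif # 9 0
#' @export
difference_column <- function(data) {
  dplyr::mutate(as_tibble(data), dif = abs(.data$manual - .data$automated))
}

#' Round half away from zero
#'
#' Fixed-precision rounding with halves going up, the convention used when
#' comparing computed ICCs against printed 3-decimal values.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Packaged manual-vs-automated validation counts
#'
#' The six-image comparison of manual counting against the automated
#' pipeline (three control images processed in mode C, three treated images
#' in mode TR), shipped as a plain-CSV fixture: per image and cell class,
#' the manual and automated counts.
#'
#' @return Tibble with columns `condition`, `image`, `class`, `manual`,
#'   `automated`.
#' @export
validation_counts <- function() {
  path <- system.file("extdata", "manual_vs_automated_counts.csv",
    package = "fluorcount", mustWork = TRUE
  )
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Reproduce the published manual-vs-automated agreement analysis
#'
#' Computes the two-way random, absolute-agreement, average-measures ICC for
#' each cell class (apoptotic, necrotic, viable) across the six validation
#' images in [validation_counts()].
#'
#' @param counts Validation counts in the layout of [validation_counts()].
#' @return Tibble with one row per class: the ICC (and its half-up 3-decimal
#'   rounding), 95% CI and p-value.
#' @examples
#' reproduce_validation_icc()
#' @export
reproduce_validation_icc <- function(counts = validation_counts()) {
  purrr::map_dfr(c("apoptotic", "necrotic", "viable"), function(cl) {
    sub <- counts[counts$class == cl, ]
    fit <- icc_two_way(sub)
    dplyr::mutate(tidy(fit), class = cl, icc_3dp = round_half_up(.data$icc, 3), .before = 1)
  })
}
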