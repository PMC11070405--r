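# Reproducibility and observer-agreement statistics for paired and
# multi-rater measurement tables: OLS regression, Pearson r, Lin's
# concordance correlation coefficient, paired t-test, (normalised) RMSE,
# Bland-Altman limits of agreement, pairwise percent differences, and
# ICC(2,1) from the two-way random-effects ANOVA.

#' Full agreement statistics for one paired comparison
#'
#' Computes the complete battery for aligned measurement vectors `x`
#' (measurement 1) and `y` (measurement 2):
#' \itemize{
#'   \item OLS regression of `y` on `x` (slope, intercept) and Pearson `r`;
#'   \item Lin's concordance correlation coefficient
#'     \eqn{CCC = 2 r s_x s_y / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)} with a
#'     95\% CI from the Fisher z-transform (Lin's variance);
#'   \item two-sided paired t-test p-value;
#'   \item \eqn{RMSE = \sqrt{mean((x - y)^2)}} and RMSE normalised to the
#'     grand mean of both measurements, in percent;
#'   \item Bland-Altman mean difference \eqn{\bar d} (`x - y`) with limits of
#'     agreement \eqn{\bar d \pm 1.96\, sd(d)};
#'   \item per-pair percent difference \eqn{|x - y| / ((x + y)/2) \times 100},
#'     reported as mean and SD.
#' }
#'
#' @param data Data frame holding the paired measurements.
#' @param x,y Column names (tidy-eval) of measurement 1 and measurement 2.
#' @param conf_level Confidence level of the CCC interval.
#' @return An object of class `paired_agreement`; see [tidy()] / [glance()].
#' @export
#' @examples
#' d <- data.frame(m1 = c(10, 12, 14, 15, 18, 21),
#'                 m2 = c(11, 12, 13, 16, 18, 20))
#' glance(paired_agreement(d, m1, m2))
paired_agreement <- function(data, x, y, conf_level = 0.95) {
  xv <- as.double(dplyr::pull(data, {{ x }}))
  yv <- as.double(dplyr::pull(data, {{ y }}))
  n <- length(xv)
  assert_that(n == length(yv) && n >= 3,
              "paired_agreement(): need equal-length vectors with n >= 3")
  assert_that(all(is.finite(xv)) && all(is.finite(yv)),
              "paired_agreement(): non-finite measurement")
  assert_that(sd(xv) > 0, "paired_agreement(): x is constant, slope undefined")
  fit <- lm(yv ~ xv)
  r <- cor(xv, yv)
  mx <- mean(xv); my <- mean(yv)
  sx2 <- var(xv); sy2 <- var(yv)
  ccc <- 2 * r * sqrt(sx2 * sy2) / (sx2 + sy2 + (mx - my)^2)
  ccc_ci <- ccc_fisher_ci(ccc, r, mx, my, sx2, sy2, n, conf_level)
  d <- xv - yv
  p_value <- if (sd(d) == 0) {
    if (mean(d) == 0) 1 else 0 # degenerate: identical pairs / constant shift
  } else {
    t.test(xv, yv, paired = TRUE)$p.value
  }
  rmse <- sqrt(mean(d^2))
  grand_mean <- mean(c(xv, yv))
  pair_means <- (xv + yv) / 2
  if (any(pair_means <= 0)) {
    bad <- which(pair_means <= 0)[1]
    rlang::abort(sprintf(
      "percent difference undefined: pair %d has nonpositive mean", bad))
  }
  pct <- abs(d) / pair_means * 100
  out <- list(n = n,
              slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              pearson_r = r, ccc = ccc, ccc_lower = ccc_ci[1],
              ccc_upper = ccc_ci[2], p_value = p_value,
              rmse = rmse, nrmse_pct = rmse / grand_mean * 100,
              ba_mean_diff = mean(d),
              ba_lower = mean(d) - 1.96 * sd(d),
              ba_upper = mean(d) + 1.96 * sd(d),
              pctdiff_mean = mean(pct), pctdiff_sd = sd(pct),
              mean_x = mx, sd_x = sqrt(sx2), mean_y = my, sd_y = sqrt(sy2),
              conf_level = conf_level,
              data = tibble::tibble(x = xv, y = yv))
  class(out) <- "paired_agreement"
  out
}

# Lin's CI: Fisher z-transform of the CCC with Lin (1989) variance
ccc_fisher_ci <- function(ccc, r, mx, my, sx2, sy2, n, conf_level) {
  if (abs(ccc) >= 1) return(c(ccc, ccc))
  z <- atanh(ccc)
  u <- (mx - my) / (sx2 * sy2)^(1 / 4)
  se2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
            2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
            ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  if (!is.finite(se2) || se2 < 0) return(c(NA_real_, NA_real_))
  q <- qnorm(1 - (1 - conf_level) / 2)
  tanh(z + c(-1, 1) * q * sqrt(se2))
}

#' @export
print.paired_agreement <- function(x, ...) {
  cat(sprintf("<paired_agreement> n = %d\n", x$n))
  cat(sprintf("  y = %.3f x + %.3f, r = %.4f, CCC = %.4f (%.2f, %.2f)\n",
              x$slope, x$intercept, x$pearson_r, x$ccc, x$ccc_lower,
              x$ccc_upper))
  cat(sprintf("  paired t p = %.4f, RMSE = %.4g (nRMSE %.2f%%)\n",
              x$p_value, x$rmse, x$nrmse_pct))
  cat(sprintf("  Bland-Altman %.4g (LoA %.4g, %.4g); %%diff %.2f +/- %.2f\n",
              x$ba_mean_diff, x$ba_lower, x$ba_upper, x$pctdiff_mean,
              x$pctdiff_sd))
  invisible(x)
}

#' Tidy a paired-agreement object
#'
#' @param x A `paired_agreement` object.
#' @param ... Unused.
#' @return One-row tibble with every statistic of the battery.
#' @method tidy paired_agreement
#' @export
tidy.paired_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 pearson_r = x$pearson_r, ccc = x$ccc,
                 ccc_lower = x$ccc_lower, ccc_upper = x$ccc_upper,
                 p_value = x$p_value, rmse = x$rmse, nrmse_pct = x$nrmse_pct,
                 ba_mean_diff = x$ba_mean_diff, ba_lower = x$ba_lower,
                 ba_upper = x$ba_upper, pctdiff_mean = x$pctdiff_mean,
                 pctdiff_sd = x$pctdiff_sd, mean_x = x$mean_x, sd_x = x$sd_x,
                 mean_y = x$mean_y, sd_y = x$sd_y)
}

#' @rdname tidy.paired_agreement
#' @method glance paired_agreement
#' @export
glance.paired_agreement <- function(x, ...) tidy.paired_agreement(x, ...)

#' Bland-Altman / regression plots for a paired comparison
#'
#' @param object A `paired_agreement` object.
#' @param type `"bland_altman"` or `"regression"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot paired_agreement
#' @export
autoplot.paired_agreement <- function(object, type = c("bland_altman",
                                                       "regression"), ...) {
  type <- match.arg(type)
  d <- object$data
  if (type == "bland_altman") {
    ggplot2::ggplot(tibble::tibble(m = (d$x + d$y) / 2, diff = d$x - d$y),
                    ggplot2::aes(x = .data$m, y = .data$diff)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_hline(yintercept = object$ba_mean_diff, colour = "grey40") +
      ggplot2::geom_hline(yintercept = c(object$ba_lower, object$ba_upper),
                          colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "Pair mean", y = "Difference (measurement 1 - 2)",
                    title = sprintf("Bland-Altman: %.3g (%.3g, %.3g)",
                                    object$ba_mean_diff, object$ba_lower,
                                    object$ba_upper)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
      ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                           colour = "red", linetype = "dashed") +
      ggplot2::labs(x = "Measurement 1", y = "Measurement 2",
                    title = sprintf("y = %.3f x + %.3f (r = %.3f)",
                                    object$slope, object$intercept,
                                    object$pearson_r)) +
      ggplot2::theme_minimal()
  }
}

#' ICC(2,1): single-measure absolute-agreement two-way random-effects ICC
#'
#' Computes the intraclass correlation from the two-way random-effects ANOVA
#' mean squares (rows = subjects, columns = raters):
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with the 95\% CI by the McGraw--Wong F-based method (as used by common
#' statistics packages for "single measures, absolute agreement").
#'
#' @param rm Numeric matrix (n subjects x k raters, no missing cells) or a
#'   data frame of numeric columns.
#' @param conf_level Confidence level for the interval.
#' @return A list with `icc`, `lower`, `upper`, `n`, `k`, the mean squares,
#'   and the Koo-Li `reliability` band of the estimate.
#' @export
#' @examples
#' m <- cbind(r1 = c(10, 12, 18, 25), r2 = c(11, 13, 17, 26),
#'            r3 = c(10, 11, 19, 25))
#' icc_2_1(m)
icc_2_1 <- function(rm, conf_level = 0.95) {
  rm <- as.matrix(rm)
  n <- nrow(rm); k <- ncol(rm)
  assert_that(n >= 2 && k >= 2, "icc_2_1(): need >= 2 subjects and >= 2 raters")
  assert_that(all(is.finite(rm)), "icc_2_1(): missing or non-finite cells")
  grand <- mean(rm)
  row_m <- rowMeans(rm); col_m <- colMeans(rm)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((rm - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  if (ss_tot == 0) rlang::abort("ICC undefined for constant data")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icc <- min(icc, 1) # the estimate is < 1 exactly; guard rounding
  # McGraw & Wong (1996) confidence bounds for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, lower = lower, upper = upper, n = n, k = k,
       msr = msr, msc = msc, mse = mse,
       reliability = classify_reliability(icc))
}

#' Koo-Li reliability band of an ICC estimate
#'
#' Maps an ICC value to the conventional interpretation bands: below 0.50
#' poor, 0.50-0.75 moderate, above 0.75 up to 0.90 good, above 0.90
#' excellent.
#'
#' @param icc ICC estimate (at most 1).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
#' @examples
#' classify_reliability(c(0.49, 0.75, 0.9, 0.99))
classify_reliability <- function(icc) {
  assert_that(all(icc <= 1), "ICC cannot exceed 1")
  out <- character(length(icc))
  out[icc < 0.50] <- "poor"
  out[icc >= 0.50 & icc <= 0.75] <- "moderate"
  out[icc > 0.75 & icc <= 0.90] <- "good"
  out[icc > 0.90] <- "excellent"
  out
}

#' Region-wise reproducibility table for paired acquisitions
#'
#' Takes a long table of per-region measurements from repeated acquisitions
#' and emits one agreement row per region, plus a pooled `Lobar Overall` row
#' in which all six lobes of all pairs are stacked (n = 6 x pairs), plus the
#' `Global Overall` row.
#'
#' @param measurements Data frame with columns `pair_id`, `acquisition`
#'   (1 or 2), `region`, and the measurement `value` (use
#'   [stack_measurement_pairs()] to build it from `lobar_measurements`
#'   tables).
#' @param value Column to analyse (tidy-eval), default `value`.
#' @return Tibble with one row per region (`GLOBAL`, pooled `LOBAR`, and the
#'   six lobes), each holding the full [paired_agreement()] battery plus
#'   `mean1`, `sd1`, `mean2`, `sd2`.
#' @export
reproducibility_table <- function(measurements, value = value) {
  val <- rlang::enquo(value)
  wide <- tidyr::pivot_wider(
    dplyr::select(measurements, "pair_id", "acquisition", "region",
                  value = !!val),
    names_from = "acquisition", values_from = "value", names_prefix = "m")
  assert_that(!anyNA(wide$m1) && !anyNA(wide$m2),
              "reproducibility_table(): incomplete acquisition pair")
  regions <- c("GLOBAL", "LOBAR", lobe_regions())
  rows <- lapply(regions, function(reg) {
    sub <- if (reg == "GLOBAL") {
      dplyr::filter(wide, .data$region == "GLOBAL")
    } else if (reg == "LOBAR") {
      dplyr::filter(wide, .data$region %in% lobe_regions())
    } else {
      dplyr::filter(wide, .data$region == reg)
    }
    assert_that(nrow(sub) >= 3, sprintf(
      "reproducibility_table(): fewer than 3 complete pairs for %s", reg))
    stats <- tidy(paired_agreement(sub, "m1", "m2"))
    dplyr::bind_cols(tibble::tibble(region = reg), stats)
  })
  dplyr::bind_rows(rows)
}

#' Stack lobar measurement tables into a paired long format
#'
#' Helper building the input of [reproducibility_table()] from a list of
#' measurement pairs.
#'
#' @param pairs List of lists with elements `m1` and `m2`, each a
#'   `lobar_measurements` tibble (see [measure_lobes()]).
#' @param column Which measurement to carry (`"mass_g"` or `"volume_ml"`).
#' @return Long tibble with columns `pair_id`, `acquisition`, `region`,
#'   `value`.
#' @export
stack_measurement_pairs <- function(pairs, column = "mass_g") {
  out <- purrr::imap(pairs, function(p, idx) {
    dplyr::bind_rows(
      tibble::tibble(pair_id = idx, acquisition = 1L, region = p$m1$region,
                     value = p$m1[[column]]),
      tibble::tibble(pair_id = idx, acquisition = 2L, region = p$m2$region,
                     value = p$m2[[column]]))
  })
  dplyr::bind_rows(out)
}
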