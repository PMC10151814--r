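# Statistical layer: paired comparisons of clinical parameters, Fisher-z
# correlation pooling, ICC(3,1) with F-based confidence interval, Bland-Altman
# limits of agreement, and equivalence testing against tolerance intervals.

#' Two-sided paired t-test
#'
#' Classical paired t on `d = x - y` with `n - 1` degrees of freedom
#' (delegating to [stats::t.test()]), with explicit handling of degenerate
#' variance: if all differences are identical and nonzero the p-value is
#' reported at the machine floor with a `degenerate_variance` flag; if all
#' are zero, `t = 0, p = 1`.
#'
#' @param x,y paired per-case values (equal length >= 2).
#' @return a list with `t`, `p`, `mean_diff`, `sd_diff`, `df`,
#'   `degenerate_variance`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- x - y
  m <- mean(d); s <- sd(d); n <- length(d)
  if (s == 0) {
    if (m == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, sd_diff = 0, df = n - 1L,
                  degenerate_variance = FALSE))
    }
    return(list(t = sign(m) * Inf, p = .Machine$double.xmin, mean_diff = m,
                sd_diff = 0, df = n - 1L, degenerate_variance = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = m, sd_diff = s,
       df = n - 1L, degenerate_variance = FALSE)
}

#' Pool correlation coefficients via Fisher's z'
#'
#' Transforms each coefficient with `atanh`, averages on the
#' variance-stabilised scale, and back-transforms: `tanh(mean(atanh(r)))`.
#'
#' @param rs numeric vector of Pearson correlations, each strictly in (-1, 1).
#' @return the pooled correlation.
#' @examples
#' fisher_z_mean(c(0.9, 0.95, 0.99))
#' @export
fisher_z_mean <- function(rs) {
  stopifnot(length(rs) >= 1L)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("infinite z: correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  tanh(mean(atanh(rs)))
}

#' ICC(3,1): single-rater, consistency, two-way mixed-effects
#'
#' From the two-way ANOVA decomposition of a complete subjects x raters grid:
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) MS_E)` where `MS_R` is the
#' between-subject and `MS_E` the residual mean square. The 95% confidence
#' interval uses the F-distribution method for consistency ICCs
#' (`F = MS_R / MS_E` with `n - 1` and `(n - 1)(k - 1)` degrees of freedom).
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns,
#'   complete (no missing cells).
#' @param conf confidence level (default 0.95).
#' @return a list with `icc`, `ci_low`, `ci_high`, `n_subjects`, `k_raters`,
#'   `ms_subject`, `ms_error`.
#' @export
icc_3_1 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 2L, ncol(ratings) >= 2L)
  if (anyNA(ratings)) stop("ratings grid must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((ratings - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= 0) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_subjects = n, k_raters = k, ms_subject = ms_r, ms_error = ms_e))
  }
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  if (ms_e == 0) {
    ci <- c(icc, icc)  # raters agree up to fixed shifts: no sampling noise in F
  } else {
    alpha <- 1 - conf
    fobs <- ms_r / ms_e
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha / 2, df1, df2)
    fu <- fobs * qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1L], ci_high = ci[2L],
       n_subjects = n, k_raters = k, ms_subject = ms_r, ms_error = ms_e)
}

#' Equivalence test of a mean difference against a tolerance interval
#'
#' Computes the t-based 95% confidence interval of the mean difference,
#' `mean +/- t_{0.975, n-1} * sd / sqrt(n)`, and declares equivalence when
#' the CI lies completely within the tolerance interval (inclusive at the
#' boundaries). Tolerance intervals are study configuration, typically
#' derived from intraobserver variability.
#'
#' @param diffs per-case differences (reader - expert).
#' @param tolerance numeric `(low, high)` with `low < high`.
#' @param conf confidence level (default 0.95).
#' @return a list with `ci_low`, `ci_high`, `tol_low`, `tol_high`,
#'   `mean_diff`, `equivalent`.
#' @export
equivalence_test <- function(diffs, tolerance, conf = 0.95) {
  stopifnot(length(diffs) >= 2L, length(tolerance) == 2L,
            tolerance[1L] < tolerance[2L])
  n <- length(diffs)
  m <- mean(diffs)
  half <- qt(1 - (1 - conf) / 2, n - 1) * sd(diffs) / sqrt(n)
  ci <- c(m - half, m + half)
  list(ci_low = ci[1L], ci_high = ci[2L],
       tol_low = tolerance[1L], tol_high = tolerance[2L],
       mean_diff = m,
       equivalent = tolerance[1L] <= ci[1L] && ci[2L] <= tolerance[2L])
}

#' Bland-Altman bias and limits of agreement
#'
#' @param diffs per-case differences.
#' @return named vector `c(bias, loa_low, loa_high)` with limits at
#'   `bias +/- 1.96 sd`.
#' @export
bland_altman <- function(diffs) {
  stopifnot(length(diffs) >= 2L)
  bias <- mean(diffs); s <- sd(diffs)
  c(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Compare clinical parameters of an evaluated reader against the expert
#'
#' For each of the seven parameters: per-case differences (reader - expert),
#' mean and standard deviation of the differences, the two-sided paired
#' t-test, and the Pearson correlation between the paired values (reported
#' as `NA` when either vector is constant).
#'
#' @param expert_params,reader_params per-case parameter tibbles from
#'   [clinical_summary()]; matched on `case_id`.
#' @return a tibble with one row per parameter.
#' @export
compare_clinical <- function(expert_params, reader_params) {
  if (!setequal(expert_params$case_id, reader_params$case_id)) {
    stop("pairing error: case IDs do not match", call. = FALSE)
  }
  e <- expert_params[order(expert_params$case_id), ]
  r <- reader_params[match(e$case_id, reader_params$case_id), ]
  rows <- lapply(CLINICAL_PARAMS, function(p) {
    xe <- e[[p]]; xr <- r[[p]]
    ok <- complete.cases(xe, xr)
    xe <- xe[ok]; xr <- xr[ok]
    tt <- if (length(xe) >= 2L) paired_t_test(xr, xe) else
      list(mean_diff = mean(xr - xe), sd_diff = NA_real_, t = NA_real_, p = NA_real_)
    pearson <- if (length(xe) < 2L || sd(xe) == 0 || sd(xr) == 0) NA_real_ else cor(xe, xr)
    tibble::tibble(parameter = p, n_cases = length(xe),
                   mean_diff = tt$mean_diff, sd_diff = tt$sd_diff,
                   t_stat = tt$t, p_value = tt$p, pearson_r = pearson)
  })
  dplyr::bind_rows(rows)
}
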