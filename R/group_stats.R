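## Comparative statistics: 2x2 within-subject (limb x time) repeated-measures
## ANOVA plus the classical two-sample tests used for cohort characteristics.
## The t and Fisher tests wrap stats::t.test / stats::fisher.test behind a
## uniform result contract; the repeated-measures decomposition is computed
## longhand (no Error-strata model fitting needed for a 2x2 design).

#' Two-way (2 x 2) repeated-measures ANOVA
#'
#' Both factors within-subject with two levels each (limb: involved vs
#' contralateral; time: 4 vs 6 months). Each effect is tested against its
#' own subject-interaction error term with (1, n-1) degrees of freedom.
#' With two levels per factor sphericity holds automatically and F_limb
#' equals the squared paired-t statistic on time-averaged limb differences.
#'
#' @param values numeric array `n x 2 x 2` (subject, limb, time), or a long
#'   data.frame with columns `subject`, `limb`, `time`, `thickness_mm`
#'   (complete: every subject crossed with both limbs and both times)
#' @return data.frame (class `anova_table`): `effect` (`limb`, `time`,
#'   `limb:time`), `df1`, `df2`, `F`, `p`
#' @export
rm_anova_2x2 <- function(values) {
  y <- as_grid_2x2(values)
  n <- dim(y)[1L]
  if (n < 3L) uc_stop("need >= 3 subjects", "design_error")
  grand <- mean(y)
  subj <- apply(y, 1L, mean)
  limb <- apply(y, 2L, mean)
  time <- apply(y, 3L, mean)
  cell_st_limb <- apply(y, c(1L, 2L), mean)   # subject x limb means
  cell_st_time <- apply(y, c(1L, 3L), mean)   # subject x time means
  cell_lt <- apply(y, c(2L, 3L), mean)        # limb x time means

  ss_limb <- 2 * n * sum((limb - grand)^2)
  ss_time <- 2 * n * sum((time - grand)^2)
  ss_lxt <- n * sum((sweep(sweep(cell_lt, 1L, limb), 2L, time) + grand)^2)

  ss_limb_err <- 2 * sum((cell_st_limb - outer(subj, limb, "+") + grand)^2)
  ss_time_err <- 2 * sum((cell_st_time - outer(subj, time, "+") + grand)^2)
  fitted3 <- array(0, dim(y))
  for (i in seq_len(n)) for (j in 1:2) for (k in 1:2) {
    fitted3[i, j, k] <- cell_st_limb[i, j] + cell_st_time[i, k] +
      cell_lt[j, k] - subj[i] - limb[j] - time[k] + grand
  }
  ss_lxt_err <- sum((y - fitted3)^2)

  eff <- function(name, ss, ss_err) {
    mse <- ss_err / (n - 1)
    f <- if (mse == 0 && ss == 0) 0 else ss / mse
    data.frame(effect = name, df1 = 1L, df2 = n - 1L, F = f,
               p = pf(f, 1, n - 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  out <- rbind(eff("limb", ss_limb, ss_limb_err),
               eff("time", ss_time, ss_time_err),
               eff("limb:time", ss_lxt, ss_lxt_err))
  class(out) <- c("anova_table", "data.frame")
  out
}

as_grid_2x2 <- function(values) {
  if (is.array(values) && length(dim(values)) == 3L) {
    if (!all(dim(values)[2:3] == 2L)) {
      uc_stop("grid must be n x 2 x 2", "design_error")
    }
    if (any(!is.finite(values))) {
      uc_stop("grid has missing cells (no imputation)", "design_error")
    }
    return(values)
  }
  d <- values
  need <- c("subject", "limb", "time", "thickness_mm")
  if (!is.data.frame(d) || !all(need %in% names(d))) {
    uc_stop("need an n x 2 x 2 array or a long data.frame with subject, limb, time, thickness_mm",
            "design_error")
  }
  subj <- unique(d$subject); limbs <- sort(unique(d$limb))
  times <- sort(unique(d$time))
  if (length(limbs) != 2L || length(times) != 2L) {
    uc_stop("limb and time must each have exactly 2 levels", "design_error")
  }
  y <- array(NA_real_, c(length(subj), 2L, 2L),
             dimnames = list(subj, limbs, times))
  agg <- stats::aggregate(thickness_mm ~ subject + limb + time, d, mean)
  y[cbind(match(agg$subject, subj), match(agg$limb, limbs),
          match(agg$time, times))] <- agg$thickness_mm
  if (any(is.na(y))) {
    uc_stop("incomplete subject x limb x time grid (no imputation)",
            "design_error")
  }
  y
}

test_result <- function(statistic, df, p, mean_diff = NA_real_,
                        method = "") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), mean_diff = unname(mean_diff),
                 method = method),
            class = "uc_test_result")
}

#' @export
print.uc_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p))
  if (is.finite(x$mean_diff)) cat(sprintf("  mean difference = %.4g\n",
                                          x$mean_diff))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided paired t-test between limbs or time points.
#'
#' @param x,y paired numeric vectors, equal length >= 2
#' @return a `uc_test_result` with `statistic`, `df`, `p`, `mean_diff`
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    uc_stop("paired samples must have equal length >= 2", "design_error")
  }
  d <- x - y
  if (stats::var(d) == 0 && mean(d) != 0) {
    uc_stop("zero variance of differences: t undefined",
            "undefined_statistic_error")
  }
  if (stats::var(d) == 0) return(test_result(0, length(d) - 1L, 1,
                                             0, "paired t-test"))
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value,
              mean(d), "paired t-test")
}

#' Independent-samples t-test
#'
#' Two-sided; pooled-variance (classical Student) by default, with
#' `var_equal = FALSE` for the Welch variant.
#'
#' @param x,y numeric samples, each of length >= 2
#' @param var_equal assume equal variances (pooled SD)? default `TRUE`
#' @return a `uc_test_result`
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    uc_stop("each sample needs >= 2 observations", "design_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    uc_stop("zero variance in both samples: t undefined",
            "undefined_statistic_error")
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  test_result(tt$statistic, tt$parameter, tt$p.value,
              mean(x) - mean(y),
              if (var_equal) "independent t-test (pooled)" else
                "independent t-test (Welch)")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table.
#'
#' @param table 2 x 2 matrix of non-negative counts
#' @return a `uc_test_result` (statistic is the odds-ratio estimate)
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table))) {
    uc_stop("need a 2 x 2 matrix of non-negative integer counts",
            "design_error")
  }
  ft <- stats::fisher.test(table)
  test_result(unname(ft$estimate), NA_real_, ft$p.value,
              method = "Fisher exact test (2 x 2)")
}
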