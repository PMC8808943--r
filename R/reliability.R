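## Test-retest reliability and precision: ICC(2,k), SEM, MDC90, and the
## qualitative ICC classification used in musculoskeletal ultrasound work.

#' ICC(2,k): two-way random effects, absolute agreement, average of k measures
#'
#' Shrout-Fleiss ICC(2,k) from the two-way (subject x session) ANOVA mean
#' squares:
#' \deqn{ICC(2,k) = \frac{MS_R - MS_E}{MS_R + (MS_C - MS_E)/n}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the rows (subjects), columns
#' (sessions), and residual mean squares and \eqn{n} the number of subjects.
#' The 95% confidence interval uses the Shrout-Fleiss F-based construction
#' for the single-measure ICC(2,1) (Satterthwaite degrees of freedom) stepped
#' up to k measures with the Spearman-Brown relation.
#'
#' @param values numeric matrix, subjects in rows, sessions in columns
#'   (no missing cells; >= 3 subjects, >= 2 sessions)
#' @param conf confidence level for the interval (default 0.95)
#' @return an `icc_result` list: `icc`, `ci_lo`, `ci_hi`, `n`, `k`, and the
#'   mean squares `msr`, `msc`, `mse`
#' @export
#' @examples
#' m <- cbind(s1 = c(2.0, 2.4, 1.8, 2.2, 2.6),
#'            s2 = c(2.1, 2.5, 1.9, 2.2, 2.7))
#' icc_2k(m)
icc_2k <- function(values, conf = 0.95) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) {
    uc_stop("measurement matrix has missing or non-finite cells",
            "measurement_matrix_error")
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 3L || k < 2L) {
    uc_stop("need >= 3 subjects and >= 2 sessions", "measurement_matrix_error")
  }
  grand <- mean(values)
  rowm <- rowMeans(values)
  colm <- colMeans(values)
  ssr <- k * sum((rowm - grand)^2)             # subjects
  ssc <- n * sum((colm - grand)^2)             # sessions
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc                       # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst <= 0) {
    uc_stop("zero total variance: ICC undefined", "undefined_icc_error")
  }
  denom <- msr + (msc - mse) / n
  if (denom == 0) {
    uc_stop("degenerate mean squares: ICC undefined", "undefined_icc_error")
  }
  icc_k <- (msr - mse) / denom
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # Shrout-Fleiss CI for ICC(2,1), then Spearman-Brown step-up to k measures
  alpha <- 1 - conf
  fj <- msc / mse
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * fj + b)^2 /
    (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
  f_u <- qf(1 - alpha / 2, n - 1, v)
  f_l <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_u * mse) /
    (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f_l * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_l * msr)
  step_up <- function(r) k * r / (1 + (k - 1) * r)
  structure(list(icc = icc_k, ci_lo = step_up(lo1), ci_hi = step_up(hi1),
                 n = n, k = k, msr = msr, msc = msc, mse = mse, conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.4f, %d%% CI [%.4f, %.4f] (n = %d) -- %s\n",
              x$k, x$icc, round(100 * x$conf), x$ci_lo, x$ci_hi, x$n,
              classify_icc(x$icc)))
  invisible(x)
}

#' Standard error of measurement
#'
#' `SEM = SD * sqrt(1 - ICC)`: the precision of a single measurement, in the
#' units of the measurement. SD is the between-subject standard deviation of
#' the reliability sample (here: session-1 thickness of the healthy cohort).
#'
#' @param sd between-subject standard deviation (mm), >= 0
#' @param icc reliability coefficient in `[0, 1]`
#' @return SEM in the units of `sd`
#' @export
sem_measurement <- function(sd, icc) {
  if (any(!is.finite(sd)) || any(sd < 0)) {
    uc_stop("sd must be finite and >= 0", "domain_error")
  }
  if (any(!is.finite(icc)) || any(icc < 0) || any(icc > 1)) {
    uc_stop("icc must lie in [0, 1] for the SEM formula", "domain_error")
  }
  sd * sqrt(1 - icc)
}

#' Minimal detectable change at 90% confidence
#'
#' `MDC90 = 1.654 * SEM * sqrt(2)`: the smallest between-session change
#' exceeding measurement error with 90% confidence. The constant 1.654 is
#' the convention of the source literature (the usual two-sided z for 90% is
#' 1.645; the two round identically at two decimals on thickness-scale SEMs
#' and the printed constant is kept, not corrected).
#'
#' @param sem standard error of measurement, >= 0
#' @param constant confidence multiplier (default 1.654)
#' @return MDC in the units of `sem`
#' @export
mdc90 <- function(sem, constant = 1.654) {
  if (any(!is.finite(sem)) || any(sem < 0)) {
    uc_stop("sem must be finite and >= 0", "domain_error")
  }
  if (!is.finite(constant) || constant <= 0) {
    uc_stop("constant must be > 0", "domain_error")
  }
  constant * sem * sqrt(2)
}

#' Qualitative ICC classification
#'
#' Half-open bands: poor `[-Inf, 0.5)`, moderate `[0.5, 0.75)`, good
#' `[0.75, 0.9)`, excellent `[0.9, Inf)`. The published cut-off wording
#' (`< 0.49`, `0.5-0.74`, `0.75-0.89`, `> 0.9`) leaves gaps at 0.49-0.5 and
#' 0.89-0.9; the half-open reading closes them with boundaries assigned to
#' the upper band.
#'
#' @param icc numeric vector of finite ICC values
#' @return character vector: `"poor"`, `"moderate"`, `"good"`, `"excellent"`
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) uc_stop("icc must be finite", "domain_error")
  cut_labels <- c("poor", "moderate", "good", "excellent")
  as.character(cut(icc, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf),
                   labels = cut_labels, right = FALSE))
}

#' Reported SEM and MDC from printed SD and ICC
#'
#' Reproduces the published-table convention: SEM is rounded half-away-from-
#' zero to `decimals` places, and MDC90 is computed *from the rounded SEM*
#' and rounded again. (Working from rounded intermediate values is how such
#' tables are assembled; with full-precision SEM the medial MDC would round
#' to 0.15 rather than the published 0.16.) Full-precision values are also
#' returned.
#'
#' @param sd,icc numeric vectors (recycled) of between-subject SD and ICC
#' @param decimals reporting decimals (default 2)
#' @param constant MDC confidence multiplier (default 1.654)
#' @return data.frame: `sd`, `icc`, `sem`, `mdc90` (full precision, with
#'   `mdc90` computed from the rounded SEM), `sem_report`, `mdc90_report`
#' @export
#' @examples
#' report_precision(sd = c(0.38, 0.61, 0.36), icc = c(0.97, 0.99, 0.98))
report_precision <- function(sd, icc, decimals = 2, constant = 1.654) {
  s <- sem_measurement(sd, icc)
  s_rep <- round_half_up(s, decimals)
  m <- mdc90(s_rep, constant)
  data.frame(sd = sd, icc = icc, sem = s, mdc90 = m,
             sem_report = s_rep, mdc90_report = round_half_up(m, decimals))
}

#' Test-retest reliability table from long-format measurements
#'
#' For each region: averages the repeated images within each subject/session
#' to one session value, forms the subjects x sessions matrix, and computes
#' ICC(2,k) with its CI, the between-subject SD of session-1 values, SEM,
#' MDC90, and the qualitative class. The `sem_report` / `mdc90_report`
#' columns follow the published-table rounding convention of
#' [report_precision()].
#'
#' @param measurements data.frame with columns `subject`, `region`, `session`,
#'   `thickness_mm` (and optionally `image_index`, `limb`); every subject
#'   must have every session for every region
#' @param decimals reporting decimals
#' @param constant MDC confidence multiplier
#' @return data.frame with one row per region: `region`, `n`, `k`, `icc`,
#'   `ci_lo`, `ci_hi`, `icc_class`, `sd`, `sem`, `mdc90`, `sem_report`,
#'   `mdc90_report`
#' @export
reliability_table <- function(measurements, decimals = 2, constant = 1.654) {
  m <- check_measurements(measurements)
  out <- lapply(split(m, m$region), function(d) {
    mat <- session_matrix(d)
    fit <- icc_2k(mat)
    sd1 <- stats::sd(mat[, 1L])
    rep <- report_precision(sd1, fit$icc, decimals, constant)
    data.frame(region = d$region[1L], n = fit$n, k = fit$k,
               icc = fit$icc, ci_lo = fit$ci_lo, ci_hi = fit$ci_hi,
               icc_class = classify_icc(fit$icc),
               sd = sd1, sem = rep$sem, mdc90 = rep$mdc90,
               sem_report = rep$sem_report, mdc90_report = rep$mdc90_report,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ord <- match(REGIONS, out$region)
  out <- out[ord[!is.na(ord)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

## subjects x sessions matrix of session-mean thickness for one region
session_matrix <- function(d) {
  sess <- sort(unique(d$session))
  subj <- unique(d$subject)
  agg <- stats::aggregate(thickness_mm ~ subject + session, data = d, FUN = mean)
  mat <- matrix(NA_real_, nrow = length(subj), ncol = length(sess),
                dimnames = list(subj, sess))
  mat[cbind(match(agg$subject, subj), match(agg$session, sess))] <-
    agg$thickness_mm
  if (any(is.na(mat))) {
    bad <- rownames(mat)[apply(mat, 1L, anyNA)]
    uc_stop(paste0("subjects missing a session: ",
                   paste(bad, collapse = ", ")),
            "incomplete_participant_error")
  }
  mat
}

check_measurements <- function(m) {
  need <- c("subject", "region", "session", "thickness_mm")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    uc_stop(paste0("measurements lack columns: ", paste(miss, collapse = ", ")),
            "schema_error")
  }
  if (!is.numeric(m$thickness_mm) || any(!is.finite(m$thickness_mm))) {
    uc_stop("thickness_mm must be finite numeric", "schema_error")
  }
  m
}
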