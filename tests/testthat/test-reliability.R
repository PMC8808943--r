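test_that("ICC(2,k) equals 1 when sessions agree perfectly", {
  m <- cbind(c(2.0, 2.4, 1.8, 2.2), c(2.0, 2.4, 1.8, 2.2))
  r <- icc_2k(m)
  expect_equal(r$icc, 1.0)
  expect_equal(r$mse, 0)
})

test_that("ICC(2,k) matches the longhand two-way ANOVA oracle", {
  m <- matrix(c(2.0, 2.1, 2.4, 2.5, 1.8, 1.9, 2.2, 2.2, 2.6, 2.7),
              ncol = 2, byrow = TRUE)
  r <- icc_2k(m)
  # frozen value from the mean-squares oracle below
  expect_equal(r$icc, 0.980392156862745, tolerance = 1e-10)

  # independent route: lm/anova decomposition, then the Shrout-Fleiss formula
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m), subj = factor(rep(seq_len(n), k)),
                  sess = factor(rep(seq_len(k), each = n)))
  a <- anova(lm(y ~ subj + sess, d))
  msr <- a["subj", "Mean Sq"]; msc <- a["sess", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  expect_equal(r$msr, msr, tolerance = 1e-12)
  expect_equal(r$icc, (msr - mse) / (msr + (msc - mse) / n),
               tolerance = 1e-10)

  # and on 5 random matrices
  for (seed in 1:5) {
    set.seed(seed)
    mm <- matrix(rnorm(8 * 3, 2.2, 0.4), ncol = 3)
    d <- data.frame(y = as.vector(mm), subj = factor(rep(1:8, 3)),
                    sess = factor(rep(1:3, each = 8)))
    a <- anova(lm(y ~ subj + sess, d))
    msr <- a["subj", "Mean Sq"]; msc <- a["sess", "Mean Sq"]
    mse <- a["Residuals", "Mean Sq"]
    expect_equal(icc_2k(mm)$icc, (msr - mse) / (msr + (msc - mse) / 8),
                 tolerance = 1e-10)
  }
})

test_that("ICC(2,k) approaches the variance-component value at large n", {
  set.seed(99)
  n <- 500
  b <- rnorm(n, 0, 0.4)
  m <- cbind(2.2 + b + rnorm(n, 0, 0.07), 2.2 + b + rnorm(n, 0, 0.07))
  expected <- 0.4^2 / (0.4^2 + 0.07^2 / 2)
  expect_equal(icc_2k(m)$icc, expected, tolerance = 0.02)
})

test_that("ICC confidence interval brackets the estimate and covers truth", {
  sim <- simulate_cohort(cohort_spec(seed = 3))
  tab <- reliability_table(sim$measurements)
  expect_true(all(tab$ci_lo <= tab$icc & tab$icc <= tab$ci_hi))

  # coverage of the analytic ICC over replicate cohorts (nominal 95%)
  spec0 <- cohort_spec(region_means = c(medial = 2.16),
                       sd_between = 0.4, sd_session = 0, sd_image = 0.07)
  truth <- unname(closed_form_icc2k(spec0))
  hits <- 0L
  for (s in 1:100) {
    spec <- spec0; spec$seed <- 5000L + s
    mat <- with(simulate_cohort(spec),
                t(sapply(split(measurements$thickness_mm,
                               measurements$subject),
                         function(v) tapply(v, rep(1:2, each = 3), mean))))
    r <- icc_2k(mat)
    hits <- hits + (r$ci_lo <= truth && truth <= r$ci_hi)
  }
  expect_gte(hits, 85)
})

test_that("ICC is shift-invariant; scaling moves SEM and MDC linearly", {
  set.seed(11)
  b <- rnorm(20, 0, 0.4)
  m <- cbind(2.2 + b + rnorm(20, 0, 0.06), 2.2 + b + rnorm(20, 0, 0.06))
  r0 <- icc_2k(m)
  expect_equal(icc_2k(m + 5)$icc, r0$icc, tolerance = 1e-9)
  expect_equal(icc_2k(m * 3)$icc, r0$icc, tolerance = 1e-9)
  s0 <- sem_measurement(sd(m[, 1]), r0$icc)
  expect_equal(sem_measurement(sd(3 * m[, 1]), icc_2k(m * 3)$icc), 3 * s0,
               tolerance = 1e-8)
  expect_equal(mdc90(3 * s0), 3 * mdc90(s0))
})

test_that("zero-variance and malformed matrices are errors", {
  expect_error(icc_2k(matrix(2, 5, 2)), class = "undefined_icc_error")
  expect_error(icc_2k(matrix(1:4, 2, 2)), class = "measurement_matrix_error")
  expect_error(icc_2k(matrix(c(1, 2, 3, NA, 5, 6), 3, 2)),
               class = "measurement_matrix_error")
})

test_that("SEM: published-value checks, monotonicity, domain errors", {
  expect_equal(round_half_up(sem_measurement(0.38, 0.97), 2), 0.07)
  expect_equal(round_half_up(sem_measurement(0.61, 0.99), 2), 0.06)
  expect_equal(round_half_up(sem_measurement(0.36, 0.98), 2), 0.05)
  expect_equal(sem_measurement(0.5, 1), 0)
  # monotone decreasing in ICC at fixed SD
  iccs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sem_measurement(0.4, iccs)) <= 0))
  expect_error(sem_measurement(0.4, 1.2), class = "domain_error")
  expect_error(sem_measurement(-0.1, 0.9), class = "domain_error")
})

test_that("MDC90: published-value checks and linearity", {
  expect_equal(round_half_up(mdc90(0.07), 2), 0.16)
  expect_equal(round_half_up(mdc90(0.06), 2), 0.14)
  expect_equal(mdc90(0), 0)
  expect_equal(mdc90(0.1), 1.654 * 0.1 * sqrt(2))
  expect_equal(mdc90(c(0.05, 0.10)), 2 * mdc90(c(0.025, 0.05)))
  expect_error(mdc90(-0.01), class = "domain_error")
})

test_that("qualitative ICC bands are half-open with boundaries stepping up", {
  expect_equal(classify_icc(c(0.97, 0.60, 0.75, 0.30, 0.5, 0.9, 0.89, -0.2)),
               c("excellent", "moderate", "good", "poor", "moderate",
                 "excellent", "good", "poor"))
  expect_error(classify_icc(NaN), class = "domain_error")
})

test_that("reliability_table averages images, uses session-1 SD, orders regions", {
  sim <- simulate_cohort(cohort_spec(seed = 21))
  tab <- reliability_table(sim$measurements)
  expect_equal(tab$region, c("medial", "intercondylar", "lateral"))
  expect_equal(tab$k, rep(2L, 3))

  # session-1 SD recomputed independently for one region
  m <- sim$measurements
  med <- m[m$region == "medial" & m$session == 1, ]
  sd1 <- sd(tapply(med$thickness_mm, med$subject, mean))
  expect_equal(tab$sd[tab$region == "medial"], sd1)
  expect_equal(tab$sem, sem_measurement(tab$sd, tab$icc))

  # a subject missing session 2 is a hard error naming the offender
  broken <- m[!(m$subject == "S001" & m$session == 2), ]
  expect_error(reliability_table(broken),
               class = "incomplete_participant_error")
  expect_error(reliability_table(broken), "S001")
})

test_that("report_precision computes MDC from the rounded SEM", {
  rep <- report_precision(sd = c(0.38, 0.61, 0.36), icc = c(0.97, 0.99, 0.98))
  expect_equal(rep$sem_report, c(0.07, 0.06, 0.05))
  expect_equal(rep$mdc90_report, c(0.16, 0.14, 0.12))
  # full-precision medial SEM would round the MDC down to 0.15 instead
  expect_equal(round_half_up(mdc90(sem_measurement(0.38, 0.97)), 2), 0.15)
})
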