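## Cohort simulator: longitudinal thickness measurements with a known
## variance decomposition and, optionally, injected true change.
##
## Measurement model per subject i, limb l, region r, session s, image m:
##   y = mu_r + b_{ilr} + delta_{ilr} * 1[s = 2] + v_{ilrs} + e_{ilrsm}
## with b ~ N(0, sd_between^2) (between-subject), v ~ N(0, sd_session^2)
## (between-session/visit error), e ~ N(0, sd_image^2) (within-session image
## repetition), all independent normals. Heavy-tailed alternatives are out
## of scope.

#' Specification of a simulated measurement cohort
#'
#' Defaults mirror the magnitudes of healthy suprapatellar femoral cartilage
#' at this probe placement: regional means 2.16 / 2.57 / 2.04 mm with
#' between-subject SDs 0.38 / 0.61 / 0.36 mm (medial / intercondylar /
#' lateral), 2 sessions of 3 images each, and measurement error chosen so
#' the SEM of a session mean lands near 0.05-0.07 mm.
#'
#' @param n_subjects number of participants
#' @param k_sessions sessions per participant (>= 2 for reliability use)
#' @param images_per_session repeated images averaged into a session value
#' @param limbs character vector of limbs imaged (default `"dominant"`)
#' @param region_means named mm means per region
#' @param sd_between between-subject SD (mm); scalar or named per region
#' @param sd_session between-session (visit) error SD (mm)
#' @param sd_image within-session image SD (mm)
#' @param fraction_thickening,fraction_thinning mixture fractions of
#'   participants with true change at session 2 (per limb, per region,
#'   independent draws); fractions must sum to <= 1
#' @param delta_mm magnitude of true change (+delta for thickening,
#'   -delta for thinning)
#' @param seed RNG seed (determinism contract)
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_subjects = 30, k_sessions = 2,
                        images_per_session = 3,
                        limbs = "dominant",
                        region_means = c(medial = 2.16, intercondylar = 2.57,
                                         lateral = 2.04),
                        sd_between = c(medial = 0.38, intercondylar = 0.61,
                                       lateral = 0.36),
                        sd_session = 0.04,
                        sd_image = 0.10,
                        fraction_thickening = 0,
                        fraction_thinning = 0,
                        delta_mm = 0.25,
                        seed = 1L) {
  if (n_subjects < 1 || k_sessions < 1 || images_per_session < 1) {
    uc_stop("cohort sizes must be >= 1", "invalid_spec_error")
  }
  if (any(c(sd_between, sd_session, sd_image) < 0)) {
    uc_stop("all SDs must be >= 0", "invalid_spec_error")
  }
  if (fraction_thickening < 0 || fraction_thinning < 0 ||
      fraction_thickening + fraction_thinning > 1) {
    uc_stop("mixture fractions must be >= 0 and sum to <= 1",
            "invalid_spec_error")
  }
  regions <- names(region_means)
  if (is.null(regions)) {
    regions <- REGIONS[seq_along(region_means)]
    names(region_means) <- regions
  }
  if (length(sd_between) == 1L) {
    sd_between <- setNames(rep(sd_between, length(regions)), regions)
  }
  structure(list(n_subjects = n_subjects, k_sessions = k_sessions,
                 images_per_session = images_per_session, limbs = limbs,
                 region_means = region_means, sd_between = sd_between,
                 sd_session = sd_session, sd_image = sd_image,
                 fraction_thickening = fraction_thickening,
                 fraction_thinning = fraction_thinning,
                 delta_mm = delta_mm, seed = seed),
            class = "cohort_spec")
}

#' Closed-form ICC(2,k) implied by a cohort specification
#'
#' For session means of `m` images: the error variance of one session value
#' is `sd_session^2 + sd_image^2 / m`, so the population average-measures
#' ICC over `k` sessions is
#' `sd_between^2 / (sd_between^2 + (sd_session^2 + sd_image^2 / m) / k)`.
#' (Session effects are drawn independently per subject, i.e. there is no
#' shared column effect, so the absolute-agreement and consistency forms
#' coincide.)
#'
#' @param spec a [cohort_spec()]
#' @return named numeric vector of ICC(2,k) per region
#' @export
closed_form_icc2k <- function(spec) {
  err <- spec$sd_session^2 + spec$sd_image^2 / spec$images_per_session
  vb <- spec$sd_between^2
  vb / (vb + err / spec$k_sessions)
}

#' Simulate a measurement cohort
#'
#' Draws long-format thickness measurements under the model documented in
#' [cohort_spec()] and returns them with the generating truth (per-subject
#' random effects, true deltas, responder labels, variance components, and
#' the closed-form ICC). Deterministic given `spec$seed`.
#'
#' @param spec a [cohort_spec()]
#' @return list: `measurements` (data.frame `subject`, `limb`, `region`,
#'   `session`, `image_index`, `thickness_mm`) and `truth`
#'   (`synthetic_truth`)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  regions <- names(spec$region_means)
  n <- spec$n_subjects; k <- spec$k_sessions; m <- spec$images_per_session
  subjects <- sprintf("S%03d", seq_len(n))

  truth_rows <- list(); meas_rows <- list()
  for (limb in spec$limbs) {
    for (r in regions) {
      b <- rnorm(n, 0, spec$sd_between[[r]])
      u <- stats::runif(n)
      lab <- ifelse(u < spec$fraction_thickening, "thickening",
                    ifelse(u < spec$fraction_thickening +
                             spec$fraction_thinning, "thinning", "none"))
      delta <- ifelse(lab == "thickening", spec$delta_mm,
                      ifelse(lab == "thinning", -spec$delta_mm, 0))
      truth_rows[[paste(limb, r)]] <- data.frame(
        subject = subjects, limb = limb, region = r,
        true_mean = spec$region_means[[r]] + b, true_delta = delta,
        responder = lab, stringsAsFactors = FALSE)
      for (s in seq_len(k)) {
        v <- rnorm(n, 0, spec$sd_session)
        sess_mu <- spec$region_means[[r]] + b + v + if (s >= 2) delta else 0
        e <- matrix(rnorm(n * m, 0, spec$sd_image), nrow = n)
        meas_rows[[paste(limb, r, s)]] <- data.frame(
          subject = rep(subjects, each = m), limb = limb, region = r,
          session = s, image_index = rep(seq_len(m), n),
          thickness_mm = as.vector(t(sess_mu + e)),
          stringsAsFactors = FALSE)
      }
    }
  }
  measurements <- do.call(rbind, meas_rows)
  rownames(measurements) <- NULL
  truth <- structure(list(
    subjects = do.call(rbind, truth_rows),
    variance_components = list(sd_between = spec$sd_between,
                               sd_session = spec$sd_session,
                               sd_image = spec$sd_image),
    icc_2k = closed_form_icc2k(spec),
    spec = spec), class = "synthetic_truth")
  list(measurements = measurements, truth = truth)
}
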