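## Responder-style classification of longitudinal change against MDC90 and
## cohort frequency summaries.

CHANGE_LEVELS <- c("thinning", "no_change", "thickening")

#' Classify a thickness change against the minimal detectable change
#'
#' "Exceeded" is strict: `thickening` if `delta > mdc`, `thinning` if
#' `delta < -mdc`, otherwise `no_change` (a change exactly equal to the MDC
#' is not a detected change).
#'
#' @param delta change in mm (session 2 minus session 1); vectorized
#' @param mdc the region's MDC90 in mm, >= 0 (recycled)
#' @return factor with levels `thinning`, `no_change`, `thickening`
#' @export
classify_change <- function(delta, mdc) {
  if (any(is.na(mdc)) || any(mdc < 0)) {
    uc_stop("mdc must be >= 0 (Inf allowed)", "domain_error")
  }
  if (any(!is.finite(delta))) uc_stop("delta must be finite", "domain_error")
  lab <- ifelse(delta > mdc, "thickening",
                ifelse(delta < -mdc, "thinning", "no_change"))
  factor(lab, levels = CHANGE_LEVELS)
}

#' Per-knee, per-region change labels across two sessions
#'
#' Averages repeated images within each subject/limb/region/session, takes
#' the delta between the two sessions (later minus earlier, by session sort
#' order), and labels each knee-region with [classify_change()] using that
#' region's MDC. Participants missing either session for any present
#' limb/region are an error (no imputation), listing the offenders.
#'
#' @param measurements long data.frame: `subject`, `limb`, `region`,
#'   `session`, `thickness_mm` (optionally `image_index`); exactly two
#'   distinct sessions
#' @param mdc named numeric vector of MDC90 per region (mm), names covering
#'   every region present, or a data.frame with columns `region`, `mdc90`
#' @return a `change_matrix`: data.frame `subject`, `limb`, `region`,
#'   `delta_mm`, `label`, with the MDC lookup in `attr(, "mdc")`
#' @export
build_change_matrix <- function(measurements, mdc) {
  m <- check_measurements(measurements)
  if (!"limb" %in% names(m)) m$limb <- "involved"
  if (is.data.frame(mdc)) mdc <- setNames(mdc$mdc90, mdc$region)
  sessions <- sort(unique(m$session))
  if (length(sessions) != 2L) {
    uc_stop("change classification needs exactly two sessions",
            "schema_error")
  }
  regions <- unique(m$region)
  miss <- setdiff(regions, names(mdc))
  if (length(miss)) {
    uc_stop(paste0("no MDC supplied for region(s): ",
                   paste(miss, collapse = ", ")), "schema_error")
  }
  agg <- stats::aggregate(thickness_mm ~ subject + limb + region + session,
                          data = m, FUN = mean)
  s1 <- agg[agg$session == sessions[1L], ]
  s2 <- agg[agg$session == sessions[2L], ]
  key <- function(d) paste(d$subject, d$limb, d$region, sep = "\r")
  mg <- merge(s1, s2, by = c("subject", "limb", "region"),
              suffixes = c("_1", "_2"), all = TRUE)
  bad <- is.na(mg$thickness_mm_1) | is.na(mg$thickness_mm_2)
  if (any(bad)) {
    uc_stop(paste0("participants missing a session: ",
                   paste(unique(mg$subject[bad]), collapse = ", ")),
            "incomplete_participant_error")
  }
  out <- data.frame(subject = mg$subject, limb = mg$limb, region = mg$region,
                    delta_mm = mg$thickness_mm_2 - mg$thickness_mm_1,
                    stringsAsFactors = FALSE)
  out$label <- classify_change(out$delta_mm, unname(mdc[out$region]))
  out <- out[order(out$subject, out$limb, match(out$region, REGIONS)), ]
  rownames(out) <- NULL
  attr(out, "mdc") <- mdc
  class(out) <- c("change_matrix", "data.frame")
  out
}

#' Cohort frequency of MDC-exceeding change
#'
#' Per limb: the percentage of participants with at least one region labeled
#' `thickening`, and with at least one region labeled `thinning`. The two
#' categories are not mutually exclusive -- a participant with a thickening
#' region and a thinning region counts in both, which is the only counting
#' rule consistent with reporting the two percentages separately per limb.
#'
#' @param cm a [build_change_matrix()] result
#' @return data.frame: `limb`, `n`, `pct_thickening`, `pct_thinning`
#' @export
frequency_summary <- function(cm) {
  if (nrow(cm) == 0L) uc_stop("empty change matrix", "schema_error")
  out <- lapply(split(as.data.frame(cm), cm$limb), function(d) {
    subj <- unique(d$subject)
    any_lab <- function(lab) {
      vapply(subj, function(s) any(d$label[d$subject == s] == lab), logical(1))
    }
    data.frame(limb = d$limb[1L], n = length(subj),
               pct_thickening = 100 * mean(any_lab("thickening")),
               pct_thinning = 100 * mean(any_lab("thinning")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
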