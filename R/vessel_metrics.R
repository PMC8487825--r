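# Clinical measurement rules for lower-extremity arterial ultrasound:
# triplicate / bilateral averaging, IMT classification, plaque calling,
# percent-diameter stenosis rate, ordinal grading, worst-lesion reduction.

#' Stenosis grade levels
#'
#' Ordinal severity classes used throughout the package: grade 0 (no
#' stenosis) through grade IV (occlusion with no detectable flow).
#'
#' @return Character vector of the five grade labels, in increasing severity.
#' @export
stenosis_grades <- function() c("0", "I", "II", "III", "IV")

as_grade <- function(x) {
  g <- factor(as.character(x), levels = stenosis_grades(), ordered = TRUE)
  if (anyNA(g) && !anyNA(x)) stop("unknown stenosis grade label")
  g
}

#' Average triplicate readings
#'
#' Each index is measured three times and the arithmetic mean is taken.
#'
#' @param readings Numeric vector of exactly 3 finite readings.
#' @return The arithmetic mean.
#' @export
#' @examples
#' triplicate_average(c(0.8, 0.9, 1.0))
triplicate_average <- function(readings) {
  if (length(readings) != 3L) {
    stop("triplicate_average() requires exactly 3 readings, got ", length(readings))
  }
  if (!all(is.finite(readings))) stop("readings must be finite")
  mean(readings)
}

#' Bilateral IMT average
#'
#' Intima-media thickness is reported per anatomical segment as the mean of
#' the left and right sides.
#'
#' @param left,right IMT in mm, both strictly positive. Vectorised.
#' @return `(left + right) / 2` in mm.
#' @export
bilateral_imt <- function(left, right) {
  if (any(!is.finite(left)) || any(!is.finite(right)) ||
      any(left <= 0) || any(right <= 0)) {
    stop("bilateral_imt(): both sides must be finite and > 0")
  }
  (left + right) / 2
}

#' Classify intima-media thickness
#'
#' IMT at or below 0.9 mm is normal; strictly above 0.9 mm is thickened.
#'
#' @param imt IMT in mm (vectorised), > 0.
#' @return Character vector, `"normal"` or `"thickened"`.
#' @export
classify_imt <- function(imt) {
  if (any(!is.finite(imt)) || any(imt <= 0)) stop("classify_imt(): imt must be > 0")
  ifelse(imt <= 0.9, "normal", "thickened")
}

#' Call plaque from wall thickening
#'
#' A plaque is called when localized or diffuse wall thickening exceeds
#' 1.2 mm (strictly). The localized/diffuse distinction is carried through
#' but both modes share the threshold.
#'
#' @param wall_thickening Thickening in mm, >= 0 (vectorised).
#' @param mode One of `"localized"`, `"diffuse"`, `"none"` (vectorised).
#' @return Logical plaque call.
#' @export
call_plaque <- function(wall_thickening, mode) {
  if (any(!is.finite(wall_thickening)) || any(wall_thickening < 0)) {
    stop("call_plaque(): wall_thickening must be finite and >= 0")
  }
  ok <- mode %in% c("localized", "diffuse", "none")
  if (!all(ok)) stop("call_plaque(): unknown thickening mode: ", mode[!ok][1])
  mode != "none" & wall_thickening > 1.2
}

#' Percent-diameter stenosis rate
#'
#' `rate = ((d2 - d1) / d2) * 100`, where `d1` is the residual lumen inner
#' diameter at the stenosis and `d2` the original lumen inner diameter.
#'
#' @param d1 Residual diameter, mm; `0 <= d1 <= d2` (vectorised).
#' @param d2 Original diameter, mm; `> 0`.
#' @return Stenosis rate in percent, in `[0, 100]`.
#' @export
#' @examples
#' stenosis_rate(8, 10)  # 20
stenosis_rate <- function(d1, d2) {
  if (any(!is.finite(d1)) || any(!is.finite(d2))) stop("diameters must be finite")
  if (any(d2 <= 0)) stop("stenosis_rate(): d2 must be > 0")
  if (any(d1 < 0)) stop("stenosis_rate(): d1 must be >= 0")
  if (any(d1 > d2)) stop("stenosis_rate(): d1 must not exceed d2")
  (d2 - d1) / d2 * 100
}

#' Grade a stenosis rate
#'
#' Ordinal grading of the percent-diameter reduction: grade 0 for rate < 1,
#' I for \[1, 20), II for \[20, 50), III for \[50, 100), and IV for complete
#' occlusion (rate = 100 with no flow signal). The half-open bins make the
#' printed integer ranges total over real-valued rates. A rate of 100 with
#' flow recorded is an inconsistent measurement and raises an error.
#'
#' @param rate Stenosis rate in percent, in `[0, 100]` (vectorised).
#' @param flow_present Logical; whether a Doppler flow signal was detected.
#' @return Ordered factor with levels [stenosis_grades()].
#' @export
#' @examples
#' grade_stenosis(20, TRUE)    # II
#' grade_stenosis(100, FALSE)  # IV
grade_stenosis <- function(rate, flow_present = TRUE) {
  if (any(!is.finite(rate)) || any(rate < 0) || any(rate > 100)) {
    stop("grade_stenosis(): rate must lie in [0, 100]")
  }
  n <- max(length(rate), length(flow_present))
  rate <- rep_len(rate, n)
  flow_present <- rep_len(flow_present, n)
  bad <- rate == 100 & flow_present
  if (any(bad)) {
    stop("grade_stenosis(): rate of 100% with flow present is inconsistent")
  }
  g <- character(n)
  g[rate < 1] <- "0"
  g[rate >= 1 & rate < 20] <- "I"
  g[rate >= 20 & rate < 50] <- "II"
  g[rate >= 50 & rate < 100] <- "III"
  g[rate == 100] <- "IV"
  as_grade(g)
}

#' Worst-lesion reduction
#'
#' When a segment holds several lesions, the most severe stenosis prevails.
#'
#' @param grades Non-empty vector of grade labels or an ordered grade factor.
#' @return The maximum grade, as an ordered factor.
#' @export
worst_lesion <- function(grades) {
  if (length(grades) == 0L) stop("worst_lesion(): empty grade list")
  g <- as_grade(grades)
  g[which.max(as.integer(g))]
}

#' Annotate a cohort table with derived vessel metrics
#'
#' Takes the tidy cohort table produced by [generate_cohort()] (one row per
#' subject-side-segment) and appends: the bilateral (left/right mean) IMT for
#' the row's subject-segment, its classification, the plaque call recomputed
#' from wall thickening and mode, the stenosis rate recomputed from the
#' diameters, and the recomputed grade.
#'
#' @param cohort Data frame with at least columns `subject_id`, `segment`,
#'   `side`, `imt_mm`, `wall_thickening_mm`, `thickening_mode`, `d1_mm`,
#'   `d2_mm`, `flow_present`.
#' @return The input with columns `imt_bilateral_mm`, `imt_class`,
#'   `plaque_call`, `stenosis_rate_pct`, `grade_derived` appended.
#' @export
annotate_cohort <- function(cohort) {
  need <- c("subject_id", "segment", "side", "imt_mm", "wall_thickening_mm",
            "thickening_mode", "d1_mm", "d2_mm", "flow_present")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("annotate_cohort(): missing columns: ",
                         paste(miss, collapse = ", "))
  key <- interaction(cohort$subject_id, cohort$segment, drop = TRUE)
  bil <- vapply(split(cohort$imt_mm, key), function(v) {
    if (length(v) == 2L) bilateral_imt(v[1], v[2]) else mean(v)
  }, 0)
  cohort$imt_bilateral_mm <- bil[as.character(key)]
  cohort$imt_class <- classify_imt(cohort$imt_bilateral_mm)
  cohort$plaque_call <- call_plaque(cohort$wall_thickening_mm, cohort$thickening_mode)
  cohort$stenosis_rate_pct <- stenosis_rate(cohort$d1_mm, cohort$d2_mm)
  cohort$grade_derived <- grade_stenosis(cohort$stenosis_rate_pct, cohort$flow_present)
  cohort
}
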