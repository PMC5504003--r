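#' Ocular perfusion pressure
#'
#' Computes mean ocular perfusion pressure from brachial blood pressure and
#' intraocular pressure:
#' \deqn{OPP = \frac{2}{3}\left[dBP + \frac{1}{3}(sBP - dBP)\right] - IOP}
#' i.e. two-thirds of the estimated mean arterial pressure minus IOP.  The
#' formula is linear in all three arguments, so group means commute with it.
#'
#' @param sbp_mmHg systolic blood pressure (mmHg).
#' @param dbp_mmHg diastolic blood pressure (mmHg); must not exceed
#'   \code{sbp_mmHg}.
#' @param iop_mmHg intraocular pressure (mmHg), non-negative.
#' @return ocular perfusion pressure in mmHg (vectorised).
#' @examples
#' compute_opp(116.0, 69.2, 17.1)  # 39.43 mmHg
#' @export
compute_opp <- function(sbp_mmHg, dbp_mmHg, iop_mmHg) {
  if (any(dbp_mmHg <= 0, na.rm = TRUE) || any(sbp_mmHg <= 0, na.rm = TRUE))
    stopf("blood pressures must be positive")
  if (any(iop_mmHg < 0, na.rm = TRUE))
    stopf("iop_mmHg must be non-negative")
  if (any(sbp_mmHg < dbp_mmHg, na.rm = TRUE))
    stopf("systolic pressure below diastolic pressure")
  2 / 3 * (dbp_mmHg + (sbp_mmHg - dbp_mmHg) / 3) - iop_mmHg
}

#' Convert decimal visual acuity to logMAR
#'
#' logMAR is the base-10 logarithm of the minimum angle of resolution, i.e.
#' \eqn{-\log_{10}} of decimal acuity.  Decimal 1.0 (20/20) maps to 0.0 and
#' the common study inclusion floor of 0.5 (20/40) maps to 0.301.
#'
#' @param decimal_acuity decimal visual acuity, strictly positive.
#' @return logMAR acuity (vectorised).
#' @export
decimal_to_logmar <- function(decimal_acuity) {
  if (any(!is.finite(decimal_acuity)) || any(decimal_acuity <= 0))
    stopf("decimal_acuity must be positive and finite")
  -log10(decimal_acuity)
}

#' Percent change from baseline
#'
#' \code{100 * (follow_up - baseline) / baseline}.  Within a cohort analysis
#' percent changes are computed per subject and then averaged (the mean of
#' per-subject changes, not the change of group means): the two differ on
#' skewed data and the per-subject form is the one a paired design reports.
#'
#' @param baseline_value baseline measurement, non-zero.
#' @param follow_up_value follow-up measurement.
#' @return percent change (vectorised).
#' @examples
#' percent_change(1.0, 1.149)  # 14.9
#' @export
percent_change <- function(baseline_value, follow_up_value) {
  if (any(baseline_value == 0, na.rm = TRUE))
    stopf("baseline_value must be non-zero")
  100 * (follow_up_value - baseline_value) / baseline_value
}
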