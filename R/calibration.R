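#' Chromatographic calibration constants
#'
#' The published calibration lines that convert raw capacity factors into
#' the descriptor suite, together with the interpretation thresholds used
#' throughout the package. They ship as data so that a laboratory running
#' its own calibration standards can recalibrate without touching code:
#' pass a modified copy wherever a `calibration` argument is accepted.
#'
#' @return A named list with components:
#' \describe{
#'   \item{brlogd}{`c(slope, intercept)` mapping log k'60 (XBridge RP18,
#'     60\% MeCN) to BRlogD, the chromatographic log D_oct surrogate.}
#'   \item{clogkw_iam}{`c(slope, intercept)` mapping BRlogD to the
#'     lipophilicity-predicted baseline of log kw IAM for a neutral
#'     compound with zero polar surface area.}
#'   \item{chamelogk_strong}{Chamelogk above which a compound is classed a
#'     strong chameleon.}
#'   \item{delta_excessive}{Delta log kw IAM above which polarity is
#'     flagged excessive for oral absorption.}
#'   \item{f_very_low, f_low}{Oral bioavailability class boundaries (\%).}
#'   \item{ionization_depression}{log10 k' depression (relative to the
#'     maximum across pH) treated as evidence of ionization.}
#' }
#' @examples
#' cal <- chromatographic_calibration()
#' cal$brlogd  # slope 3.31, intercept 2.79
#' @export
chromatographic_calibration <- function() {
  list(
    brlogd = c(slope = 3.31, intercept = 2.79),
    clogkw_iam = c(slope = 0.92, intercept = -1.03),
    chamelogk_strong = 0.6,
    delta_excessive = 1.5,
    f_very_low = 1,
    f_low = 5,
    ionization_depression = 0.3
  )
}
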