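#' Log10 capacity factor from retention and dead time
#'
#' The capacity factor k' = (t_R - t_0) / t_0 expresses retention in
#' column-independent units; chromatographic lipophilicity work uses its
#' base-10 logarithm throughout.
#'
#' @param t_r Retention time of the analyte (minutes). Vectorized.
#' @param t_0 Dead (void) time of the system (minutes).
#' @return log10 k', same length as `t_r`.
#' @examples
#' capacity_factor(2, 1)    # k' = 1  -> 0
#' capacity_factor(11, 1)   # k' = 10 -> 1
#' @export
capacity_factor <- function(t_r, t_0) {
  if (any(!is.finite(t_0)) || any(t_0 <= 0)) {
    stop("invalid dead time: t_0 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(t_r)) || any(t_r <= t_0)) {
    stop("non-retained solute: t_r must exceed t_0", call. = FALSE)
  }
  log10((t_r - t_0) / t_0)
}

#' BRlogD from log k'60 on the RP18 phase
#'
#' Converts the capacity factor at 60\% MeCN on an XBridge Shield RP18
#' column into BRlogD, a chromatographic surrogate of the octanol/water
#' distribution coefficient, via the laboratory calibration line.
#'
#' @param logk60 log10 capacity factor at 60\% MeCN. Vectorized.
#' @param calibration Calibration list, see [chromatographic_calibration()].
#' @return BRlogD (unitless).
#' @examples
#' brlogd(0)  # the calibration intercept, 2.79
#' @export
brlogd <- function(logk60, calibration = chromatographic_calibration()) {
  stopifnot(is.numeric(logk60))
  if (any(!is.finite(logk60))) stop("logk60 must be finite", call. = FALSE)
  cf <- calibration$brlogd
  unname(cf["slope"] * logk60 + cf["intercept"])
}

#' Predicted baseline IAM lipophilicity
#'
#' clog kw IAM is the log kw IAM expected for a neutral compound with zero
#' polar surface area at a given BRlogD; the gap between measurement and
#' this baseline is the polarity descriptor [delta_logkw_iam()].
#'
#' @param brlogd_value BRlogD (unitless). Vectorized.
#' @inheritParams brlogd
#' @return clog kw IAM (unitless).
#' @examples
#' clogkw_iam(0)  # the calibration intercept, -1.03
#' @export
clogkw_iam <- function(brlogd_value, calibration = chromatographic_calibration()) {
  stopifnot(is.numeric(brlogd_value))
  if (any(!is.finite(brlogd_value))) stop("brlogd must be finite", call. = FALSE)
  cf <- calibration$clogkw_iam
  unname(cf["slope"] * brlogd_value + cf["intercept"])
}

#' Polarity descriptor delta log kw IAM
#'
#' Measured IAM lipophilicity minus its lipophilicity-predicted baseline.
#' Large positive values indicate polarity in excess of what general
#' lipophilicity explains; values above the `delta_excessive` threshold
#' (default 1.5) are associated with poor oral absorption.
#'
#' @param logkw_iam Measured log kw IAM (extrapolated to fully aqueous
#'   eluent). Vectorized.
#' @param brlogd_value BRlogD of the same compound.
#' @inheritParams brlogd
#' @return delta log kw IAM (unitless).
#' @seealso [flag_excessive_polarity()]
#' @export
delta_logkw_iam <- function(logkw_iam, brlogd_value,
                            calibration = chromatographic_calibration()) {
  stopifnot(is.numeric(logkw_iam))
  if (any(!is.finite(logkw_iam))) stop("logkw_iam must be finite", call. = FALSE)
  logkw_iam - clogkw_iam(brlogd_value, calibration)
}

#' Flag excessive polarity
#'
#' @param delta delta log kw IAM values.
#' @param threshold Flagging threshold (default 1.5).
#' @return Logical vector; `TRUE` where polarity is excessive.
#' @export
flag_excessive_polarity <- function(delta,
                                    threshold = chromatographic_calibration()$delta_excessive) {
  !is.na(delta) & delta > threshold
}

#' Fit the isocratic retention line
#'
#' Ordinary least-squares fit of log10 k' on the organic fraction of the
#' mobile phase. The line is the workhorse of both the fully-aqueous
#' extrapolation (log kw IAM) and the Chamelogk extrapolation to 100\%
#' organic.
#'
#' @param organic_fraction Percent organic modifier (v/v), length >= 2.
#' @param logk log10 capacity factors at those fractions.
#' @return An object of class `"retention_line"`: a list with `slope`
#'   (per percent), `intercept` (log10 k' at 0\% organic), `r2`,
#'   `n_points` and `fraction_range`.
#' @examples
#' fit_retention_line(c(50, 60, 70), c(-0.5, -1.0, -1.5))
#' @export
fit_retention_line <- function(organic_fraction, logk) {
  stopifnot(is.numeric(organic_fraction), is.numeric(logk))
  keep <- is.finite(organic_fraction) & is.finite(logk)
  x <- organic_fraction[keep]
  y <- logk[keep]
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("insufficient data: need >= 2 distinct organic fractions", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r2 <- if (length(x) == 2L || stats::var(y) == 0) 1 else
    unname(stats::cor(x, y)^2)
  structure(
    list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
         r2 = r2, n_points = length(x),
         fraction_range = range(x)),
    class = "retention_line"
  )
}

#' @export
print.retention_line <- function(x, ...) {
  cat(sprintf(
    "Retention line: log k' = %.4f %+.4f * fraction  (n = %d, r2 = %.3f, range %g-%g%%)\n",
    x$intercept, x$slope, x$n_points, x$r2,
    x$fraction_range[1L], x$fraction_range[2L]))
  invisible(x)
}

#' Evaluate a retention line at a given organic fraction
#'
#' @param line A `"retention_line"`.
#' @param organic_fraction Percent organic.
#' @return Predicted log10 k'.
#' @export
predict_retention <- function(line, organic_fraction) {
  stopifnot(inherits(line, "retention_line"))
  line$intercept + line$slope * organic_fraction
}

#' Extrapolated IAM lipophilicity, log kw IAM
#'
#' Fits the retention line over the measured IAM compositions (typically
#' 10-50\% MeCN) and extrapolates it to the fully aqueous eluent. The
#' extrapolation target is exposed because conventions differ; the default,
#' 0\% organic, matches the w (water) subscript of the descriptor.
#'
#' @param organic_fraction Percent MeCN of each IAM measurement.
#' @param logk log10 k' at those compositions.
#' @param target_fraction Organic fraction to extrapolate to (default 0).
#' @return log kw IAM (unitless).
#' @examples
#' logkw_iam_extrapolate(c(10, 30, 50), c(2.9, 2.7, 2.5))  # 3.0
#' @export
logkw_iam_extrapolate <- function(organic_fraction, logk, target_fraction = 0) {
  line <- fit_retention_line(organic_fraction, logk)
  predict_retention(line, target_fraction)
}

#' Chamelogk, the chromatographic chameleonicity index
#'
#' On the polymeric PLRP-S phase a non-chameleonic solute follows a single
#' linear trend of log k' versus organic fraction. A chameleon folds in
#' the nearly pure organic eluent, masking polarity and retaining more
#' strongly than the trend predicts. Chamelogk is that positive deviation:
#' the measured log k' at 100\% MeCN minus the value extrapolated from the
#' linear 50/60/70\% regime.
#'
#' @param line_points Data frame with columns `organic_fraction` and
#'   `logk` holding the 50, 60 and 70\% MeCN observations. Compositions
#'   other than 50/60/70 are ignored with a warning.
#' @param measured_logk100 log10 k' measured at 100\% MeCN.
#' @return Chamelogk (unitless).
#' @examples
#' pts <- data.frame(organic_fraction = c(50, 60, 70),
#'                   logk = c(1.0, 0.5, 0.0))
#' chamelogk(pts, measured_logk100 = -0.7)  # 0.8 above the trend
#' @export
chamelogk <- function(line_points, measured_logk100) {
  stopifnot(is.data.frame(line_points),
            all(c("organic_fraction", "logk") %in% names(line_points)))
  wanted <- c(50, 60, 70)
  extra <- setdiff(unique(line_points$organic_fraction), wanted)
  if (length(extra)) {
    warning("ignoring organic fractions outside the 50/60/70 design: ",
            paste(extra, collapse = ", "), call. = FALSE)
    line_points <- line_points[line_points$organic_fraction %in% wanted, ]
  }
  have <- wanted %in% line_points$organic_fraction
  if (!all(have) || length(measured_logk100) != 1L || !is.finite(measured_logk100)) {
    stop("insufficient data: Chamelogk needs log k' at 50, 60, 70 and 100% MeCN",
         call. = FALSE)
  }
  line <- fit_retention_line(line_points$organic_fraction, line_points$logk)
  measured_logk100 - predict_retention(line, 100)
}

#' Classify chameleonicity from Chamelogk
#'
#' @param chamelogk_value Chamelogk values.
#' @param threshold Strong-chameleon threshold (default 0.6).
#' @return Character vector, `"strong"` or `"weak"` (`NA` propagated).
#' @export
classify_chameleon <- function(chamelogk_value,
                               threshold = chromatographic_calibration()$chamelogk_strong) {
  ifelse(is.na(chamelogk_value), NA_character_,
         ifelse(chamelogk_value > threshold, "strong", "weak"))
}

#' EPSA-to-TPSA ratio
#'
#' ETR compares the experimentally observed polar surface area (EPSA, from
#' supercritical-fluid chromatography) with the topological expectation
#' (TPSA). Ratios well below 1 indicate conformation-dependent polarity
#' masking.
#'
#' @param epsa EPSA in square Angstrom (>= 0).
#' @param tpsa TPSA in square Angstrom (> 0).
#' @return ETR (unitless).
#' @export
etr <- function(epsa, tpsa) {
  stopifnot(is.numeric(epsa), is.numeric(tpsa))
  if (any(!is.na(tpsa) & tpsa <= 0)) {
    stop("invalid denominator: TPSA must be > 0", call. = FALSE)
  }
  if (any(!is.na(epsa) & epsa < 0)) {
    stop("EPSA must be >= 0", call. = FALSE)
  }
  epsa / tpsa
}

#' Ionization class from the pH-retention profile
#'
#' Retention of the neutral species on the PLRP-S phase is pH-independent;
#' ionization depresses retention. Comparing log k'80 at acidic, neutral
#' and basic pH therefore reveals the ionization behavior across the pH
#' range that matters for oral absorption. Depression at both extremes
#' marks an ampholyte; depression at pH 2 only marks a base (ionized in
#' the gastric pH range even when neutral at pH 7, so it is reported as
#' such); otherwise a profile whose pH 7 retention sits within
#' `depression` log units of the maximum is dominantly neutral at
#' physiological and gastric pH; depression at pH 12 only, with pH 7
#' retention also depressed, marks an acid partially ionized at pH 7.
#'
#' @param logk80_by_ph Named numeric vector of log10 k'80, names `"2"`,
#'   `"7"`, `"12"`.
#' @param depression Depression threshold in log10 units (default 0.3,
#'   clearly above retention-time reproducibility noise).
#' @return One of `"NEUTRAL"`, `"BASE_IONIZED"`, `"ACID_IONIZED"`,
#'   `"AMPHOTERIC"`, `"UNDETERMINED"`.
#' @examples
#' ionization_class(c(`2` = 0.2, `7` = 1.0, `12` = 1.0))  # BASE_IONIZED
#' @export
ionization_class <- function(logk80_by_ph,
                             depression = chromatographic_calibration()$ionization_depression) {
  need <- c("2", "7", "12")
  if (!all(need %in% names(logk80_by_ph)) ||
      any(!is.finite(logk80_by_ph[need]))) {
    warning("pH profile incomplete; ionization class undetermined", call. = FALSE)
    return("UNDETERMINED")
  }
  v <- logk80_by_ph[need]
  m <- max(v)
  low2 <- (m - v["2"]) > depression
  low12 <- (m - v["12"]) > depression
  if (low2 && low12) return("AMPHOTERIC")
  if (low2) return("BASE_IONIZED")
  if (m - v["7"] <= depression) return("NEUTRAL")
  if (low12) return("ACID_IONIZED")
  # pH 7 depressed but neither extreme is: no consistent reading
  warning("pH profile depressed only at pH 7; ionization class undetermined",
          call. = FALSE)
  "UNDETERMINED"
}
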