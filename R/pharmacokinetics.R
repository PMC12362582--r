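#' Noncompartmental AUC by the trapezoidal rule
#'
#' Area under the plasma concentration-time curve from the first to the
#' last observed time point, with no extrapolation to infinity. The
#' default linear trapezoid is the conservative noncompartmental choice;
#' `"linear-log"` switches to the linear-up/log-down hybrid often used for
#' declining phases.
#'
#' Concentrations reported as `NA` (below the limit of quantification)
#' are dropped with a warning before integration.
#'
#' @param time Sampling times (hours), strictly increasing.
#' @param conc Plasma concentrations (ng/mL), non-negative.
#' @param method `"linear"` (default) or `"linear-log"`.
#' @return AUC in ng*h/mL.
#' @examples
#' auc_trapezoid(c(0, 4), c(10, 10))        # 40
#' auc_trapezoid(c(0, 2, 4), c(0, 10, 0))   # 20
#' @export
auc_trapezoid <- function(time, conc, method = c("linear", "linear-log")) {
  method <- match.arg(method)
  stopifnot(is.numeric(time), is.numeric(conc), length(time) == length(conc))
  blq <- is.na(conc)
  if (any(blq)) {
    warning(sum(blq), " BLQ/missing concentration(s) dropped", call. = FALSE)
    time <- time[!blq]
    conc <- conc[!blq]
  }
  if (length(time) < 2L) stop("invalid profile: need >= 2 timepoints", call. = FALSE)
  if (any(diff(time) <= 0)) {
    stop("invalid profile: times must be strictly increasing", call. = FALSE)
  }
  if (any(conc < 0)) stop("invalid profile: negative concentration", call. = FALSE)
  if (method == "linear") return(pracma::trapz(time, conc))
  # linear-up / log-down: log interpolation where concentration declines
  # between two positive values, linear otherwise
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1L]
  logdown <- c2 < c1 & c2 > 0
  seg <- ifelse(logdown,
                dt * (c1 - c2) / log(c1 / c2),
                dt * (c1 + c2) / 2)
  sum(seg)
}

#' Oral bioavailability from paired oral and IV profiles
#'
#' F\% is the ratio of dose-normalized oral to intravenous exposure:
#' F\% = (AUC_oral / dose_oral) / (AUC_IV / dose_IV) * 100. The result is
#' also classed as very low (F < 1\%), low (F < 5\%) or medium/high
#' (F > 5\%).
#'
#' @param oral,iv Lists (or one-row data frames) with elements `dose`
#'   (mg/kg), `time` (h) and `conc` (ng/mL); `compound_id` optional.
#' @param method AUC method, see [auc_trapezoid()].
#' @return A list of class `"bioavailability"`: `compound_id`, `auc_oral`,
#'   `auc_iv`, `auc_dn_oral`, `auc_dn_iv`, `f_percent`, `f_class`.
#' @examples
#' oral <- list(dose = 30, time = c(0, 1, 2, 4, 8), conc = c(0, 60, 80, 40, 10))
#' iv <- list(dose = 5, time = c(0, 1, 2, 4, 8), conc = c(200, 120, 70, 25, 5))
#' oral_bioavailability(oral, iv)
#' @export
oral_bioavailability <- function(oral, iv, method = "linear") {
  for (p in list(oral, iv)) {
    stopifnot(is.list(p), all(c("dose", "time", "conc") %in% names(p)))
    if (!is.numeric(p$dose) || p$dose <= 0) stop("dose must be > 0", call. = FALSE)
  }
  auc_oral <- auc_trapezoid(oral$time, oral$conc, method)
  auc_iv <- auc_trapezoid(iv$time, iv$conc, method)
  if (auc_iv == 0) {
    stop("undefined bioavailability: IV AUC is zero", call. = FALSE)
  }
  dn_oral <- auc_oral / oral$dose
  dn_iv <- auc_iv / iv$dose
  f <- dn_oral / dn_iv * 100
  structure(
    list(compound_id = oral$compound_id %||% NA_character_,
         auc_oral = auc_oral, auc_iv = auc_iv,
         auc_dn_oral = dn_oral, auc_dn_iv = dn_iv,
         f_percent = f, f_class = bioavailability_class(f)),
    class = "bioavailability"
  )
}

#' @export
print.bioavailability <- function(x, ...) {
  cat(sprintf("F%% = %.2f (%s)  [AUC_DN oral %.3g, IV %.3g ng*h/mL per mg/kg]\n",
              x$f_percent, x$f_class, x$auc_dn_oral, x$auc_dn_iv))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bioavailability for every compound in a long-format PK table
#'
#' @param pk Data frame with columns `compound_id`, `route` (`"ORAL"` /
#'   `"IV"`), `dose` (mg/kg), `time_h`, `conc_ng_ml`.
#' @param method AUC method, see [auc_trapezoid()].
#' @return Data frame, one row per compound with both routes present:
#'   `compound_id`, `auc_oral`, `auc_iv`, `auc_dn_oral`, `auc_dn_iv`,
#'   `f_percent`, `f_class`.
#' @export
compute_bioavailability <- function(pk, method = "linear") {
  req <- c("compound_id", "route", "dose", "time_h", "conc_ng_ml")
  stopifnot(is.data.frame(pk), all(req %in% names(pk)))
  ids <- unique(pk$compound_id)
  rows <- lapply(ids, function(id) {
    d <- pk[pk$compound_id == id, , drop = FALSE]
    profile <- function(route) {
      p <- d[d$route == route, , drop = FALSE]
      if (nrow(p) < 2L) return(NULL)
      p <- p[order(p$time_h), , drop = FALSE]
      list(compound_id = id, dose = p$dose[1L], time = p$time_h, conc = p$conc_ng_ml)
    }
    oral <- profile("ORAL")
    iv <- profile("IV")
    if (is.null(oral) || is.null(iv)) {
      warning("compound ", id, " lacks a complete oral/IV pair; skipped",
              call. = FALSE)
      return(NULL)
    }
    b <- oral_bioavailability(oral, iv, method)
    data.frame(compound_id = id, auc_oral = b$auc_oral, auc_iv = b$auc_iv,
               auc_dn_oral = b$auc_dn_oral, auc_dn_iv = b$auc_dn_iv,
               f_percent = b$f_percent, f_class = b$f_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
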