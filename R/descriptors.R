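#' Compute the full chromatographic descriptor suite per compound
#'
#' Consumes a long-format retention table (one row per injection) and an
#' optional compound metadata table and assembles one descriptor row per
#' compound: log k'60 RP18 and BRlogD, log k'80 PLRP-S, the IAM
#' extrapolation log kw IAM with its predicted baseline and delta,
#' Chamelogk with its chameleon class, ETR, and the pH-retention
#' ionization class. A descriptor is computed only when its measurements
#' are present; otherwise it is `NA`.
#'
#' The measurement design expected per compound (all at pH 7 unless
#' noted): RP18 at 60\% MeCN; PLRP-S at 50, 60, 70, 80 and 100\% MeCN
#' plus 80\% at pH 2 and pH 12; IAM at two or more compositions in the
#' 10-50\% range.
#'
#' @param retention Data frame with columns `compound_id`, `system`
#'   (`"RP18"`, `"PLRP_S"`, `"IAM"`), `organic_fraction`, `ph`, `t_r`,
#'   `t_0` (times in minutes). Rows with `t_r <= t_0` are rejected.
#' @param meta Optional data frame with `compound_id` and any of `epsa`,
#'   `tpsa` (square Angstrom); needed for ETR.
#' @param calibration See [chromatographic_calibration()].
#' @param logkw_target_fraction Organic fraction the IAM line is
#'   extrapolated to (default 0, fully aqueous).
#' @return Data frame with one row per compound: `compound_id`,
#'   `logk60_rp18`, `brlogd`, `logk80_plrps`, `logkw_iam`, `clogkw_iam`,
#'   `delta_logkw_iam`, `excessive_polarity`, `chamelogk`,
#'   `chameleon_class`, `epsa`, `tpsa`, `etr`, `ionization_class`.
#' @export
compute_descriptors <- function(retention, meta = NULL,
                                calibration = chromatographic_calibration(),
                                logkw_target_fraction = 0) {
  req <- c("compound_id", "system", "organic_fraction", "ph", "t_r", "t_0")
  stopifnot(is.data.frame(retention), all(req %in% names(retention)))
  bad <- !is.finite(retention$t_r) | !is.finite(retention$t_0) |
    retention$t_0 <= 0 | retention$t_r <= retention$t_0
  if (any(bad)) {
    warning(sum(bad), " retention measurement(s) rejected (t_r <= t_0 or invalid)",
            call. = FALSE)
    retention <- retention[!bad, , drop = FALSE]
  }
  retention$logk <- log10((retention$t_r - retention$t_0) / retention$t_0)

  ids <- unique(retention$compound_id)
  rows <- lapply(ids, function(id) {
    r <- retention[retention$compound_id == id, , drop = FALSE]
    pick <- function(system, fraction = NULL, ph = 7) {
      sel <- r$system == system & r$ph == ph
      if (!is.null(fraction)) sel <- sel & r$organic_fraction == fraction
      r[sel, , drop = FALSE]
    }
    one <- function(df) if (nrow(df) == 1L) df$logk else NA_real_

    logk60 <- one(pick("RP18", 60))
    brd <- if (is.finite(logk60)) brlogd(logk60, calibration) else NA_real_

    logk80 <- one(pick("PLRP_S", 80))

    iam <- pick("IAM")
    iam <- iam[iam$organic_fraction >= 10 & iam$organic_fraction <= 50, ,
               drop = FALSE]
    logkw <- if (nrow(iam) >= 2L && length(unique(iam$organic_fraction)) >= 2L) {
      logkw_iam_extrapolate(iam$organic_fraction, iam$logk,
                            target_fraction = logkw_target_fraction)
    } else NA_real_
    clogkw <- if (is.finite(brd)) clogkw_iam(brd, calibration) else NA_real_
    delta <- if (is.finite(logkw) && is.finite(clogkw)) logkw - clogkw else NA_real_

    line_pts <- pick("PLRP_S")
    line_pts <- line_pts[line_pts$organic_fraction %in% c(50, 60, 70), ,
                         drop = FALSE]
    lk100 <- one(pick("PLRP_S", 100))
    cham <- if (nrow(line_pts) == 3L && is.finite(lk100)) {
      chamelogk(data.frame(organic_fraction = line_pts$organic_fraction,
                           logk = line_pts$logk), lk100)
    } else NA_real_

    ion <- {
      prof <- vapply(c(2, 7, 12), function(p) {
        d <- pick("PLRP_S", 80, ph = p)
        if (nrow(d) == 1L) d$logk else NA_real_
      }, numeric(1))
      names(prof) <- c("2", "7", "12")
      if (all(is.finite(prof))) {
        ionization_class(prof, depression = calibration$ionization_depression)
      } else NA_character_
    }

    data.frame(
      compound_id = id, logk60_rp18 = logk60, brlogd = brd,
      logk80_plrps = logk80, logkw_iam = logkw, clogkw_iam = clogkw,
      delta_logkw_iam = delta,
      excessive_polarity = flag_excessive_polarity(delta, calibration$delta_excessive),
      chamelogk = cham,
      chameleon_class = classify_chameleon(cham, calibration$chamelogk_strong),
      ionization_class = ion,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  out$epsa <- NA_real_
  out$tpsa <- NA_real_
  if (!is.null(meta)) {
    stopifnot(is.data.frame(meta), "compound_id" %in% names(meta))
    j <- match(out$compound_id, meta$compound_id)
    if ("epsa" %in% names(meta)) out$epsa <- meta$epsa[j]
    if ("tpsa" %in% names(meta)) out$tpsa <- meta$tpsa[j]
  }
  out$etr <- ifelse(is.finite(out$epsa) & is.finite(out$tpsa) & out$tpsa > 0,
                    out$epsa / out$tpsa, NA_real_)
  rownames(out) <- NULL
  out
}
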