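#' Linear descriptor-descriptor relation with declared exclusions
#'
#' Simple OLS of one compound-level field on another, with r-squared
#' reported as the squared Pearson correlation (identical to the OLS
#' coefficient of determination for a simple linear fit). Outlier
#' exclusion is declarative: compounds are removed only when named in
#' `exclude`, never detected automatically.
#'
#' @param records Data frame of compound records (must contain
#'   `compound_id` and the two fields).
#' @param x_field,y_field Column names of predictor and response.
#' @param exclude Character vector of `compound_id`s to drop.
#' @return Object of class `"relation_result"`: `x_name`, `y_name`,
#'   `slope`, `intercept`, `r2`, `n_used`, `excluded_ids`.
#' @examples
#' d <- data.frame(compound_id = letters[1:5], x = 1:5, y = 2 * (1:5) + 1)
#' linear_relation(d, "x", "y")
#' @export
linear_relation <- function(records, x_field, y_field, exclude = character()) {
  stopifnot(is.data.frame(records), "compound_id" %in% names(records),
            all(c(x_field, y_field) %in% names(records)))
  d <- records[!(records$compound_id %in% exclude), , drop = FALSE]
  x <- d[[x_field]]
  y <- d[[y_field]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("insufficient data: need >= 3 usable records after exclusion",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(y) == 0) 1 else unname(stats::cor(x, y)^2)
  structure(
    list(x_name = x_field, y_name = y_field,
         slope = unname(cf[2L]), intercept = unname(cf[1L]),
         r2 = r2, n_used = length(x), excluded_ids = exclude),
    class = "relation_result"
  )
}

#' @export
print.relation_result <- function(x, ...) {
  excl <- if (length(x$excluded_ids)) {
    paste0("; excluded: ", paste(x$excluded_ids, collapse = ", "))
  } else ""
  cat(sprintf("%s ~ %s: slope %.4g, intercept %.4g, r2 = %.3f (n = %d%s)\n",
              x$y_name, x$x_name, x$slope, x$intercept, x$r2, x$n_used, excl))
  invisible(x)
}

#' Oral bioavailability class
#'
#' Very low (F < 1\%), low (F < 5\%) or medium/high (F > 5\%). The
#' boundaries themselves fall in the lower-severity class (F = 5 is LOW).
#'
#' @param f_percent Bioavailability in percent, >= 0. Vectorized.
#' @return Character vector: `"VERY_LOW"`, `"LOW"` or `"MEDIUM_HIGH"`.
#' @examples
#' bioavailability_class(c(0.5, 3, 20))
#' @export
bioavailability_class <- function(f_percent) {
  stopifnot(is.numeric(f_percent))
  if (any(!is.na(f_percent) & f_percent < 0)) {
    stop("invalid value: F% must be >= 0", call. = FALSE)
  }
  ifelse(is.na(f_percent), NA_character_,
         ifelse(f_percent < 1, "VERY_LOW",
                ifelse(f_percent <= 5, "LOW", "MEDIUM_HIGH")))
}

#' Count compounds in a bioavailability class
#'
#' @param records Data frame with an `f_percent` column.
#' @param class One of `"VERY_LOW"`, `"LOW"`, `"MEDIUM_HIGH"`.
#' @return Integer count.
#' @export
count_class <- function(records, class) {
  stopifnot(is.data.frame(records), "f_percent" %in% names(records))
  class <- match.arg(class, c("VERY_LOW", "LOW", "MEDIUM_HIGH"))
  if (nrow(records) == 0L) return(0L)
  sum(bioavailability_class(records$f_percent) == class, na.rm = TRUE)
}

#' Lipophilicity-polarity plane coordinates
#'
#' Emits, per compound, the (BRlogD, delta log kw IAM) coordinates with
#' the bioavailability class and the excessive-polarity flag — the 2D
#' partition in which well-absorbed compounds cluster at high
#' lipophilicity and low polarity. Rows missing any coordinate are
#' skipped with a warning.
#'
#' @param records Data frame with `compound_id`, `brlogd`,
#'   `delta_logkw_iam` and `f_percent`.
#' @param delta_threshold Excessive-polarity threshold (default 1.5).
#' @return Data frame: `compound_id`, `brlogd`, `delta_logkw_iam`,
#'   `f_class`, `excessive_polarity`.
#' @export
polarity_lipophilicity_plane <- function(records,
                                         delta_threshold = chromatographic_calibration()$delta_excessive) {
  req <- c("compound_id", "brlogd", "delta_logkw_iam", "f_percent")
  stopifnot(is.data.frame(records), all(req %in% names(records)))
  ok <- is.finite(records$brlogd) & is.finite(records$delta_logkw_iam)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped: missing plane coordinates",
            call. = FALSE)
  }
  d <- records[ok, , drop = FALSE]
  data.frame(
    compound_id = d$compound_id,
    brlogd = d$brlogd,
    delta_logkw_iam = d$delta_logkw_iam,
    f_class = bioavailability_class(d$f_percent),
    excessive_polarity = flag_excessive_polarity(d$delta_logkw_iam,
                                                 delta_threshold),
    stringsAsFactors = FALSE
  )
}
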