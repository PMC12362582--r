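#' Summarize a conformer ensemble in property space
#'
#' Reduces per-frame descriptors to the ensemble-level quantifiers used to
#' compare solvents and compounds: medians and IQRs of R_gyr and 3D PSA
#' 1.4, and the fraction of frames in the folded/low-polarity region
#' (R_gyr below `rgyr_threshold` AND 3D PSA 1.4 below `psa_threshold`).
#' The medians are preferred over means because conformer populations are
#' typically multimodal and skewed.
#'
#' @param frames Data frame of per-frame descriptors with columns `r_gyr`
#'   and `psa_14` (as from [ensemble_descriptors()]).
#' @param compound_id,solvent,method Labels carried into the summary;
#'   `solvent` is free text plus a `polarity` class (`"POLAR"` /
#'   `"NONPOLAR"`).
#' @param polarity Solvent polarity class.
#' @param rgyr_threshold,psa_threshold Folded/low-polarity guide
#'   thresholds (defaults 7 Angstrom and 200 square Angstrom). These are
#'   visual-comparison aids, not validated cutoffs.
#' @return Object of class `"ensemble_summary"` (a list).
#' @export
summarize_ensemble <- function(frames, compound_id = NA_character_,
                               solvent = NA_character_,
                               polarity = c("POLAR", "NONPOLAR"),
                               method = c("CS", "SMD"),
                               rgyr_threshold = 7, psa_threshold = 200) {
  stopifnot(is.data.frame(frames),
            all(c("r_gyr", "psa_14") %in% names(frames)))
  if (nrow(frames) == 0L) stop("empty ensemble", call. = FALSE)
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  iqr <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75))))
  structure(
    list(compound_id = compound_id, solvent = solvent, polarity = polarity,
         method = method, n_frames = nrow(frames),
         median_rgyr = stats::median(frames$r_gyr),
         median_psa14 = stats::median(frames$psa_14),
         iqr_rgyr = iqr(frames$r_gyr), iqr_psa14 = iqr(frames$psa_14),
         fraction_folded_lowpolar =
           mean(frames$r_gyr < rgyr_threshold & frames$psa_14 < psa_threshold)),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Ensemble %s / %s (%s, %s): %d frames\n  median R_gyr %.2f A (IQR %.2f), median 3D PSA 1.4 %.1f A^2 (IQR %.1f)\n  folded/low-polarity fraction %.2f\n",
    x$compound_id, x$solvent, x$polarity, x$method, x$n_frames,
    x$median_rgyr, x$iqr_rgyr, x$median_psa14, x$iqr_psa14,
    x$fraction_folded_lowpolar))
  invisible(x)
}

#' 2D conformer density map
#'
#' Histogram of the ensemble on the (R_gyr, 3D PSA 1.4) plane. A plain
#' histogram (rather than a kernel estimate) conserves frame counts
#' exactly and makes the density maximum deterministic. Ties for the
#' maximum bin are broken toward lower PSA, then lower R_gyr.
#'
#' @param frames Per-frame descriptor data frame (`r_gyr`, `psa_14`).
#' @param x_bin_width R_gyr bin width, Angstrom (default 0.25).
#' @param y_bin_width PSA bin width, square Angstrom (default 5).
#' @return Object of class `"density_map"`: `x_edges`, `y_edges`, `counts`
#'   (length(x_edges)-1 by length(y_edges)-1), `max_bin` (i, j), plus the
#'   per-frame bin assignment.
#' @export
density_map <- function(frames, x_bin_width = 0.25, y_bin_width = 5) {
  stopifnot(is.data.frame(frames),
            all(c("r_gyr", "psa_14") %in% names(frames)))
  if (nrow(frames) == 0L) stop("empty ensemble", call. = FALSE)
  if (x_bin_width <= 0 || y_bin_width <= 0) {
    stop("invalid binning: bin widths must be positive", call. = FALSE)
  }
  edges <- function(v, w) {
    lo <- floor(min(v) / w) * w
    hi <- ceiling(max(v) / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  }
  xe <- edges(frames$r_gyr, x_bin_width)
  ye <- edges(frames$psa_14, y_bin_width)
  ix <- pmin(findInterval(frames$r_gyr, xe, rightmost.closed = TRUE),
             length(xe) - 1L)
  iy <- pmin(findInterval(frames$psa_14, ye, rightmost.closed = TRUE),
             length(ye) - 1L)
  counts <- matrix(0L, length(xe) - 1L, length(ye) - 1L)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  mx <- max(counts)
  cand <- which(counts == mx, arr.ind = TRUE)
  # tie-break: lower psa bin (j), then lower r_gyr bin (i)
  cand <- cand[order(cand[, 2L], cand[, 1L]), , drop = FALSE]
  structure(
    list(x_edges = xe, y_edges = ye, counts = counts,
         max_bin = c(i = unname(cand[1L, 1L]), j = unname(cand[1L, 2L])),
         bin_x = ix, bin_y = iy),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "Density map: %d x %d bins, %d frames, max bin (%d, %d) with %d frames\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts),
    x$max_bin["i"], x$max_bin["j"], max(x$counts)))
  invisible(x)
}

#' Representative conformer of the density maximum
#'
#' Among the frames falling in the most populated bin of the density map,
#' returns the one closest to the bin center in standardized (z-scored)
#' coordinates; ties go to the lowest frame id. This is the single
#' conformer used to depict an ensemble's dominant state.
#'
#' @param frames The per-frame descriptor data frame the map was built
#'   from (`frame_id`, `r_gyr`, `psa_14`).
#' @param map The [density_map()] of those frames.
#' @return The selected `frame_id`.
#' @export
density_max_conformer <- function(frames, map) {
  stopifnot(inherits(map, "density_map"),
            nrow(frames) == length(map$bin_x))
  inbin <- which(map$bin_x == map$max_bin["i"] & map$bin_y == map$max_bin["j"])
  cx <- (map$x_edges[map$max_bin["i"]] + map$x_edges[map$max_bin["i"] + 1L]) / 2
  cy <- (map$y_edges[map$max_bin["j"]] + map$y_edges[map$max_bin["j"] + 1L]) / 2
  sx <- stats::sd(frames$r_gyr)
  sy <- stats::sd(frames$psa_14)
  if (!is.finite(sx) || sx == 0) sx <- 1
  if (!is.finite(sy) || sy == 0) sy <- 1
  d2 <- ((frames$r_gyr[inbin] - cx) / sx)^2 + ((frames$psa_14[inbin] - cy) / sy)^2
  cand <- inbin[d2 == min(d2)]
  min(frames$frame_id[cand])
}

#' Polar-vs-nonpolar ensemble contrast
#'
#' The chameleonic signature in property space: how the ensemble medians
#' shift between a polar solvent (water) and a nonpolar one (chloroform /
#' toluene). Returns polar-minus-nonpolar deltas; a chameleon typically
#' shows positive delta PSA (more exposed polarity in water) and, for
#' water-folding compounds, negative delta R_gyr.
#'
#' @param polar,nonpolar `"ensemble_summary"` objects for the same
#'   compound.
#' @return Named numeric: `delta_median_rgyr`, `delta_median_psa14`.
#' @export
chameleon_contrast <- function(polar, nonpolar) {
  stopifnot(inherits(polar, "ensemble_summary"),
            inherits(nonpolar, "ensemble_summary"))
  if (!identical(polar$compound_id, nonpolar$compound_id)) {
    stop("label mismatch: summaries are for different compounds", call. = FALSE)
  }
  c(delta_median_rgyr = polar$median_rgyr - nonpolar$median_rgyr,
    delta_median_psa14 = polar$median_psa14 - nonpolar$median_psa14)
}

#' Summarize many (compound, solvent) ensembles from a long table
#'
#' @param descriptors Data frame with columns `compound_id`, `solvent`,
#'   `polarity`, `method`, `frame_id`, `r_gyr`, `psa_14`.
#' @param ... Passed to [summarize_ensemble()].
#' @return Data frame, one row per (compound, solvent).
#' @export
summarize_ensembles <- function(descriptors, ...) {
  req <- c("compound_id", "solvent", "polarity", "method", "r_gyr", "psa_14")
  stopifnot(is.data.frame(descriptors), all(req %in% names(descriptors)))
  keys <- unique(descriptors[c("compound_id", "solvent")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    d <- descriptors[descriptors$compound_id == keys$compound_id[k] &
                       descriptors$solvent == keys$solvent[k], , drop = FALSE]
    s <- summarize_ensemble(d, compound_id = keys$compound_id[k],
                            solvent = keys$solvent[k],
                            polarity = d$polarity[1L], method = d$method[1L],
                            ...)
    data.frame(compound_id = s$compound_id, solvent = s$solvent,
               polarity = s$polarity, method = s$method,
               n_frames = s$n_frames, median_rgyr = s$median_rgyr,
               median_psa14 = s$median_psa14, iqr_rgyr = s$iqr_rgyr,
               iqr_psa14 = s$iqr_psa14,
               fraction_folded_lowpolar = s$fraction_folded_lowpolar,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
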