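#' Per-compound experimental reference table (transcription required)
#'
#' The published per-compound experimental table (F\%, efflux ratio,
#' permeability, EPSA, TPSA and the chromatographic descriptor columns for
#' the 11 degraders the pipeline was built around) is distributed only
#' inside the source publication, not as a machine-readable dataset. The
#' packaged file `extdata/experimental_compounds_transcription_required.csv` therefore
#' ships as a header-only template: users with access to the publication
#' transcribe the printed values into it (or supply their own table of
#' the same shape) to reproduce the published correlations. Until then
#' this accessor fails with an informative error.
#'
#' For a synthetic table with the same statistical structure, see
#' [gen_property_table()].
#'
#' @param path Optional path to a transcribed CSV of the same schema.
#' @return Data frame of compound records.
#' @export
transcribed_compound_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "experimental_compounds_transcription_required.csv",
                        package = "chromaleon")
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    stop("the experimental compound table has not been transcribed: the ",
         "packaged file is a header-only template. Transcribe the printed ",
         "per-compound values from the source publication into ", path,
         " (columns: ", paste(names(d), collapse = ", "), ").",
         call. = FALSE)
  }
  d
}
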