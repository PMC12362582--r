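#' Read a conformer ensemble from a multi-model PDB or multi-frame XYZ file
#'
#' PDB files are parsed with \pkg{bio3d} (`MODEL`/`ENDMDL` delimited;
#' element symbols from the element column, falling back to the atom-name
#' convention); `CONECT` records, which \pkg{bio3d} does not expose, are
#' read directly and become the bond list of every frame. XYZ files are
#' the plain multi-frame dialect: an atom count line, a comment line, then
#' `element x y z` rows, repeated per frame (no bonds; hydrogen bonding is
#' inferred by distance downstream when needed).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @return List of [conformer()] objects, in file order.
#' @export
read_conformers <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", ent = "pdb", xyz = "xyz",
                     stop("cannot infer format from extension: ", path,
                          call. = FALSE))
  }
  if (format == "pdb") read_conformers_pdb(path) else read_conformers_xyz(path)
}

read_conformers_pdb <- function(path) {
  lines <- readLines(path)
  n_model <- sum(startsWith(lines, "MODEL"))
  n_end <- sum(startsWith(lines, "ENDMDL"))
  if (n_model != n_end) {
    stop("parse error in ", path, ": ", n_model, " MODEL but ", n_end,
         " ENDMDL records (truncated model block)", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elements <- trimws(pdb$atom$elesy)
  # element fallback from the atom-name column, PDB convention
  blank <- is.na(elements) | elements == ""
  if (any(blank)) {
    nm <- trimws(pdb$atom$elety[blank])
    elements[blank] <- sub("[0-9'].*$", "", nm)
  }
  elements <- paste0(toupper(substr(elements, 1L, 1L)),
                     tolower(substring(elements, 2L, 2L)))
  nframes <- nrow(pdb$xyz)
  if (is.null(nframes) || nframes == 0L) stop("empty file: no frames in ", path,
                                              call. = FALSE)
  # CONECT records: columns are fixed-width but commonly space separated
  con <- lines[startsWith(lines, "CONECT")]
  bonds <- NULL
  if (length(con)) {
    pairs <- lapply(con, function(l) {
      ids <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", l)),
                                                  "\\s+")[[1]]))
      ids <- ids[!is.na(ids)]
      if (length(ids) < 2L) return(NULL)
      cbind(ids[1L], ids[-1L])
    })
    bonds <- do.call(rbind, pairs)
    if (!is.null(bonds)) {
      bonds <- unique(t(apply(bonds, 1L, sort)))
    }
  }
  lapply(seq_len(nframes), function(f) {
    conformer(elements, matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE),
              bonds = bonds, frame_id = f)
  })
}

read_conformers_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") {
      i <- i + 1L
      next
    }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop("parse error in ", path, " line ", i, ": expected atom count",
           call. = FALSE)
    }
    if (i + 1L + nat > length(lines)) {
      stop("parse error in ", path, " line ", i, ": truncated frame",
           call. = FALSE)
    }
    block <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4L)
    if (length(bad)) {
      stop("parse error in ", path, " line ", i + 1L + bad[1L],
           ": expected 'element x y z'", call. = FALSE)
    }
    elements <- vapply(parts, `[`, character(1), 1L)
    xyz <- t(vapply(parts,
                    function(p) suppressWarnings(as.numeric(p[2:4])),
                    numeric(3)))
    if (any(!is.finite(xyz))) {
      stop("parse error in ", path, ": non-numeric coordinate in frame ",
           length(frames) + 1L, call. = FALSE)
    }
    frames[[length(frames) + 1L]] <- conformer(elements, xyz,
                                               frame_id = length(frames) + 1L)
    i <- i + 2L + nat
  }
  if (!length(frames)) stop("empty file: no frames in ", path, call. = FALSE)
  frames
}

#' Write conformers as a multi-frame XYZ file
#'
#' @param frames List of [conformer()] objects.
#' @param path Output path.
#' @param comment Comment line per frame (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, comment = "") {
  stopifnot(is.list(frames), length(frames) >= 1L)
  comment <- rep_len(comment, length(frames))
  out <- unlist(lapply(seq_along(frames), function(f) {
    cf <- frames[[f]]
    c(as.character(length(cf$elements)), comment[f],
      sprintf("%-2s %12.6f %12.6f %12.6f", cf$elements,
              cf$xyz[, 1L], cf$xyz[, 2L], cf$xyz[, 3L]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Write conformers as a multi-model PDB file
#'
#' HETATM records with the element column set; bonds of the first frame
#' are emitted as CONECT records after the last model.
#'
#' @inheritParams write_xyz
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frames, path) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  out <- unlist(lapply(seq_along(frames), function(f) {
    cf <- frames[[f]]
    n <- length(cf$elements)
    c(sprintf("MODEL     %4d", f),
      sprintf("HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
              seq_len(n),
              paste0(cf$elements, seq_len(n) %% 100),
              cf$xyz[, 1L], cf$xyz[, 2L], cf$xyz[, 3L],
              toupper(cf$elements)),
      "ENDMDL")
  }))
  bonds <- frames[[1L]]$bonds
  if (!is.null(bonds)) {
    out <- c(out, sprintf("CONECT%5d%5d", bonds[, 1L], bonds[, 2L]))
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Run the descriptor/PK/ensemble/relations pipeline
#'
#' Orchestrates the stages on in-memory inputs and writes one CSV per
#' stage plus a JSON run manifest (row counts, configuration echo,
#' package version). Stages run only when their inputs are supplied;
#' requesting a stage whose dependency is absent fails before anything is
#' written.
#'
#' @param inputs List with any of: `retention` (+ optional `meta`), `pk`,
#'   `conformer_descriptors` (long per-frame table with labels, see
#'   [summarize_ensembles()]), `compounds` plus `relations` (list of
#'   `list(x, y, exclude)` specs).
#' @param out_dir Output directory (created if needed).
#' @param calibration See [chromatographic_calibration()].
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Named list of the result data frames, invisibly; files are the
#'   primary product.
#' @export
run_pipeline <- function(inputs, out_dir, calibration = chromatographic_calibration(),
                         seed = NULL) {
  stopifnot(is.list(inputs))
  if (!is.null(inputs$relations) && is.null(inputs$compounds)) {
    stop("dependency error: relations requested but no compound table supplied",
         call. = FALSE)
  }
  if (!is.null(inputs$compounds) && nrow(inputs$compounds) == 0L) {
    stop("dependency error: empty compound table", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  emit <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
    results[[name]] <<- df
  }

  if (!is.null(inputs$retention)) {
    emit(compute_descriptors(inputs$retention, inputs$meta, calibration),
         "descriptors")
  }
  if (!is.null(inputs$pk)) {
    emit(compute_bioavailability(inputs$pk), "bioavailability")
  }
  if (!is.null(inputs$conformer_descriptors)) {
    emit(summarize_ensembles(inputs$conformer_descriptors), "ensemble_summary")
  }
  if (!is.null(inputs$compounds)) {
    specs <- inputs$relations %||% list()
    rel <- lapply(specs, function(s) {
      r <- linear_relation(inputs$compounds, s$x, s$y,
                           exclude = s$exclude %||% character())
      data.frame(x = r$x_name, y = r$y_name, slope = r$slope,
                 intercept = r$intercept, r2 = r$r2, n_used = r$n_used,
                 excluded = paste(r$excluded_ids, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    if (length(rel)) emit(do.call(rbind, rel), "relations")
    if (all(c("brlogd", "delta_logkw_iam", "f_percent") %in%
            names(inputs$compounds))) {
      emit(polarity_lipophilicity_plane(inputs$compounds), "plane")
    }
  }

  manifest <- list(
    package = "chromaleon",
    version = as.character(utils::packageVersion("chromaleon")),
    seed = seed,
    calibration = calibration,
    outputs = lapply(results, nrow)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
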