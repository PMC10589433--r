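#' Read a NIfTI image
#'
#' @param path Path to a NIfTI-1/2 file (optionally gzipped).
#' @return An `RNifti` `niftiImage` (array with header attributes;
#'   spacing via [nifti_spacing()]).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  tryCatch(RNifti::readNifti(path),
           error = function(e) {
             stop(errorCondition(paste0("malformed NIfTI file: ", path, " (",
                                        conditionMessage(e), ")"),
                                 class = c("cvrsvd_format_error", "error")))
           })
}

#' Write an array as NIfTI
#'
#' @param volume Numeric/logical array (3D or 4D); logical masks are
#'   written as 0/1 integers.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing_mm Voxel spacing, mm (length 3). Ignored if `volume` is
#'   already a `niftiImage` (its header, including orientation, is
#'   preserved).
#' @param tr_s For 4D volumes, repetition time stored in the time
#'   dimension's pixdim.
#' @return The path, invisibly.
#' @export
write_nifti <- function(volume, path, spacing_mm = NULL, tr_s = NULL) {
  if (inherits(volume, "niftiImage")) {
    img <- volume
  } else {
    if (is.logical(volume)) {
      volume <- array(as.integer(volume), dim = dim(volume))
    }
    img <- RNifti::asNifti(volume)
    if (!is.null(spacing_mm) || !is.null(tr_s)) {
      pd <- RNifti::pixdim(img)
      if (!is.null(spacing_mm)) pd[1:3] <- spacing_mm
      if (!is.null(tr_s) && length(pd) >= 4L) pd[4] <- tr_s
      RNifti::pixdim(img) <- pd
    }
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Voxel spacing of a NIfTI image
#'
#' @param img A `niftiImage`.
#' @return Numeric length-3, mm.
#' @export
nifti_spacing <- function(img) {
  abs(RNifti::pixdim(img)[1:3])
}

#' Read a 4D BOLD NIfTI with its repetition time
#'
#' @param path Path to a 4D NIfTI; `tr_s` is taken from the header's
#'   fourth pixdim unless overridden.
#' @param tr_s Optional TR override (e.g. from a sidecar), seconds.
#' @return List with `data` (4D array), `tr_s`, `spacing_mm`.
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- read_nifti(path)
  if (length(dim(img)) != 4L) {
    stop(errorCondition("expected a 4D BOLD image",
                        class = c("cvrsvd_format_error", "error")))
  }
  if (is.null(tr_s)) {
    tr_s <- RNifti::pixdim(img)[4]
    if (!is.finite(tr_s) || tr_s <= 0) {
      stop(errorCondition("TR missing from NIfTI header; pass `tr_s`",
                          class = c("cvrsvd_format_error", "error")))
    }
  }
  list(data = img[, , , , drop = FALSE], tr_s = tr_s,
       spacing_mm = nifti_spacing(img))
}

# sniff comma vs tab/space separator from the header line
.read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = TRUE)
}

#' Read a physiological CO2 recording
#'
#' Delimited text (comma or whitespace) with a header naming columns
#' `time_s` and `co2_mmHg`.
#'
#' @param path File path.
#' @param source Trace provenance; use `"measured"` for a raw waveform
#'   (to be passed through [detect_end_tidal_peaks()]) or
#'   `"end_tidal_extracted"` for a precomputed end-tidal trace.
#' @return An [etco2_trace()].
#' @export
read_physio <- function(path, source = "measured") {
  d <- .read_delim_auto(path)
  if (!all(c("time_s", "co2_mmHg") %in% names(d))) {
    stop(errorCondition("physio file must have columns time_s, co2_mmHg",
                        class = c("cvrsvd_format_error", "error")))
  }
  etco2_trace(d$time_s, d$co2_mmHg, source = source)
}

#' Write an EtCO2 trace as delimited text
#'
#' @param trace An [etco2_trace()].
#' @param path Output path (tab-delimited, columns `time_s`, `co2_mmHg`).
#' @return The path, invisibly.
#' @export
write_physio <- function(trace, path) {
  stopifnot(inherits(trace, "etco2_trace"))
  utils::write.table(
    data.frame(time_s = trace$times_s, co2_mmHg = trace$values_mmHg),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' CSV with the cohort column dictionary (see the package vignette);
#' `sex` and `smoking` are restored as factors with the reference levels
#' used by the regression stage.
#'
#' @param path File path.
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("female", "male"))
  if ("smoking" %in% names(d)) {
    d$smoking <- factor(d$smoking,
                        levels = c("never", "ex_gt1y", "current_recent"))
  }
  d
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write a provenance manifest as JSON
#'
#' @param manifest A list (parameters, seeds, versions, per-subject
#'   inclusion records).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
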