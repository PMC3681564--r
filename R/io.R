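#' Spectrum and ensemble JSON containers
#'
#' The package's on-disk spectrum container is a plain-text JSON document:
#' the intensity matrix (column-major values plus dimensions) together with
#' every axis calibration field and the sample metadata. An ensemble file
#' holds a list of such spectra. The layout is self-describing and
#' readable by any JSON library; adapters for vendor-processed formats
#' (Bruker processed directories, NMRPipe planes) can populate the same
#' in-memory structures via [spectrum_grid()].
#'
#' @param spectrum a [spectrum_grid()].
#' @param path file path.
#' @return invisible path (writers); a [spectrum_grid()] /
#'   [nmr_ensemble()] (readers).
#' @export
write_spectrum_json <- function(spectrum, path) {
  jsonlite::write_json(spectrum_to_list(spectrum), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

spectrum_to_list <- function(spectrum) {
  ax <- function(a) a[c("n_time", "dwell", "sfrq", "sw", "ref_ppm",
                        "n_freq", "label")]
  list(container = "fmlr2d-spectrum", version = 1L,
       sample_id = spectrum$sample_id, group_label = spectrum$group_label,
       axis_C = ax(spectrum$axis_C), axis_H = ax(spectrum$axis_H),
       dim = dim(spectrum$intensities),
       intensities = as.numeric(spectrum$intensities))
}

list_to_spectrum <- function(x) {
  ax <- function(a) axis_spec(a$n_time, sfrq = a$sfrq, sw = a$sw,
                              ref_ppm = a$ref_ppm, n_freq = a$n_freq,
                              label = a$label)
  spectrum_grid(matrix(unlist(x$intensities), x$dim[[1]], x$dim[[2]]),
                ax(x$axis_C), ax(x$axis_H),
                sample_id = x$sample_id %||% "",
                group_label = x$group_label %||% "")
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$container, "fmlr2d-spectrum"))
    stop("not an fmlr2d spectrum container: ", path)
  list_to_spectrum(x)
}

#' @rdname write_spectrum_json
#' @param ensemble an [nmr_ensemble()].
#' @export
write_ensemble_json <- function(ensemble, path) {
  jsonlite::write_json(list(container = "fmlr2d-ensemble", version = 1L,
                            spectra = lapply(ensemble, spectrum_to_list)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_ensemble_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$container, "fmlr2d-ensemble"))
    stop("not an fmlr2d ensemble container: ", path)
  nmr_ensemble(lapply(x$spectra, list_to_spectrum))
}

#' Write / read the fitted signal table as CSV
#'
#' Columns: `sample_id`, `spectrum_index`, `signal_id`, `amplitude`,
#' `ppm_H`, `ppm_C`, `fwhm_H_Hz`, `fwhm_C_Hz`, `roi_id` (empty when
#' unassigned), `iteration_added`.
#'
#' @param signals a [signal_table()] (with `sample_id` column, as returned
#'   by [deconvolve_ensemble()]).
#' @param path CSV path.
#' @return invisible path / a [signal_table()].
#' @export
write_signal_table <- function(signals, path) {
  df <- as.data.frame(signals)
  if (!"sample_id" %in% names(df)) df$sample_id <- ""
  out <- data.frame(sample_id = df$sample_id,
                    spectrum_index = df$spectrum_index,
                    signal_id = df$signal_id, amplitude = df$amplitude,
                    ppm_H = df$ppm_H, ppm_C = df$ppm_C,
                    fwhm_H_Hz = df$fwhm_H, fwhm_C_Hz = df$fwhm_C,
                    roi_id = ifelse(is.na(df$roi_id), "", df$roi_id),
                    iteration_added = df$iteration_added)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_signal_table
#' @export
read_signal_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       signal_id = "character",
                                       roi_id = "character"))
  sig <- signal_table(amplitude = df$amplitude, ppm_H = df$ppm_H,
                      ppm_C = df$ppm_C, fwhm_H = df$fwhm_H_Hz,
                      fwhm_C = df$fwhm_C_Hz,
                      spectrum_index = df$spectrum_index,
                      roi_id = ifelse(df$roi_id == "", NA_character_, df$roi_id),
                      signal_id = df$signal_id,
                      iteration_added = df$iteration_added)
  sig$sample_id <- df$sample_id
  sig
}
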