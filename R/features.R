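#' ROI x spectrum feature matrices
#'
#' The profiling feature set: one row per ROI, one column per spectrum.
#' Entries are either summed fitted signal amplitudes
#' ([build_feature_matrix()]) or direct grid integrals
#' ([integrate_rois()]); the `normalization` field tracks whether the values
#' are raw, lignin-normalized, or internal-standard normalized.
#'
#' @param values numeric ROI x spectrum matrix.
#' @param rois the [roi_table()] the rows refer to.
#' @param sample_ids,group_labels per-column metadata.
#' @param normalization one of `"raw"`, `"lignin_normalized"`,
#'   `"internal_standard"`.
#' @param unassigned list with `n` and `amplitude` of signals left out of
#'   the matrix.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, rois, sample_ids,
                           group_labels = rep("", length(sample_ids)),
                           normalization = "raw",
                           unassigned = list(n = 0L, amplitude = 0)) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("values must be an all-finite matrix")
  if (nrow(values) != nrow(rois)) stop("one row per ROI required")
  if (ncol(values) != length(sample_ids)) stop("one column per sample required")
  if (normalization == "raw" && any(values < 0))
    stop("raw feature values must be >= 0")
  dimnames(values) <- list(rois$roi_id, sample_ids)
  structure(list(values = values, roi_ids = rois$roi_id, labels = rois$label,
                 roles = rois$role, sample_ids = sample_ids,
                 group_labels = group_labels, normalization = normalization,
                 unassigned = unassigned),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d ROIs x %d spectra (%s)>\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' Feature matrix from fitted signal amplitudes
#'
#' Entry (r, s) is the simple sum of the amplitudes of all signals assigned
#' to ROI r in spectrum s. Signals with `roi_id = NA` are excluded and
#' reported in the `unassigned` field, so that matrix total plus unassigned
#' total equals the total fitted amplitude exactly.
#'
#' @param signals a [signal_table()] with `roi_id` filled (see
#'   [assign_signals()]).
#' @param rois a [roi_table()].
#' @param sample_ids per-spectrum ids (length = number of spectra).
#' @param group_labels per-spectrum group labels.
#' @return a raw [feature_matrix()].
#' @export
build_feature_matrix <- function(signals, rois, sample_ids,
                                 group_labels = rep("", length(sample_ids))) {
  n_s <- length(sample_ids)
  vals <- matrix(0, nrow(rois), n_s)
  keep <- !is.na(signals$roi_id)
  if (any(keep)) {
    r_idx <- match(signals$roi_id[keep], rois$roi_id)
    if (anyNA(r_idx)) stop("signal assigned to unknown roi_id")
    s_idx <- signals$spectrum_index[keep]
    if (any(s_idx < 1 | s_idx > n_s)) stop("spectrum_index outside 1..n_spectra")
    for (k in seq_along(r_idx))
      vals[r_idx[k], s_idx[k]] <- vals[r_idx[k], s_idx[k]] + signals$amplitude[keep][k]
  }
  feature_matrix(vals, rois, sample_ids, group_labels,
                 unassigned = list(n = sum(!keep),
                                   amplitude = sum(signals$amplitude[!keep])))
}

#' Feature matrix by direct ROI integration
#'
#' The model-free comparison method: entry (r, s) is the sum of spectrum
#' intensities over all grid points inside ROI r. Unlike the
#' deconvolution-based amplitudes, these integrals change whenever an ROI
#' boundary moves across signal intensity.
#'
#' @param ensemble an [nmr_ensemble()].
#' @param rois a [roi_table()].
#' @return a [feature_matrix()] with `normalization = "raw"`. Integration of
#'   noisy data can yield small negative sums; values are reported as-is via
#'   `normalization = "integration"`.
#' @export
integrate_rois <- function(ensemble, rois) {
  axC <- ensemble[[1]]$axis_C; axH <- ensemble[[1]]$axis_H
  rh <- ppm_range(axH); rc <- ppm_range(axC)
  outside <- rois$h_max_ppm < rh[1] | rois$h_min_ppm > rh[2] |
             rois$c_max_ppm < rc[1] | rois$c_min_ppm > rc[2]
  if (any(outside))
    stop("ROI(s) fully outside the spectral window: ",
         paste(rois$roi_id[outside], collapse = ", "))
  masks <- roi_masks(rois, axC, axH)
  vals <- vapply(ensemble,
                 function(sp) vapply(masks, function(m) sum(sp$intensities[m]),
                                     numeric(1)),
                 numeric(nrow(rois)))
  vals <- matrix(vals, nrow = nrow(rois))
  feature_matrix(vals, rois,
                 sample_ids = vapply(ensemble, `[[`, "", "sample_id"),
                 group_labels = vapply(ensemble, `[[`, "", "group_label"),
                 normalization = "integration")
}

#' Write / read a feature matrix CSV
#'
#' Spreadsheet-importable layout: header row `roi_id,label,<sample ids...>`,
#' a second metadata row carrying the group labels, then one row per ROI.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV path.
#' @return invisible path / a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  con <- file(path, "w"); on.exit(close(con))
  esc <- function(x) paste0('"', gsub('"', '""', x), '"')
  writeLines(paste(c("roi_id", "label", esc(fm$sample_ids)), collapse = ","), con)
  writeLines(paste(c("group", "", esc(fm$group_labels)), collapse = ","), con)
  for (i in seq_along(fm$roi_ids))
    writeLines(paste(c(esc(fm$roi_ids[i]), esc(fm$labels[i]),
                       sprintf("%.12g", fm$values[i, ])), collapse = ","), con)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param rois optional [roi_table()] to restore roles; defaults to role
#'   `"other"` for every row.
#' @export
read_feature_matrix <- function(path, rois = NULL) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(raw[1, -(1:2)])
  groups <- as.character(raw[2, -(1:2)])
  body <- raw[-(1:2), , drop = FALSE]
  vals <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  ids <- as.character(body[, 1])
  if (is.null(rois)) {
    rois <- roi_table(data.frame(roi_id = ids, label = as.character(body[, 2]),
                                 role = "other", h_min_ppm = 0, h_max_ppm = 1,
                                 c_min_ppm = 0, c_max_ppm = 1))
  } else {
    rois <- rois[match(ids, rois$roi_id), ]
  }
  feature_matrix(vals, rois, sample_ids, groups, normalization = "raw")
}
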