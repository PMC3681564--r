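#' Region-of-interest tables
#'
#' An ROI is a rectangular 1H x 13C ppm window associated with (optionally)
#' an assignment label and a lignin role. Roles drive the lignin-content
#' normalization: `"S"`, `"S'"`, `"G"`, `"G'"`, `"H"` mark the aromatic
#' transitions entering the weighted lignin sum; everything else is
#' `"other"` (assigned but not part of the sum) or `"unassigned"`.
#'
#' @param df data frame with columns `roi_id`, `label`, `role`,
#'   `h_min_ppm`, `h_max_ppm`, `c_min_ppm`, `c_max_ppm` and optionally
#'   `color`.
#' @return validated data frame of class `roi_table`.
#' @export
roi_table <- function(df) {
  need <- c("roi_id", "label", "role", "h_min_ppm", "h_max_ppm",
            "c_min_ppm", "c_max_ppm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ROI table lacks columns: ", paste(miss, collapse = ", "))
  if (!"color" %in% names(df)) df$color <- NA_character_
  df$color <- as.character(df$color)
  df <- df[, c(need, "color")]
  df$roi_id <- as.character(df$roi_id); df$label <- as.character(df$label)
  df$role <- as.character(df$role)
  roles <- c("S", "S'", "G", "G'", "H", "other", "unassigned")
  bad_role <- !df$role %in% roles
  if (any(bad_role))
    stop("invalid role for ROI(s): ",
         paste(df$roi_id[bad_role], collapse = ", "))
  dup <- df$roi_id[duplicated(df$roi_id)]
  if (length(dup)) stop("duplicated roi_id(s): ", paste(unique(dup), collapse = ", "))
  inv <- df$h_min_ppm >= df$h_max_ppm | df$c_min_ppm >= df$c_max_ppm
  if (any(inv))
    stop("inverted or empty ppm bounds for ROI(s): ",
         paste(df$roi_id[inv], collapse = ", "))
  class(df) <- c("roi_table", "data.frame")
  df
}

#' Read / write an ROI table as CSV
#'
#' The CSV carries the header `roi_id,label,role,h_min_ppm,h_max_ppm,
#' c_min_ppm,c_max_ppm,color`; bounds are written with 4 decimal places.
#' A constant ppm offset per axis can be applied on load, the usual
#' adjustment when a table drawn on one study is reused on another.
#'
#' @param path CSV file path.
#' @param h_offset,c_offset constant ppm shifts added to the 1H / 13C bounds
#'   on load.
#' @return [roi_table()] (for `load_roi_table`); invisible path (for
#'   `save_roi_table`).
#' @export
load_roi_table <- function(path, h_offset = 0, c_offset = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(roi_id = "character", label = "character",
                                       role = "character"))
  df$h_min_ppm <- df$h_min_ppm + h_offset
  df$h_max_ppm <- df$h_max_ppm + h_offset
  df$c_min_ppm <- df$c_min_ppm + c_offset
  df$c_max_ppm <- df$c_max_ppm + c_offset
  roi_table(df)
}

#' @rdname load_roi_table
#' @param rois a [roi_table()].
#' @export
save_roi_table <- function(rois, path) {
  out <- as.data.frame(rois)
  for (cc in c("h_min_ppm", "h_max_ppm", "c_min_ppm", "c_max_ppm"))
    out[[cc]] <- sprintf("%.4f", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' ROIs containing a peak centre
#'
#' Containment uses closed intervals: a centre lying exactly on an ROI edge
#' belongs to that ROI. Returned in table order.
#'
#' @param ppm_H,ppm_C peak centre, ppm.
#' @param rois a [roi_table()].
#' @return character vector of roi_ids (possibly empty).
#' @export
containing_rois <- function(ppm_H, ppm_C, rois) {
  hit <- ppm_H >= rois$h_min_ppm & ppm_H <= rois$h_max_ppm &
         ppm_C >= rois$c_min_ppm & ppm_C <= rois$c_max_ppm
  rois$roi_id[hit]
}

# logical mask of grid points inside one ROI (closed intervals)
roi_mask_one <- function(roi, axis_C, axis_H) {
  pc <- ppm_axis(axis_C); ph <- ppm_axis(axis_H)
  outer(pc >= roi$c_min_ppm & pc <= roi$c_max_ppm,
        ph >= roi$h_min_ppm & ph <= roi$h_max_ppm, FUN = "&")
}

roi_masks <- function(rois, axis_C, axis_H) {
  ms <- lapply(seq_len(nrow(rois)), function(i) roi_mask_one(rois[i, ], axis_C, axis_H))
  names(ms) <- rois$roi_id
  ms
}

roi_union_mask <- function(rois, axis_C, axis_H) {
  m <- matrix(FALSE, axis_C$n_freq, axis_H$n_freq)
  for (msk in roi_masks(rois, axis_C, axis_H)) m <- m | msk
  m
}

#' Per-axis distance normalization for the gravity metric
#'
#' ppm distances entering the gravity metric are divided per axis by the
#' median ROI width on that axis, so the narrow 1H and wide 13C dispersions
#' contribute comparably.
#'
#' @param rois a [roi_table()].
#' @return named vector `c(h = , c = )` of ppm scales.
#' @export
gravity_scale <- function(rois) {
  c(h = stats::median(rois$h_max_ppm - rois$h_min_ppm),
    c = stats::median(rois$c_max_ppm - rois$c_min_ppm))
}

#' Gravity-metric ROI disambiguation
#'
#' When a source peak centre falls inside two or more overlapping ROIs, it
#' is assigned to the candidate with the greatest gravity metric: the sum
#' over that ROI's already-assigned peers of (source amplitude x peer
#' amplitude) / (scaled Euclidean ppm distance between source and peer).
#' Ties break to the first candidate in table order. If no candidate has any
#' peers the source falls back to the nearest ROI centre (scaled distance),
#' with a warning.
#'
#' @param source one-row data frame (or list) with `amplitude`, `ppm_H`,
#'   `ppm_C`.
#' @param candidate_ids roi_ids of the overlapping candidates (>= 2), in
#'   table order.
#' @param peers data frame of already uniquely assigned signals with
#'   `amplitude`, `ppm_H`, `ppm_C`, `roi_id`.
#' @param rois a [roi_table()].
#' @param scale per-axis ppm normalization, see [gravity_scale()].
#' @return the winning roi_id.
#' @export
gravity_assign <- function(source, candidate_ids, peers, rois,
                           scale = gravity_scale(rois)) {
  if (length(candidate_ids) < 2) stop("gravity_assign needs >= 2 candidates")
  g <- vapply(candidate_ids, function(id) {
    p <- peers[!is.na(peers$roi_id) & peers$roi_id == id, , drop = FALSE]
    if (!nrow(p)) return(NA_real_)
    d <- sqrt(((source$ppm_H - p$ppm_H) / scale[["h"]])^2 +
              ((source$ppm_C - p$ppm_C) / scale[["c"]])^2)
    sum(source$amplitude * p$amplitude / d)
  }, numeric(1))
  if (all(is.na(g))) {
    warning("no peers in any candidate ROI; falling back to nearest ROI centre")
    cand <- rois[match(candidate_ids, rois$roi_id), ]
    d <- sqrt(((source$ppm_H - (cand$h_min_ppm + cand$h_max_ppm) / 2) / scale[["h"]])^2 +
              ((source$ppm_C - (cand$c_min_ppm + cand$c_max_ppm) / 2) / scale[["c"]])^2)
    return(candidate_ids[which.min(d)])
  }
  candidate_ids[which.max(g)]   # which.max: first maximum = table-order tie-break
}

#' Assign fitted signals to ROIs
#'
#' Two-pass scheme: signals whose centre lies inside exactly one ROI are
#' assigned by containment; signals inside overlapping ROIs are then
#' resolved with the gravity metric using the uniquely assigned signals of
#' the same spectrum as peers. Signals outside every ROI keep `roi_id = NA`.
#'
#' @param signals a [signal_table()].
#' @param rois a [roi_table()].
#' @param scale see [gravity_scale()].
#' @return the signal table with `roi_id` filled in.
#' @export
assign_signals <- function(signals, rois, scale = gravity_scale(rois)) {
  if (!nrow(signals)) return(signals)
  cands <- lapply(seq_len(nrow(signals)),
                  function(i) containing_rois(signals$ppm_H[i], signals$ppm_C[i], rois))
  n_cand <- lengths(cands)
  signals$roi_id <- NA_character_
  signals$roi_id[n_cand == 1] <- unlist(cands[n_cand == 1])
  for (i in which(n_cand > 1)) {
    peers <- signals[signals$spectrum_index == signals$spectrum_index[i] &
                     !is.na(signals$roi_id), , drop = FALSE]
    signals$roi_id[i] <- gravity_assign(signals[i, ], cands[[i]], peers, rois, scale)
  }
  signals
}
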