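# Independent oracles used across the suite.

# Brute-force O(N^2) DFT of a (zero-filled) FID, reported in the same
# descending-frequency order as apply_processing: ordered bin j (0-based)
# carries DFT index (N/2 - j) mod N.
naive_dft_desc <- function(x, zf) {
  x <- c(x, rep(0 + 0i, zf - length(x)))
  k <- 0:(zf - 1)
  vapply(0:(zf - 1), function(j) {
    m <- (zf / 2 - j) %% zf
    sum(x * exp(-2i * pi * m * k / zf))
  }, complex(1))
}

# Direct recomputation of the gravity metric for one candidate ROI.
brute_gravity <- function(source, roi_id, peers, scale) {
  p <- peers[!is.na(peers$roi_id) & peers$roi_id == roi_id, , drop = FALSE]
  if (!nrow(p)) return(NA_real_)
  d <- sqrt(((source$ppm_H - p$ppm_H) / scale[["h"]])^2 +
            ((source$ppm_C - p$ppm_C) / scale[["c"]])^2)
  sum(source$amplitude * p$amplitude / d)
}

# Small shared fixtures -----------------------------------------------------

tiny_axes <- function(n = 64L) default_axes(n, n)

# single-row ROI table helper
one_roi <- function(id, h1, h2, c1, c2, role = "other", label = "") {
  roi_table(data.frame(roi_id = id, label = label, role = role,
                       h_min_ppm = h1, h_max_ppm = h2,
                       c_min_ppm = c1, c_max_ppm = c2,
                       stringsAsFactors = FALSE))
}

rbind_rois <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  roi_table(df)
}

# feature matrix from a bare value matrix (unit-square ROI geometry)
fm_from_values <- function(vals, roles = rep("other", nrow(vals)),
                           groups = rep("", ncol(vals)),
                           ids = paste0("r", seq_len(nrow(vals)))) {
  rois <- roi_table(data.frame(roi_id = ids, label = ids, role = roles,
                               h_min_ppm = seq_len(nrow(vals)),
                               h_max_ppm = seq_len(nrow(vals)) + 0.5,
                               c_min_ppm = 1, c_max_ppm = 2,
                               stringsAsFactors = FALSE))
  feature_matrix(vals, rois, paste0("s", seq_len(ncol(vals))), groups,
                 normalization = "internal_standard")
}

# noise-free two-spectrum ensemble with three isolated signals each
tiny_truth_ensemble <- function(axes = default_axes(), amp = c(40, 25, 30)) {
  ops <- default_ops(axes)
  mk <- function(s) signal_table(amplitude = amp,
                                 ppm_H = c(6.7, 6.98, 7.2),
                                 ppm_C = c(104, 111, 128),
                                 fwhm_H = c(70, 90, 110),
                                 fwhm_C = c(80, 100, 60),
                                 spectrum_index = s)
  ens <- nmr_ensemble(lapply(1:2, function(s)
    spectrum_grid(synthesize_spectrum(mk(s), axes, ops),
                  axes$C, axes$H, paste0("s", s), "g")))
  list(ensemble = ens, signals = list(mk(1), mk(2)), ops = ops, axes = axes)
}

sgh_only_rois <- function() {
  rois <- bundled_roi_template()
  sub <- rois[rois$role %in% c("S", "S'", "G", "G'", "H"), ]
  class(sub) <- c("roi_table", "data.frame")
  sub
}
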