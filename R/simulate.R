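#' Bundled ROI template
#'
#' A 13-box template covering a lignin-aromatic-like spectral window
#' (1H 6.0-8.2 ppm, 13C 98.5-135.5 ppm). It contains one ROI for each of
#' the five lignin roles entering the lignin-content sum (S2/6, S'2/6, G2,
#' G'2, H2/6), assigned "other" boxes (G5/6-like, a side-chain-like region),
#' unassigned boxes, and one deliberately overlapping pair (OVA/OVB) that
#' exercises the gravity-metric disambiguation. The ppm coordinates are
#' synthetic fixture values chosen to be plausible for this spectral window;
#' they are not measured assignments.
#'
#' @return a [roi_table()].
#' @export
bundled_roi_template <- function() {
  roi_table(data.frame(
    roi_id = c("S26", "Sp26", "G2", "Gp2", "H26", "G56", "LBa",
               "R55", "R66", "OVA", "OVB", "X01", "X02"),
    label = c("S2/6", "S'2/6", "G2", "G'2", "H2/6", "G5/6", "LBa",
              "", "", "", "", "", ""),
    role = c("S", "S'", "G", "G'", "H", "other", "other",
             "unassigned", "unassigned", "unassigned", "unassigned",
             "other", "other"),
    h_min_ppm = c(6.45, 7.15, 6.75, 7.30, 7.05, 6.60, 6.90,
                  6.05, 7.55, 7.50, 7.70, 6.05, 7.60),
    h_max_ppm = c(6.95, 7.50, 7.20, 7.65, 7.42, 7.02, 7.30,
                  6.45, 7.95, 7.86, 8.06, 6.50, 8.00),
    c_min_ppm = c(102.0, 105.0, 108.8, 110.4, 126.0, 114.2, 120.6,
                  108.0, 124.0, 130.2, 131.4, 130.0, 100.0),
    c_max_ppm = c(106.0, 108.0, 113.2, 114.6, 130.0, 119.8, 124.4,
                  112.0, 128.0, 133.2, 134.4, 134.0, 104.5),
    color = NA_character_,
    stringsAsFactors = FALSE))
}

#' Default axis calibration for synthetic HSQC ensembles
#'
#' A 700 MHz 1H (176 MHz 13C) instrument with a spectral window matching
#' the bundled ROI template. Grid sizes are configurable; the defaults
#' (128 complex points zero-filled to 256 per dimension) keep synthetic
#' benchmarks fast while resolving 40-160 Hz linewidths.
#'
#' @param n_time_H,n_time_C acquired complex points per dimension.
#' @param n_freq_H,n_freq_C zero-filled grid lengths.
#' @return list with [axis_spec()] elements `H` and `C`.
#' @export
default_axes <- function(n_time_H = 128L, n_time_C = 128L,
                         n_freq_H = next_pow2(2L * n_time_H),
                         n_freq_C = next_pow2(2L * n_time_C)) {
  list(H = axis_spec(n_time_H, sfrq = 700.13, sw = 2.2 * 700.13,
                     ref_ppm = 8.2, n_freq = n_freq_H, label = "H1"),
       C = axis_spec(n_time_C, sfrq = 176.05, sw = 37 * 176.05,
                     ref_ppm = 135.5, n_freq = n_freq_C, label = "C13"))
}

#' Default processing operators
#'
#' Matched Gaussian apodization along the direct (1H) dimension, squared
#' cosine bell along the indirect (13C) dimension, zero-fill to the axis
#' grid, no phase correction (synthetic data are generated pre-phased).
#'
#' @param axes axis list from [default_axes()].
#' @param lb matched-Gaussian line broadening, Hz (defaults to the usual
#'   80 Hz prototype linewidth).
#' @param gb matched-Gaussian maximum position, fraction of the acquisition
#'   time.
#' @return list with [proc_op()] elements `H` and `C`.
#' @export
default_ops <- function(axes, lb = 80, gb = 0.1) {
  list(H = proc_op("matched_gaussian", lb = lb, gb = gb,
                   zero_fill_to = axes$H$n_freq),
       C = proc_op("squared_cosine", zero_fill_to = axes$C$n_freq))
}

#' Specify a sample group for simulation
#'
#' @param name group label.
#' @param n number of replicate spectra.
#' @param composition named percentages `c(S = , G = , H = )` of lignin
#'   monomer units; must be non-negative and sum to 100.
#' @return list describing the group.
#' @export
sim_group <- function(name, n, composition = c(S = 28, G = 70, H = 2)) {
  if (any(composition < 0)) stop("composition fractions must be non-negative")
  if (abs(sum(composition) - 100) > 1e-6) stop("composition must sum to 100")
  list(name = name, n = as.integer(n), composition = composition)
}

#' Render processed measurement noise
#'
#' Measurement noise enters the time domain and is shaped by the same
#' processing operator as the signal: complex white Gaussian noise is drawn
#' on the acquisition raster, pushed through both dimensions' apodization /
#' zero-fill / FT / phase chains, and the real part taken. The time-domain
#' scale is chosen analytically (from the window energies) so the marginal
#' SD of the resulting frequency-domain noise equals `noise_sd` exactly in
#' expectation; neighbouring grid points are correlated over roughly the
#' apodization linewidth, as in real processed spectra.
#'
#' @param noise_sd target frequency-domain noise SD, intensity units.
#' @param axes,ops axis and operator lists.
#' @return `n_freq_C` x `n_freq_H` real noise matrix.
#' @export
render_noise_plane <- function(noise_sd, axes, ops) {
  win_energy <- function(op, ax) {
    w <- apod_window(op, ax$n_time, ax$dwell)
    w[1] <- w[1] * op$first_point_scale
    sum(w^2)
  }
  cH <- win_energy(ops$H, axes$H)
  cC <- win_energy(ops$C, axes$C)
  sd_t <- noise_sd * sqrt(2 / (cH * cC))
  ntC <- axes$C$n_time; ntH <- axes$H$n_time
  E <- matrix(complex(real = stats::rnorm(ntC * ntH, 0, sd_t / sqrt(2)),
                      imaginary = stats::rnorm(ntC * ntH, 0, sd_t / sqrt(2))),
              ntC, ntH)
  along_H <- t(apply(E, 1, function(r) apply_processing(r, ops$H, axes$H)))
  out <- apply(along_H, 2, function(cl) apply_processing(cl, ops$C, axes$C))
  Re(out)
}

# split an SGH composition into the five role base amplitudes, on a fixed
# lignin-content scale L0 (inverts the weighted lignin sum)
role_base_amplitudes <- function(composition, L0) {
  c(S26 = composition[["S"]] * L0 / 200, Sp26 = composition[["S"]] * L0 / 200,
    G2 = composition[["G"]] * L0 / 400, Gp2 = composition[["G"]] * L0 / 400,
    H26 = composition[["H"]] * L0 / 100)
}

#' Simulate a ground-truth HSQC ensemble
#'
#' Builds a catalog of true signals (one "compound" per selected ROI plus
#' optional extra compounds scattered across ROIs), renders each spectrum by
#' pushing the time-domain model through the same processing operator the
#' analysis uses, and adds processed time-domain Gaussian noise
#' ([render_noise_plane()]) whose frequency-domain SD is `noise_sd`.
#' Signal centres are shared across spectra up to a small per-spectrum
#' drift; amplitudes are group base values with multiplicative lognormal
#' replicate variation. SGH ROI amplitudes encode each group's composition
#' on a fixed lignin-content scale, so the configured S:G:H percentages are
#' exactly recoverable in the noise-free, variation-free limit.
#'
#' @param groups list of [sim_group()]s.
#' @param rois a [roi_table()]; the signal-bearing ROIs are the five SGH
#'   boxes plus `signal_rois`.
#' @param axes,ops axis and operator lists ([default_axes()],
#'   [default_ops()]).
#' @param signal_rois roi_ids of non-SGH ROIs that carry one base compound
#'   each (default: every non-SGH ROI in `rois`).
#' @param n_extra extra compounds placed in randomly chosen signal ROIs,
#'   kept at least `min_sep_fwhm` linewidths away from existing compounds.
#' @param fwhm_range linewidth range (Hz) sampled per compound.
#' @param rep_sdlog lognormal sdlog of replicate amplitude variation.
#' @param snr target signal-to-noise: the noise SD is the median true peak
#'   height divided by `snr`. Ignored when `noise_sd` is given.
#' @param noise_sd explicit noise SD (0 for noise-free data).
#' @param L0 lignin-content scale of the SGH amplitudes.
#' @param other_amp base amplitude of non-SGH compounds, as a fraction of
#'   `L0`.
#' @param drift_H,drift_C maximal per-spectrum centre drift, ppm.
#' @param min_sep_fwhm minimum centre separation between compounds, in
#'   linewidth units.
#' @param seed RNG seed; identical seed and configuration reproduce the
#'   ensemble bit for bit.
#' @return list with `ensemble` (an [nmr_ensemble()]) and `truth` (list
#'   with `signals` truth [signal_table()] incl. `sample_id`, `group`,
#'   `roi_id`; `noise_sd`; `seed`; `config`).
#' @export
simulate_ensemble <- function(groups, rois = bundled_roi_template(),
                              axes = default_axes(), ops = default_ops(axes),
                              signal_rois = NULL, n_extra = 0L,
                              fwhm_range = c(60, 120), rep_sdlog = 0.1,
                              snr = 20, noise_sd = NULL, L0 = 100,
                              other_amp = 0.3, drift_H = 0.004,
                              drift_C = 0.03, min_sep_fwhm = 1.3, seed = 1L) {
  if (!length(groups)) stop("need at least one group")
  set.seed(seed)
  sgh_ids <- rois$roi_id[rois$role %in% c("S", "S'", "G", "G'", "H")]
  if (is.null(signal_rois)) signal_rois <- setdiff(rois$roi_id, sgh_ids)
  compound_rois <- c(sgh_ids, signal_rois)

  # shared compound positions: ROI centre + jitter within the central band,
  # leaving margin for per-spectrum drift so every centre stays in its ROI
  place <- function(roi, pad_h, pad_c) {
    hw <- (roi$h_max_ppm - roi$h_min_ppm) / 2
    cw <- (roi$c_max_ppm - roi$c_min_ppm) / 2
    c(h = (roi$h_min_ppm + roi$h_max_ppm) / 2 +
        stats::runif(1, -1, 1) * pmax(hw * 0.55 - pad_h, 0),
      c = (roi$c_min_ppm + roi$c_max_ppm) / 2 +
        stats::runif(1, -1, 1) * pmax(cw * 0.55 - pad_c, 0))
  }
  compounds <- list()
  for (id in compound_rois) {
    roi <- rois[rois$roi_id == id, ]
    pos <- place(roi, drift_H, drift_C)
    compounds[[length(compounds) + 1L]] <-
      list(roi_id = id, ppm_H = pos[["h"]], ppm_C = pos[["c"]],
           fwhm_H = stats::runif(1, fwhm_range[1], fwhm_range[2]),
           fwhm_C = stats::runif(1, fwhm_range[1], fwhm_range[2]),
           base = NA_real_)
  }
  if (n_extra > 0) {
    pool <- rois[rois$roi_id %in% compound_rois, ]
    sep_ok <- function(h, c0, fh, fc) {
      if (!length(compounds)) return(TRUE)
      all(vapply(compounds, function(cp) {
        dh <- (h - cp$ppm_H) * axes$H$sfrq / max(fh, cp$fwhm_H)
        dc <- (c0 - cp$ppm_C) * axes$C$sfrq / max(fc, cp$fwhm_C)
        sqrt(dh^2 + dc^2) >= min_sep_fwhm
      }, logical(1)))
    }
    added <- 0L; tries <- 0L
    while (added < n_extra && tries < 200L * n_extra) {
      tries <- tries + 1L
      roi <- pool[sample.int(nrow(pool), 1), ]
      pos <- place(roi, drift_H, drift_C)
      fh <- stats::runif(1, fwhm_range[1], fwhm_range[2])
      fc <- stats::runif(1, fwhm_range[1], fwhm_range[2])
      if (sep_ok(pos[["h"]], pos[["c"]], fh, fc)) {
        compounds[[length(compounds) + 1L]] <-
          list(roi_id = roi$roi_id, ppm_H = pos[["h"]], ppm_C = pos[["c"]],
               fwhm_H = fh, fwhm_C = fc,
               base = other_amp * L0 * stats::runif(1, 0.5, 1.5))
        added <- added + 1L
      }
    }
    if (added < n_extra)
      warning("placed only ", added, " of ", n_extra, " extra compounds")
  }

  eta <- c(H = 1, C = 1)
  cache <- basis_cache()
  truth_rows <- list()
  spec_meta <- list()
  s_idx <- 0L
  for (grp in groups) {
    bases <- role_base_amplitudes(grp$composition, L0)
    for (r in seq_len(grp$n)) {
      s_idx <- s_idx + 1L
      sid <- sprintf("%s_%02d", grp$name, r)
      spec_meta[[s_idx]] <- list(sample_id = sid, group = grp$name)
      for (cp in compounds) {
        base <- if (cp$roi_id %in% names(bases)) bases[[cp$roi_id]]
                else if (!is.na(cp$base)) cp$base else other_amp * L0
        if (base <= 0) next
        amp <- base * stats::rlnorm(1, 0, rep_sdlog)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          spectrum_index = s_idx, sample_id = sid, group = grp$name,
          roi_id = cp$roi_id, amplitude = amp,
          ppm_H = cp$ppm_H + stats::runif(1, -drift_H, drift_H),
          ppm_C = cp$ppm_C + stats::runif(1, -drift_C, drift_C),
          fwhm_H = cp$fwhm_H, fwhm_C = cp$fwhm_C, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  truth$signal_id <- paste0("true", seq_len(nrow(truth)))

  heights <- vapply(seq_len(nrow(truth)), function(i)
    truth$amplitude[i] * unit_peak_height(truth$ppm_H[i], truth$ppm_C[i],
                                          truth$fwhm_H[i], truth$fwhm_C[i],
                                          axes, ops, eta, cache),
    numeric(1))
  if (is.null(noise_sd)) noise_sd <- stats::median(heights) / snr

  spectra <- vector("list", s_idx)
  for (s in seq_len(s_idx)) {
    rows <- truth[truth$spectrum_index == s, , drop = FALSE]
    sig <- signal_table(amplitude = rows$amplitude, ppm_H = rows$ppm_H,
                        ppm_C = rows$ppm_C, fwhm_H = rows$fwhm_H,
                        fwhm_C = rows$fwhm_C, spectrum_index = s,
                        roi_id = rows$roi_id, signal_id = rows$signal_id)
    M <- synthesize_spectrum(sig, axes, ops, eta, cache)
    if (noise_sd > 0)
      M <- M + render_noise_plane(noise_sd, axes, ops)
    spectra[[s]] <- spectrum_grid(M, axes$C, axes$H,
                                  sample_id = spec_meta[[s]]$sample_id,
                                  group_label = spec_meta[[s]]$group)
  }
  truth_sig <- signal_table(amplitude = truth$amplitude, ppm_H = truth$ppm_H,
                            ppm_C = truth$ppm_C, fwhm_H = truth$fwhm_H,
                            fwhm_C = truth$fwhm_C,
                            spectrum_index = truth$spectrum_index,
                            roi_id = truth$roi_id, signal_id = truth$signal_id)
  truth_sig$sample_id <- truth$sample_id
  truth_sig$group <- truth$group
  list(ensemble = nmr_ensemble(spectra),
       truth = list(signals = truth_sig, noise_sd = noise_sd, seed = seed,
                    config = list(groups = groups, fwhm_range = fwhm_range,
                                  rep_sdlog = rep_sdlog, snr = snr, L0 = L0,
                                  other_amp = other_amp, n_extra = n_extra,
                                  drift_H = drift_H, drift_C = drift_C)))
}

#' Match fitted signals to ground truth
#'
#' Greedy one-to-one nearest-neighbour matching within each spectrum: pairs
#' are considered in order of increasing centre distance (scaled per axis by
#' the true signal's linewidth) and accepted while the distance is at most
#' `tol` linewidths. Reported per-parameter errors are relative amplitude
#' errors and centre distances in linewidth units; the matching is invariant
#' to row order of either table.
#'
#' @param truth,fitted [signal_table()]s (must carry `spectrum_index`).
#' @param axes axis list (for ppm-to-Hz scaling).
#' @param tol match tolerance, in units of the true linewidth.
#' @return list with `matches` (data frame truth/fitted id pairs with
#'   errors), `summary` (list: `n_true`, `n_fitted`, `n_matched`,
#'   `true_positive_rate`, `median_amplitude_rel_err`,
#'   `median_freq_err_fwhm`), `unmatched_truth`, `extra_fitted`.
#' @export
match_signals <- function(truth, fitted, axes, tol = 0.5) {
  pairs <- list()
  for (s in unique(truth$spectrum_index)) {
    tr <- truth[truth$spectrum_index == s, , drop = FALSE]
    ft <- fitted[fitted$spectrum_index == s, , drop = FALSE]
    if (!nrow(tr) || !nrow(ft)) next
    dh <- outer(tr$ppm_H, ft$ppm_H, "-") * axes$H$sfrq / tr$fwhm_H
    dc <- outer(tr$ppm_C, ft$ppm_C, "-") * axes$C$sfrq / tr$fwhm_C
    D <- sqrt(dh^2 + dc^2)
    ord <- order(D)
    used_t <- logical(nrow(tr)); used_f <- logical(nrow(ft))
    for (k in ord) {
      if (D[k] > tol) break
      i <- (k - 1) %% nrow(tr) + 1; j <- (k - 1) %/% nrow(tr) + 1
      if (used_t[i] || used_f[j]) next
      used_t[i] <- TRUE; used_f[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(
        spectrum_index = s, truth_id = tr$signal_id[i],
        fitted_id = ft$signal_id[j], dist_fwhm = D[k],
        amplitude_rel_err = (ft$amplitude[j] - tr$amplitude[i]) / tr$amplitude[i],
        stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(spectrum_index = integer(), truth_id = character(),
                             fitted_id = character(), dist_fwhm = numeric(),
                             amplitude_rel_err = numeric())
  summary <- list(
    n_true = nrow(truth), n_fitted = nrow(fitted), n_matched = nrow(matches),
    true_positive_rate = if (nrow(truth)) nrow(matches) / nrow(truth) else NA_real_,
    median_amplitude_rel_err = if (nrow(matches))
      stats::median(abs(matches$amplitude_rel_err)) else NA_real_,
    median_freq_err_fwhm = if (nrow(matches))
      stats::median(matches$dist_fwhm) else NA_real_)
  list(matches = matches, summary = summary,
       unmatched_truth = setdiff(truth$signal_id, matches$truth_id),
       extra_fitted = setdiff(fitted$signal_id, matches$fitted_id))
}
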