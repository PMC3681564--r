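#' Signal tables
#'
#' Fitted (or true) 2D signals are kept in a plain data frame with one row
#' per signal and the five free parameters of the model: a non-negative
#' `amplitude`, the peak centre `ppm_H` / `ppm_C`, and per-dimension
#' linewidths `fwhm_H` / `fwhm_C` in Hz (full width at half maximum on the
#' Lorentzian, `eta = 1`, scale: decay rate `alpha = pi * fwhm`). The decay
#' powers are analysis-level constants and are not stored per signal.
#'
#' @param amplitude non-negative amplitudes.
#' @param ppm_H,ppm_C peak centres, ppm.
#' @param fwhm_H,fwhm_C linewidths, Hz.
#' @param spectrum_index 1-based index of the ensemble member the signal
#'   belongs to.
#' @param roi_id assigned ROI id (`NA` if unassigned).
#' @param signal_id unique id; autogenerated when missing.
#' @param iteration_added deconvolution iteration that introduced the signal.
#' @return data frame of class `signal_table`.
#' @export
signal_table <- function(amplitude = numeric(), ppm_H = numeric(),
                         ppm_C = numeric(), fwhm_H = numeric(),
                         fwhm_C = numeric(),
                         spectrum_index = rep(1L, length(amplitude)),
                         roi_id = rep(NA_character_, length(amplitude)),
                         signal_id = NULL, iteration_added = NA_integer_) {
  n <- length(amplitude)
  if (is.null(signal_id)) signal_id <- if (n) paste0("sig", seq_len(n)) else character()
  df <- data.frame(signal_id = as.character(signal_id),
                   spectrum_index = as.integer(spectrum_index),
                   amplitude = as.numeric(amplitude),
                   ppm_H = as.numeric(ppm_H), ppm_C = as.numeric(ppm_C),
                   fwhm_H = as.numeric(fwhm_H), fwhm_C = as.numeric(fwhm_C),
                   roi_id = as.character(roi_id),
                   iteration_added = rep_len(as.integer(iteration_added), n),
                   stringsAsFactors = FALSE)
  if (n) {
    if (any(!is.finite(df$amplitude)) || any(df$amplitude < 0))
      stop("amplitudes must be finite and >= 0")
    if (any(df$fwhm_H <= 0) || any(df$fwhm_C <= 0))
      stop("linewidths must be > 0")
  }
  class(df) <- c("signal_table", "data.frame")
  df
}

#' Number of free model parameters of a signal table
#'
#' Each signal carries exactly five free parameters (amplitude, two
#' frequencies, two decay rates), so a model with `n` signals exposes `5 * n`
#' parameters.
#'
#' @param signals a [signal_table()] (or anything with rows).
#' @return integer parameter count.
#' @export
n_parameters <- function(signals) 5L * nrow(signals)

#' 2D absorption spectrum container
#'
#' @param intensities real matrix; rows index the 13C (indirect) frequency
#'   grid, columns the 1H (direct) grid.
#' @param axis_C,axis_H [axis_spec()] objects for the two dimensions.
#' @param sample_id,group_label sample metadata.
#' @return object of class `spectrum_grid`.
#' @export
spectrum_grid <- function(intensities, axis_C, axis_H,
                          sample_id = "", group_label = "") {
  if (!is.matrix(intensities) || !all(is.finite(intensities)))
    stop("intensities must be an all-finite matrix")
  if (nrow(intensities) != axis_C$n_freq || ncol(intensities) != axis_H$n_freq)
    stop("intensity matrix dimensions must match the axis frequency grids")
  structure(list(intensities = intensities, axis_C = axis_C, axis_H = axis_H,
                 sample_id = sample_id, group_label = group_label),
            class = "spectrum_grid")
}

#' @export
print.spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum_grid %s [%s]: %d x %d (13C x 1H)>\n",
              x$sample_id, x$group_label,
              nrow(x$intensities), ncol(x$intensities)))
  invisible(x)
}

#' Ensemble of spectra sharing axis calibration
#'
#' The pseudo-3D stack used for concerted analysis: all members must share
#' identical axis calibration so thresholds, ROIs and configuration apply
#' uniformly; the pseudo-dimension index is the position in the list.
#'
#' @param spectra list of [spectrum_grid()] objects.
#' @return object of class `nmr_ensemble` (a list of spectra).
#' @export
nmr_ensemble <- function(spectra) {
  if (!length(spectra)) stop("ensemble must contain at least one spectrum")
  ref <- spectra[[1]]
  same_axis <- function(a, b)
    isTRUE(all.equal(a[c("n_time", "dwell", "sfrq", "sw", "ref_ppm", "n_freq")],
                     b[c("n_time", "dwell", "sfrq", "sw", "ref_ppm", "n_freq")]))
  for (sp in spectra) {
    if (!inherits(sp, "spectrum_grid")) stop("all members must be spectrum_grid")
    if (!same_axis(sp$axis_C, ref$axis_C) || !same_axis(sp$axis_H, ref$axis_H))
      stop("all ensemble members must share identical axis calibration")
  }
  structure(spectra, class = "nmr_ensemble")
}

#' @export
print.nmr_ensemble <- function(x, ...) {
  cat(sprintf("<nmr_ensemble: %d spectra, %d x %d grid>\n", length(x),
              nrow(x[[1]]$intensities), ncol(x[[1]]$intensities)))
  invisible(x)
}

# per-signal 1D bases along both dimensions (optionally with derivatives)
signal_bases <- function(sig, axes, ops, eta, cache, deriv = FALSE) {
  bH <- damped_sinusoid(ppm_to_hz(axes$H, sig$ppm_H), pi * sig$fwhm_H, eta[["H"]])
  bC <- damped_sinusoid(ppm_to_hz(axes$C, sig$ppm_C), pi * sig$fwhm_C, eta[["C"]])
  out <- list(
    bH = freq_basis_1d(bH, axes$H, ops$H, cache),
    bC = freq_basis_1d(bC, axes$C, ops$C, cache))
  if (deriv) {
    out$dH_w <- freq_basis_1d(bH, axes$H, ops$H, cache, deriv = "omega")
    out$dH_a <- freq_basis_1d(bH, axes$H, ops$H, cache, deriv = "alpha")
    out$dC_w <- freq_basis_1d(bC, axes$C, ops$C, cache, deriv = "omega")
    out$dC_a <- freq_basis_1d(bC, axes$C, ops$C, cache, deriv = "alpha")
  }
  out
}

check_signal_range <- function(signals, axes) {
  rh <- ppm_range(axes$H); rc <- ppm_range(axes$C)
  bad <- signals$ppm_H < rh[1] | signals$ppm_H > rh[2] |
         signals$ppm_C < rc[1] | signals$ppm_C > rc[2]
  if (any(bad))
    stop("signal frequency outside the representable spectral width: ",
         paste(signals$signal_id[bad], collapse = ", "))
}

#' Synthesize the model spectrum of a signal table
#'
#' The 2D model plane is the sum over signals of `amplitude` times the outer
#' product of the two processed 1D absorption basis vectors. It is additive
#' in signals and homogeneous in amplitude.
#'
#' @param signals a [signal_table()].
#' @param axes list with elements `H` and `C` ([axis_spec()]).
#' @param ops list with elements `H` and `C` ([proc_op()]).
#' @param eta named vector `c(H = , C = )` of decay powers.
#' @param cache optional [basis_cache()].
#' @return `n_freq_C` x `n_freq_H` numeric matrix.
#' @export
synthesize_spectrum <- function(signals, axes, ops, eta = c(H = 1, C = 1),
                                cache = NULL) {
  M <- matrix(0, axes$C$n_freq, axes$H$n_freq)
  if (!nrow(signals)) return(M)
  check_signal_range(signals, axes)
  for (i in seq_len(nrow(signals))) {
    b <- signal_bases(signals[i, ], axes, ops, eta, cache)
    M <- M + signals$amplitude[i] * tcrossprod(b$bC, b$bH)
  }
  M
}

#' Analytic parameter derivatives of the model spectrum
#'
#' For every signal, the derivative plane with respect to each of its five
#' free parameters, obtained by pushing the time-domain derivative bases
#' through the same processing operator as the model itself. The amplitude
#' derivative is the unit-amplitude basis plane; frequency derivatives carry
#' the ppm-to-Hz chain factor (`sfrq`), linewidth derivatives the
#' `alpha = pi * fwhm` chain factor.
#'
#' @inheritParams synthesize_spectrum
#' @return list (one element per signal) of lists of derivative matrices
#'   named `amplitude`, `ppm_H`, `ppm_C`, `fwhm_H`, `fwhm_C`.
#' @export
model_jacobian <- function(signals, axes, ops, eta = c(H = 1, C = 1),
                           cache = NULL) {
  check_signal_range(signals, axes)
  lapply(seq_len(nrow(signals)), function(i) {
    s <- signals[i, ]
    b <- signal_bases(s, axes, ops, eta, cache, deriv = TRUE)
    list(amplitude = tcrossprod(b$bC, b$bH),
         ppm_H = s$amplitude * axes$H$sfrq * tcrossprod(b$bC, b$dH_w),
         ppm_C = s$amplitude * axes$C$sfrq * tcrossprod(b$dC_w, b$bH),
         fwhm_H = s$amplitude * pi * tcrossprod(b$bC, b$dH_a),
         fwhm_C = s$amplitude * pi * tcrossprod(b$dC_a, b$bH))
  })
}

# ---- masked evaluation used by the fitting engine -------------------------

# model values at mask points (ii = row/13C index, jj = col/1H index)
eval_model_masked <- function(signals, axes, ops, eta, cache, ii, jj) {
  v <- numeric(length(ii))
  for (i in seq_len(nrow(signals))) {
    b <- signal_bases(signals[i, ], axes, ops, eta, cache)
    v <- v + signals$amplitude[i] * b$bC[ii] * b$bH[jj]
  }
  v
}

# Jacobian of masked model values; columns in blocks of 5 per signal
# (amplitude, ppm_H, ppm_C, fwhm_H, fwhm_C)
eval_jacobian_masked <- function(signals, axes, ops, eta, cache, ii, jj) {
  J <- matrix(0, length(ii), 5L * nrow(signals))
  for (i in seq_len(nrow(signals))) {
    s <- signals[i, ]
    b <- signal_bases(s, axes, ops, eta, cache, deriv = TRUE)
    k <- 5L * (i - 1L)
    J[, k + 1L] <- b$bC[ii] * b$bH[jj]
    J[, k + 2L] <- s$amplitude * axes$H$sfrq * b$bC[ii] * b$dH_w[jj]
    J[, k + 3L] <- s$amplitude * axes$C$sfrq * b$dC_w[ii] * b$bH[jj]
    J[, k + 4L] <- s$amplitude * pi * b$bC[ii] * b$dH_a[jj]
    J[, k + 5L] <- s$amplitude * pi * b$dC_a[ii] * b$bH[jj]
  }
  J
}

pack_params <- function(signals)
  as.numeric(t(as.matrix(signals[, c("amplitude", "ppm_H", "ppm_C",
                                     "fwhm_H", "fwhm_C")])))

unpack_params <- function(par, signals) {
  m <- matrix(par, ncol = 5, byrow = TRUE)
  signals$amplitude <- m[, 1]; signals$ppm_H <- m[, 2]; signals$ppm_C <- m[, 3]
  signals$fwhm_H <- m[, 4]; signals$fwhm_C <- m[, 5]
  signals
}
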