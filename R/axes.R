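#' Axis calibration for one spectral dimension
#'
#' An `axis_spec` captures everything needed to evaluate a time-domain model
#' along one dimension of a 2D HSQC experiment and to map its processed
#' frequency grid to chemical shifts: the number of acquired (complex) time
#' points, the spectrometer observe frequency, the spectral width, the
#' chemical shift of the first frequency point, and the frequency-grid length
#' after zero-filling.
#'
#' The ppm axis runs from `ref_ppm` (first point) downward, the conventional
#' left-to-right NMR display order, and is strictly monotone decreasing.
#'
#' @param n_time number of acquired complex time-domain points (>= 2).
#' @param sfrq observe frequency of the nucleus, MHz (Hz per ppm).
#' @param sw spectral width, Hz. The dwell time is `1/sw`.
#' @param ref_ppm chemical shift (ppm) of the first (left-most) frequency point.
#' @param n_freq frequency-grid length after zero-filling; must be an even
#'   number `>= n_time`. Default: next power of two at least `2 * n_time`.
#' @param label dimension label, `"H1"` (direct) or `"C13"` (indirect).
#' @return An object of class `axis_spec`.
#' @examples
#' ax <- axis_spec(128, sfrq = 700.13, sw = 1540, ref_ppm = 8.2)
#' head(ppm_axis(ax))
#' @export
axis_spec <- function(n_time, sfrq, sw, ref_ppm,
                      n_freq = next_pow2(2L * n_time),
                      label = c("H1", "C13")) {
  label <- match.arg(label)
  if (!is.finite(n_time) || n_time < 2) stop("n_time must be >= 2")
  if (!is.finite(sw) || sw <= 0) stop("sw must be > 0")
  if (!is.finite(sfrq) || sfrq <= 0) stop("sfrq must be > 0")
  if (!is.finite(ref_ppm)) stop("ref_ppm must be finite")
  n_freq <- as.integer(n_freq)
  if (n_freq < n_time) stop("n_freq must be >= n_time")
  if (n_freq %% 2L != 0L) stop("n_freq must be even")
  structure(
    list(n_time = as.integer(n_time), dwell = 1 / sw, sfrq = sfrq, sw = sw,
         ref_ppm = ref_ppm, n_freq = n_freq, label = label),
    class = "axis_spec")
}

#' @export
print.axis_spec <- function(x, ...) {
  cat(sprintf("<axis_spec %s: %d time pts, %d freq pts, sw %.1f Hz, %.2f MHz, ref %.3f ppm>\n",
              x$label, x$n_time, x$n_freq, x$sw, x$sfrq, x$ref_ppm))
  invisible(x)
}

#' Smallest power of two not below `n`
#' @param n positive number.
#' @return integer power of two `>= n`.
#' @export
next_pow2 <- function(n) as.integer(2^ceiling(log2(n)))

#' Chemical-shift axis of a processed dimension
#'
#' @param axis an [axis_spec()].
#' @return numeric vector of length `n_freq`, strictly decreasing ppm values.
#' @export
ppm_axis <- function(axis) {
  axis$ref_ppm - (seq_len(axis$n_freq) - 1) * axis$sw / (axis$sfrq * axis$n_freq)
}

#' @rdname ppm_axis
#' @export
ppm_range <- function(axis) {
  c(axis$ref_ppm - axis$sw / axis$sfrq, axis$ref_ppm)
}

# carrier sits at the centre of the spectral window
carrier_ppm <- function(axis) axis$ref_ppm - axis$sw / (2 * axis$sfrq)

#' Convert chemical shift to frequency offset from the carrier
#'
#' @param axis an [axis_spec()].
#' @param ppm chemical shift(s), ppm.
#' @return offset(s) in Hz relative to the carrier (window centre).
#' @export
ppm_to_hz <- function(axis, ppm) (ppm - carrier_ppm(axis)) * axis$sfrq

#' @rdname ppm_to_hz
#' @param hz frequency offset(s) in Hz.
#' @export
hz_to_ppm <- function(axis, hz) carrier_ppm(axis) + hz / axis$sfrq

# sampled acquisition times t_k = k * dwell, k = 0 .. n_time-1
acq_times <- function(axis) (seq_len(axis$n_time) - 1) * axis$dwell

`%||%` <- function(a, b) if (is.null(a)) b else a
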