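#' One-dimensional damped sinusoid basis
#'
#' The time-domain basis along one dimension is the product of a complex
#' sinusoid `exp(i * 2 * pi * omega * t)` and a real damping function
#' `exp(-alpha * t^eta)`. `omega` is the frequency offset from the carrier in
#' Hz, `alpha` the decay rate, and `eta` the decay power. `eta` is a
#' profiling-level constant: it is fixed per analysis (never optimized), with
#' `eta = 1` giving Lorentzian decay, for which the full width at half maximum
#' of the absorption line is `alpha / pi` Hz.
#'
#' @param omega_hz frequency offset from the carrier, Hz.
#' @param alpha decay rate (>= 0), s^-eta.
#' @param eta decay power (> 0), fixed per analysis.
#' @return An object of class `damped_sinusoid`.
#' @export
damped_sinusoid <- function(omega_hz, alpha, eta = 1) {
  if (!all(is.finite(c(omega_hz, alpha, eta))))
    stop("damped_sinusoid parameters must be finite")
  if (alpha < 0) stop("alpha must be >= 0")
  if (eta <= 0) stop("eta must be > 0")
  structure(list(omega = omega_hz, alpha = alpha, eta = eta),
            class = "damped_sinusoid")
}

#' Evaluate a damped sinusoid on the acquisition raster
#'
#' Returns the complex FID sampled at `t_k = k * dwell`, `k = 0 ..
#' n_time - 1`. `deriv` selects the analytic parameter derivative of the
#' basis: `"omega"` gives `i * 2 * pi * t` times the FID (derivative with
#' respect to the frequency in Hz), `"alpha"` gives `-t^eta` times the FID.
#'
#' @param basis a [damped_sinusoid()].
#' @param axis an [axis_spec()].
#' @param deriv `"none"`, `"omega"` or `"alpha"`.
#' @return complex vector of length `axis$n_time`.
#' @export
eval_fid_1d <- function(basis, axis, deriv = c("none", "omega", "alpha")) {
  deriv <- match.arg(deriv)
  if (!inherits(basis, "damped_sinusoid")) basis <- do.call(damped_sinusoid, basis)
  t <- acq_times(axis)
  fid <- exp(1i * 2 * pi * basis$omega * t - basis$alpha * t^basis$eta)
  switch(deriv,
         none  = fid,
         omega = 1i * 2 * pi * t * fid,
         alpha = -(t^basis$eta) * fid)
}

#' Cache for frequency-domain basis vectors
#'
#' Basis vectors are keyed by (dimension label, derivative, omega, alpha,
#' eta); a cache is only valid for one fixed (axis, operator) pair and is
#' transparent: cached and uncached evaluations are bit-identical.
#'
#' @return an environment usable as the `cache` argument of
#'   [freq_basis_1d()] and the model builders.
#' @export
basis_cache <- function() new.env(parent = emptyenv())

#' Frequency-domain absorption basis vector
#'
#' Real part of the processed damped sinusoid: the exact frequency-domain
#' shape that a time-domain signal with these parameters takes after the
#' dimension's processing chain. Optionally returns the processed analytic
#' derivative basis instead.
#'
#' @inheritParams eval_fid_1d
#' @param op the dimension's [proc_op()].
#' @param cache optional [basis_cache()] environment.
#' @return numeric vector of length `n_freq`.
#' @export
freq_basis_1d <- function(basis, axis, op, cache = NULL,
                          deriv = c("none", "omega", "alpha")) {
  deriv <- match.arg(deriv)
  if (!inherits(basis, "damped_sinusoid")) basis <- do.call(damped_sinusoid, basis)
  if (!is.null(cache)) {
    key <- sprintf("%s|%s|%.17g|%.17g|%.17g",
                   axis$label, deriv, basis$omega, basis$alpha, basis$eta)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  v <- Re(apply_processing(eval_fid_1d(basis, axis, deriv), op, axis))
  if (!is.null(cache)) cache[[key]] <- v
  v
}
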