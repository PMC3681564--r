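#' Prototype linewidth configuration
#'
#' FMLR seeds every new signal with the linewidths of an operator-chosen
#' archetypal ("prototype") signal, and constrains all fitted linewidths to
#' a factor window around them per dimension: with the usual 80 Hz prototype
#' and factors 1/2 to 2, fitted linewidths must lie in [40, 160] Hz.
#'
#' @param linewidth_H,linewidth_C prototype linewidths, Hz.
#' @param low_factor,high_factor linewidth box-constraint factors,
#'   `0 < low <= 1 <= high`.
#' @return object of class `prototype_config`.
#' @export
prototype_config <- function(linewidth_H = 80, linewidth_C = 80,
                             low_factor = 0.5, high_factor = 2) {
  if (!(low_factor > 0 && low_factor <= 1 && high_factor >= 1))
    stop("need 0 < low_factor <= 1 <= high_factor")
  if (linewidth_H <= 0 || linewidth_C <= 0) stop("linewidths must be > 0")
  structure(list(linewidth_H = linewidth_H, linewidth_C = linewidth_C,
                 low_factor = low_factor, high_factor = high_factor),
            class = "prototype_config")
}

#' Linewidth box constraints implied by a prototype
#'
#' @param prototype a [prototype_config()].
#' @return list with elements `H` and `C`, each `c(low, high)` in Hz.
#' @export
linewidth_bounds <- function(prototype) {
  list(H = prototype$linewidth_H * c(prototype$low_factor, prototype$high_factor),
       C = prototype$linewidth_C * c(prototype$low_factor, prototype$high_factor))
}

#' Deconvolution configuration
#'
#' @param snr_stop minimum pick threshold as a multiple of the noise SD;
#'   deconvolution stops once the geometric threshold schedule drops below
#'   `snr_stop * noise_sd` and a final pass at that floor picks nothing.
#' @param threshold_decay geometric decay factor of the pick threshold
#'   (> 1).
#' @param max_iterations hard cap on pick-refine iterations.
#' @param model_only_in_rois if `TRUE` (the default and the documented
#'   behaviour) only residual peaks inside at least one ROI are modeled.
#' @param eta_H,eta_C decay powers, fixed per analysis.
#' @param min_separation_fwhm candidates closer than this many prototype
#'   linewidths to an existing signal of the same spectrum are skipped in
#'   that iteration (avoids duplicate modeling of one shoulder).
#' @param cluster_link_fwhm signals whose centres are within this many
#'   prototype linewidths (scaled Euclidean distance) are refined jointly.
#' @param global_refit refit every cluster each iteration instead of only
#'   clusters that received new signals.
#' @param fit_maxiter per-cluster Levenberg-Marquardt iteration cap.
#' @param fit_ftol relative objective convergence tolerance.
#' @return object of class `deconvolution_config`.
#' @export
deconvolution_config <- function(snr_stop = 4, threshold_decay = 2,
                                 max_iterations = 10L,
                                 model_only_in_rois = TRUE,
                                 eta_H = 1, eta_C = 1,
                                 min_separation_fwhm = 0.5,
                                 cluster_link_fwhm = 3,
                                 global_refit = FALSE,
                                 fit_maxiter = 50L, fit_ftol = 1e-8) {
  if (snr_stop <= 0) stop("snr_stop must be > 0")
  if (threshold_decay <= 1) stop("threshold_decay must be > 1")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(snr_stop = snr_stop, threshold_decay = threshold_decay,
                 max_iterations = as.integer(max_iterations),
                 model_only_in_rois = model_only_in_rois,
                 eta_H = eta_H, eta_C = eta_C,
                 min_separation_fwhm = min_separation_fwhm,
                 cluster_link_fwhm = cluster_link_fwhm,
                 global_refit = global_refit,
                 fit_maxiter = as.integer(fit_maxiter), fit_ftol = fit_ftol),
            class = "deconvolution_config")
}

config_eta <- function(config) c(H = config$eta_H, C = config$eta_C)

#' Robust noise estimate of an ensemble
#'
#' Median-absolute-deviation estimate (scaled by 1.4826 to the Gaussian SD)
#' of the signal-free intensities: grid points outside every ROI, pooled
#' across all ensemble members. If the ROIs tile the whole grid the whole
#' spectrum is used when `fallback = TRUE`, otherwise an error is raised.
#'
#' @param ensemble an [nmr_ensemble()].
#' @param rois a [roi_table()] or `NULL` (whole spectrum).
#' @param fallback use the whole grid when no point lies outside the ROIs.
#' @return noise SD in intensity units.
#' @export
estimate_noise_sd <- function(ensemble, rois = NULL, fallback = TRUE) {
  axC <- ensemble[[1]]$axis_C; axH <- ensemble[[1]]$axis_H
  keep <- if (is.null(rois)) matrix(TRUE, axC$n_freq, axH$n_freq)
          else !roi_union_mask(rois, axC, axH)
  if (!any(keep)) {
    if (!fallback) stop("no grid points outside the ROIs")
    keep <- matrix(TRUE, axC$n_freq, axH$n_freq)
  }
  x <- unlist(lapply(ensemble, function(sp) sp$intensities[keep]),
              use.names = FALSE)
  stats::mad(x)
}

#' Pick candidate peaks in a residual spectrum
#'
#' Local maxima of the residual over the 8-neighborhood with height at
#' least `threshold`, whose centre lies inside at least one ROI. Candidates
#' are returned sorted by decreasing height; ties break to lower `ppm_H`,
#' then lower `ppm_C`.
#'
#' @param residual a [spectrum_grid()] (data minus current model).
#' @param rois a [roi_table()] (`NULL` disables the ROI filter).
#' @param threshold minimum peak height (> 0), intensity units.
#' @return data frame `ppm_H`, `ppm_C`, `height`, `row`, `col` (possibly
#'   zero rows).
#' @export
pick_candidates <- function(residual, rois, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  M <- residual$intensities
  nr <- nrow(M); nc <- ncol(M)
  P <- matrix(-Inf, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- M
  ge_all <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ge_all <- ge_all & (M >= P[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)])
  }
  hits <- which(ge_all & M >= threshold, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(ppm_H = numeric(), ppm_C = numeric(),
                      height = numeric(), row = integer(), col = integer()))
  }
  ph <- ppm_axis(residual$axis_H); pc <- ppm_axis(residual$axis_C)
  cand <- data.frame(ppm_H = ph[hits[, 2]], ppm_C = pc[hits[, 1]],
                     height = M[hits], row = hits[, 1], col = hits[, 2])
  if (!is.null(rois)) {
    inside <- vapply(seq_len(nrow(cand)), function(i)
      length(containing_rois(cand$ppm_H[i], cand$ppm_C[i], rois)) > 0, logical(1))
    cand <- cand[inside, , drop = FALSE]
  }
  cand <- cand[order(-cand$height, cand$ppm_H, cand$ppm_C), , drop = FALSE]
  # drop 8-adjacent plateau duplicates, keeping the first in sort order
  if (nrow(cand) > 1) {
    keep <- rep(TRUE, nrow(cand))
    for (i in 2:nrow(cand)) {
      adj <- abs(cand$row[seq_len(i - 1)] - cand$row[i]) <= 1 &
             abs(cand$col[seq_len(i - 1)] - cand$col[i]) <= 1
      if (any(adj & keep[seq_len(i - 1)] &
              cand$height[seq_len(i - 1)] == cand$height[i]))
        keep[i] <- FALSE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}

# scaled centre-to-centre distance in units of the prototype linewidth
separation_fwhm <- function(ppm_H1, ppm_C1, ppm_H2, ppm_C2, prototype, axes) {
  dh <- (ppm_H1 - ppm_H2) * axes$H$sfrq / prototype$linewidth_H
  dc <- (ppm_C1 - ppm_C2) * axes$C$sfrq / prototype$linewidth_C
  sqrt(dh^2 + dc^2)
}

# peak height of the unit-amplitude basis plane at the given parameters
unit_peak_height <- function(ppm_H, ppm_C, fwhm_H, fwhm_C, axes, ops, eta, cache) {
  bH <- freq_basis_1d(damped_sinusoid(ppm_to_hz(axes$H, ppm_H), pi * fwhm_H, eta[["H"]]),
                      axes$H, ops$H, cache)
  bC <- freq_basis_1d(damped_sinusoid(ppm_to_hz(axes$C, ppm_C), pi * fwhm_C, eta[["C"]]),
                      axes$C, ops$C, cache)
  max(bC) * max(bH)
}

# connected components of signals linked when centres are within
# cluster_link_fwhm prototype linewidths
signal_clusters <- function(signals, prototype, axes, link) {
  n <- nrow(signals)
  if (n <= 1) return(rep(1L, n)[seq_len(n)])
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    d <- separation_fwhm(signals$ppm_H[i], signals$ppm_C[i],
                         signals$ppm_H[(i + 1):n], signals$ppm_C[(i + 1):n],
                         prototype, axes)
    for (j in which(d <= link)) {
      jj <- i + j
      old <- comp[jj]; new <- comp[i]
      if (old != new) comp[comp == old] <- new
    }
  }
  match(comp, unique(comp))
}

# bounded Levenberg-Marquardt refinement of one signal subset against
# target values at mask points (ii, jj)
fit_signal_block <- function(target, signals, ii, jj, axes, ops, eta, cache,
                             lw_bounds, config, warn_nonconv = TRUE) {
  n <- nrow(signals)
  par0 <- pack_params(signals)
  rh <- ppm_range(axes$H); rc <- ppm_range(axes$C)
  lower <- rep(c(0, rh[1], rc[1], lw_bounds$H[1], lw_bounds$C[1]), n)
  upper <- rep(c(Inf, rh[2], rc[2], lw_bounds$H[2], lw_bounds$C[2]), n)
  par0 <- pmin(pmax(par0, lower), upper)
  fn <- function(p) target - eval_model_masked(unpack_params(p, signals),
                                               axes, ops, eta, cache, ii, jj)
  jac <- function(p) -eval_jacobian_masked(unpack_params(p, signals),
                                           axes, ops, eta, cache, ii, jj)
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = fn, jac = jac,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$fit_maxiter,
                           ftol = config$fit_ftol, ptol = config$fit_ftol))),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("least-squares refinement failed; keeping initial parameters")
    return(signals)
  }
  if (warn_nonconv && fit$info %in% c(-1, 0, 9))
    warning("refinement did not converge within the evaluation budget; ",
            "returning best parameters so far")
  # accept only if the objective did not get worse (LM should guarantee it)
  if (sum(fit$fvec^2) <= sum(fn(par0)^2)) unpack_params(fit$par, signals)
  else signals
}

#' Fit the prototype signal in an operator-chosen window
#'
#' Fits a single five-parameter signal to the dominant peak inside the seed
#' window, with broad linewidth sanity bounds instead of the prototype box,
#' and returns its linewidths as the prototype configuration for the
#' ensemble analysis.
#'
#' @param spectrum a [spectrum_grid()].
#' @param seed_region window `c(h_min, h_max, c_min, c_max)` in ppm
#'   containing exactly one dominant peak.
#' @param ops processing operators, list with `H` and `C`.
#' @param noise_sd noise SD; estimated from the spectrum outside the window
#'   when `NULL`.
#' @param config a [deconvolution_config()] (for `snr_stop`, `eta`, fit
#'   controls).
#' @param low_factor,high_factor constraint factors stored in the returned
#'   prototype.
#' @param sanity_bounds broad linewidth bounds (Hz) used for the prototype
#'   fit itself.
#' @return a [prototype_config()] with attribute `"signal"` holding the
#'   fitted [signal_table()] row.
#' @export
fit_prototype <- function(spectrum, seed_region, ops, noise_sd = NULL,
                          config = deconvolution_config(),
                          low_factor = 0.5, high_factor = 2,
                          sanity_bounds = c(5, 2000)) {
  axes <- list(H = spectrum$axis_H, C = spectrum$axis_C)
  win <- roi_table(data.frame(roi_id = "seed", label = "", role = "other",
                              h_min_ppm = seed_region[1], h_max_ppm = seed_region[2],
                              c_min_ppm = seed_region[3], c_max_ppm = seed_region[4]))
  mask <- roi_mask_one(win[1, ], axes$C, axes$H)
  if (!any(mask)) stop("seed window contains no grid points")
  if (is.null(noise_sd))
    noise_sd <- estimate_noise_sd(nmr_ensemble(list(spectrum)), win)
  idx <- which(mask, arr.ind = TRUE)
  vals <- spectrum$intensities[mask]
  if (max(vals) < config$snr_stop * noise_sd)
    stop("no peak above snr_stop * noise in the seed window")
  top <- idx[which.max(vals), ]
  eta <- config_eta(config)
  cache <- basis_cache()
  init <- signal_table(amplitude = 1, ppm_H = ppm_axis(axes$H)[top[2]],
                       ppm_C = ppm_axis(axes$C)[top[1]],
                       fwhm_H = 80, fwhm_C = 80)
  u <- unit_peak_height(init$ppm_H, init$ppm_C, init$fwhm_H, init$fwhm_C,
                        axes, ops, eta, cache)
  init$amplitude <- max(vals) / u
  fit <- fit_signal_block(vals, init, idx[, 1], idx[, 2], axes, ops, eta,
                          cache, list(H = sanity_bounds, C = sanity_bounds),
                          config)
  proto <- prototype_config(fit$fwhm_H, fit$fwhm_C, low_factor, high_factor)
  attr(proto, "signal") <- fit
  proto
}

#' Refine a spectrum's signals by constrained least squares
#'
#' Minimizes the sum of squared residuals over the ROI grid points with
#' non-negative amplitudes and the prototype linewidth box, refining jointly
#' per connected cluster of overlapping signals (centres within
#' `cluster_link_fwhm` prototype linewidths) while holding the remaining
#' signals fixed. Signals whose centre drifts outside every ROI are
#' dropped.
#'
#' @param spectrum the data [spectrum_grid()].
#' @param signals current [signal_table()] rows for this spectrum.
#' @param prototype a [prototype_config()].
#' @param rois a [roi_table()].
#' @param ops processing operators, list with `H` and `C`.
#' @param config a [deconvolution_config()].
#' @param cache optional [basis_cache()].
#' @param refit_only optional logical vector marking signals whose clusters
#'   must be refined (`NULL` refines all clusters).
#' @param warn_nonconv emit a warning when a cluster fit stops at its
#'   evaluation budget (best-so-far parameters are kept either way).
#' @return the refined [signal_table()].
#' @export
refine_model <- function(spectrum, signals, prototype, rois, ops,
                         config = deconvolution_config(), cache = NULL,
                         refit_only = NULL, warn_nonconv = TRUE) {
  if (!nrow(signals)) return(signals)
  axes <- list(H = spectrum$axis_H, C = spectrum$axis_C)
  eta <- config_eta(config)
  if (is.null(cache)) cache <- basis_cache()
  lw <- linewidth_bounds(prototype)
  union_mask <- roi_union_mask(rois, axes$C, axes$H)
  model <- synthesize_spectrum(signals, axes, ops, eta, cache)
  clus <- signal_clusters(signals, prototype, axes, config$cluster_link_fwhm)
  todo <- if (is.null(refit_only)) unique(clus) else unique(clus[refit_only])
  ph <- ppm_axis(axes$H); pc <- ppm_axis(axes$C)
  for (cl in todo) {
    sel <- clus == cl
    sub <- signals[sel, , drop = FALSE]
    # footprint: ROI points within 4 prototype linewidths of a cluster centre
    span_h <- 4 * prototype$linewidth_H / axes$H$sfrq
    span_c <- 4 * prototype$linewidth_C / axes$C$sfrq
    col_ok <- ph >= min(sub$ppm_H) - span_h & ph <= max(sub$ppm_H) + span_h
    row_ok <- pc >= min(sub$ppm_C) - span_c & pc <= max(sub$ppm_C) + span_c
    fmask <- union_mask & outer(row_ok, col_ok)
    if (!any(fmask)) fmask <- union_mask
    idx <- which(fmask, arr.ind = TRUE)
    ii <- idx[, 1]; jj <- idx[, 2]
    sub_model <- eval_model_masked(sub, axes, ops, eta, cache, ii, jj)
    target <- spectrum$intensities[fmask] - (model[fmask] - sub_model)
    new_sub <- fit_signal_block(target, sub, ii, jj, axes, ops, eta, cache,
                                lw, config, warn_nonconv)
    # update the full model plane with the refitted cluster
    delta <- synthesize_spectrum(new_sub, axes, ops, eta, cache) -
             synthesize_spectrum(sub, axes, ops, eta, cache)
    model <- model + delta
    signals[sel, ] <- new_sub
  }
  keep <- vapply(seq_len(nrow(signals)), function(i)
    length(containing_rois(signals$ppm_H[i], signals$ppm_C[i], rois)) > 0,
    logical(1))
  signals[keep, , drop = FALSE]
}

#' Greedy FMLR deconvolution of an ensemble
#'
#' Implements the iterative threshold schedule: the pick threshold starts at
#' the tallest ROI-restricted residual point of the whole ensemble, and is
#' divided by `threshold_decay` after each iteration. Within an iteration,
#' each spectrum's residual is peak-picked at the current threshold (never
#' below the `snr_stop * noise_sd` floor), new signals are seeded with
#' prototype linewidths and a one-step linear amplitude estimate, and the
#' clusters receiving new signals are refined by bounded least squares.
#' The analysis stops when the schedule has dropped below the floor and a
#' pass at the floor adds no further signal, or after `max_iterations`.
#'
#' @param ensemble an [nmr_ensemble()].
#' @param rois a [roi_table()].
#' @param prototype a [prototype_config()].
#' @param ops processing operators, list with `H` and `C` (the same chain
#'   applied to the data).
#' @param config a [deconvolution_config()].
#' @param noise_sd noise SD; estimated with [estimate_noise_sd()] when
#'   `NULL`.
#' @param verbose print per-iteration progress.
#' @return object of class `deconvolution_result`: list with `signals`
#'   (all spectra, with `sample_id` column), `residual` (an
#'   [nmr_ensemble()]), `noise_sd`, `iterations_run`, `n_parameters`,
#'   `threshold_final`, `rss_history`, `config`, `prototype`.
#' @export
deconvolve_ensemble <- function(ensemble, rois, prototype, ops,
                                config = deconvolution_config(),
                                noise_sd = NULL, verbose = FALSE) {
  axes <- list(H = ensemble[[1]]$axis_H, C = ensemble[[1]]$axis_C)
  eta <- config_eta(config)
  cache <- basis_cache()
  union_mask <- roi_union_mask(rois, axes$C, axes$H)
  if (!any(union_mask)) stop("no grid point lies inside any ROI")
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(ensemble, rois)
  floor_thr <- config$snr_stop * noise_sd
  n_spec <- length(ensemble)
  sig_by_spec <- rep(list(signal_table()), n_spec)
  models <- lapply(ensemble, function(sp) 0 * sp$intensities)
  resid_of <- function(s) ensemble[[s]]$intensities - models[[s]]
  thr_geo <- max(vapply(seq_len(n_spec),
                        function(s) max(resid_of(s)[union_mask]), numeric(1)))
  iterations <- 0L
  rss_history <- numeric()
  next_id <- 1L

  repeat {
    iterations <- iterations + 1L
    thr <- max(thr_geo, floor_thr)
    new_any <- FALSE
    for (s in seq_len(n_spec)) {
      res_grid <- spectrum_grid(resid_of(s), axes$C, axes$H)
      cand <- pick_candidates(res_grid,
                              if (config$model_only_in_rois) rois else NULL,
                              thr)
      if (!nrow(cand)) next
      new_any <- TRUE
      cur <- sig_by_spec[[s]]
      added <- 0L
      for (i in seq_len(nrow(cand))) {
        # skip candidates that duplicate a signal added earlier in this
        # same iteration (residual shoulders of a peak just modeled)
        if (added > 0L) {
          fresh <- cur[cur$iteration_added == iterations &
                         !is.na(cur$iteration_added), , drop = FALSE]
          if (nrow(fresh) &&
              min(separation_fwhm(cand$ppm_H[i], cand$ppm_C[i],
                                  fresh$ppm_H, fresh$ppm_C,
                                  prototype, axes)) <
                config$min_separation_fwhm) next
        }
        amp <- cand$height[i] /
          unit_peak_height(cand$ppm_H[i], cand$ppm_C[i],
                           prototype$linewidth_H, prototype$linewidth_C,
                           axes, ops, eta, cache)
        add <- signal_table(amplitude = max(amp, 0),
                            ppm_H = cand$ppm_H[i], ppm_C = cand$ppm_C[i],
                            fwhm_H = prototype$linewidth_H,
                            fwhm_C = prototype$linewidth_C,
                            spectrum_index = s,
                            signal_id = paste0("s", s, "_", next_id),
                            iteration_added = iterations)
        next_id <- next_id + 1L
        cur <- rbind(as.data.frame(cur), as.data.frame(add))
        class(cur) <- c("signal_table", "data.frame")
        added <- added + 1L
      }
      if (added > 0L) {
        is_new <- cur$iteration_added == iterations & !is.na(cur$iteration_added)
        refined <- refine_model(ensemble[[s]], cur, prototype, rois, ops,
                                config, cache,
                                refit_only = if (config$global_refit) NULL else is_new,
                                warn_nonconv = FALSE)
        sig_by_spec[[s]] <- refined
        models[[s]] <- synthesize_spectrum(refined, axes, ops, eta, cache)
      }
    }
    at_floor <- thr_geo <= floor_thr
    if (!new_any) {
      # quiescent pass: full block-coordinate sweep over every cluster,
      # tightening the joint fit before lowering the threshold further
      for (s in seq_len(n_spec)) {
        if (!nrow(sig_by_spec[[s]])) next
        refined <- refine_model(ensemble[[s]], sig_by_spec[[s]], prototype,
                                rois, ops, config, cache, refit_only = NULL,
                                warn_nonconv = FALSE)
        sig_by_spec[[s]] <- refined
        models[[s]] <- synthesize_spectrum(refined, axes, ops, eta, cache)
      }
    }
    rss_history <- c(rss_history,
                     sum(vapply(seq_len(n_spec),
                                function(s) sum(resid_of(s)[union_mask]^2),
                                numeric(1))))
    if (verbose)
      message(sprintf("iteration %d: threshold %.4g, %d signals, rss %.6g",
                      iterations, thr,
                      sum(vapply(sig_by_spec, nrow, integer(1))),
                      rss_history[iterations]))
    thr_geo <- thr_geo / config$threshold_decay
    if (iterations >= config$max_iterations) break
    if (at_floor && !new_any) {
      # re-examine the polished residual; terminate only if nothing is left
      still <- any(vapply(seq_len(n_spec), function(s)
        nrow(pick_candidates(spectrum_grid(resid_of(s), axes$C, axes$H),
                             if (config$model_only_in_rois) rois else NULL,
                             floor_thr)) > 0, logical(1)))
      if (!still) break
    }
  }
  signals <- do.call(rbind, lapply(sig_by_spec, as.data.frame))
  class(signals) <- c("signal_table", "data.frame")
  rownames(signals) <- NULL
  signals$sample_id <- vapply(ensemble, `[[`, "", "sample_id")[signals$spectrum_index]
  residual <- nmr_ensemble(lapply(seq_len(n_spec), function(s)
    spectrum_grid(resid_of(s), axes$C, axes$H,
                  sample_id = ensemble[[s]]$sample_id,
                  group_label = ensemble[[s]]$group_label)))
  structure(list(signals = signals, residual = residual, noise_sd = noise_sd,
                 iterations_run = iterations,
                 n_parameters = n_parameters(signals),
                 threshold_final = thr_geo, rss_history = rss_history,
                 config = config, prototype = prototype),
            class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf(paste0("<deconvolution_result: %d signals (%d parameters), ",
                     "%d iterations, noise SD %.4g>\n"),
              nrow(x$signals), x$n_parameters, x$iterations_run, x$noise_sd))
  invisible(x)
}
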