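test_that("noise estimation is robust and handles degenerate ensembles", {
  axes <- default_axes(256L, 256L, 512L, 512L)
  zero <- nmr_ensemble(list(spectrum_grid(matrix(0, 512, 512),
                                          axes$C, axes$H)))
  expect_identical(estimate_noise_sd(zero), 0)
  set.seed(31)
  M <- matrix(rnorm(512 * 512), 512, 512)
  ens <- nmr_ensemble(list(spectrum_grid(M, axes$C, axes$H)))
  expect_equal(estimate_noise_sd(ens), 1, tolerance = 0.02)
  # a huge signal (100x the noise SD, 25x the pick floor) fully inside an
  # ROI leaves the outside-ROI estimate alone
  roi <- one_roi("big", 6.8, 7.4, 108, 120)
  ops <- default_ops(axes)
  u <- fmlr2d:::unit_peak_height(7.1, 114, 80, 80, axes, ops,
                                 c(H = 1, C = 1), NULL)
  sig <- signal_table(amplitude = 100 / u, ppm_H = 7.1, ppm_C = 114,
                      fwhm_H = 80, fwhm_C = 80)
  M2 <- M + synthesize_spectrum(sig, axes, ops)
  ens2 <- nmr_ensemble(list(spectrum_grid(M2, axes$C, axes$H)))
  e0 <- estimate_noise_sd(ens, roi)
  e1 <- estimate_noise_sd(ens2, roi)
  expect_equal(e1, e0, tolerance = 0.03)
  # ROIs tiling the full grid: fallback off must error
  all_roi <- one_roi("all", -100, 100, -500, 500)
  expect_error(estimate_noise_sd(ens, all_roi, fallback = FALSE), "outside")
})

test_that("prototype fitting recovers the archetypal linewidths", {
  axes <- default_axes(); ops <- default_ops(axes)
  sig <- signal_table(amplitude = 50, ppm_H = 6.7, ppm_C = 104,
                      fwhm_H = 80, fwhm_C = 80)
  clean <- synthesize_spectrum(sig, axes, ops)
  win <- c(6.45, 6.95, 102, 106)
  for (snr in c(100, 10)) {
    set.seed(snr)
    noise_sd <- max(clean) / snr
    # iid measurement noise on the grid
    M <- clean + matrix(rnorm(length(clean), 0, noise_sd), nrow(clean))
    proto <- fit_prototype(spectrum_grid(M, axes$C, axes$H), win, ops,
                           noise_sd = noise_sd)
    tol <- if (snr == 100) 0.05 else 0.10
    expect_equal(proto$linewidth_H, 80, tolerance = tol)
    expect_equal(proto$linewidth_C, 80, tolerance = tol)
  }
  # empty window: nothing above the pick floor
  empty <- spectrum_grid(matrix(0, axes$C$n_freq, axes$H$n_freq),
                         axes$C, axes$H)
  expect_error(fit_prototype(empty, win, ops, noise_sd = 1), "no peak")
})

test_that("candidate picking respects ROIs, thresholds and tie-breaks", {
  axes <- tiny_axes(); ops <- default_ops(axes)
  zero <- spectrum_grid(matrix(0, axes$C$n_freq, axes$H$n_freq),
                        axes$C, axes$H)
  rois <- one_roi("a", 6.5, 7.0, 102, 112)
  expect_identical(nrow(pick_candidates(zero, rois, 1)), 0L)
  # one peak inside the ROI, one outside, both above threshold
  sig <- signal_table(amplitude = c(10, 10), ppm_H = c(6.7, 7.6),
                      ppm_C = c(105, 125), fwhm_H = c(80, 80),
                      fwhm_C = c(80, 80))
  M <- synthesize_spectrum(sig, axes, ops)
  cand <- pick_candidates(spectrum_grid(M, axes$C, axes$H), rois,
                          0.5 * max(M))
  expect_identical(nrow(cand), 1L)
  expect_true(cand$ppm_H < 7.0)
  # threshold filter: heights 10 and 6, threshold 7 keeps only the tall one
  sig2 <- signal_table(amplitude = c(10, 6), ppm_H = c(6.6, 6.9),
                       ppm_C = c(104, 110), fwhm_H = c(80, 80),
                       fwhm_C = c(80, 80))
  u <- fmlr2d:::unit_peak_height(6.6, 104, 80, 80, axes, ops,
                                 c(H = 1, C = 1), NULL)
  M2 <- synthesize_spectrum(sig2, axes, ops)
  cand2 <- pick_candidates(spectrum_grid(M2, axes$C, axes$H), rois, 7 * u)
  expect_identical(nrow(cand2), 1L)
  expect_equal(cand2$ppm_H, 6.6, tolerance = 0.03)
  expect_error(pick_candidates(zero, rois, 0), "threshold")
})

test_that("refinement is a fixed point at the optimum and honors the box", {
  axes <- tiny_axes(); ops <- default_ops(axes)
  rois <- one_roi("a", 6.4, 7.0, 100, 110)
  sig <- signal_table(amplitude = 20, ppm_H = 6.7, ppm_C = 105,
                      fwhm_H = 90, fwhm_C = 70)
  data <- spectrum_grid(synthesize_spectrum(sig, axes, ops), axes$C, axes$H)
  out <- refine_model(data, sig, prototype_config(80, 80), rois, ops)
  expect_equal(out$amplitude, sig$amplitude, tolerance = 1e-8)
  expect_equal(out$ppm_H, sig$ppm_H, tolerance = 1e-8)
  expect_equal(out$fwhm_C, sig$fwhm_C, tolerance = 1e-8)
  # a 200 Hz true linewidth pins at the 160 Hz ceiling
  wide <- signal_table(amplitude = 20, ppm_H = 6.7, ppm_C = 105,
                       fwhm_H = 200, fwhm_C = 80)
  data2 <- spectrum_grid(synthesize_spectrum(wide, axes, ops), axes$C, axes$H)
  init <- wide; init$fwhm_H <- 80
  out2 <- refine_model(data2, init, prototype_config(80, 80), rois, ops)
  expect_equal(out2$fwhm_H, 160)
})

test_that("two overlapped signals at 0.7 linewidth separation are resolved", {
  axes <- default_axes(); ops <- default_ops(axes)
  rois <- one_roi("a", 6.4, 7.1, 100, 110)
  sep_ppm <- 0.7 * 80 / axes$H$sfrq
  truth <- signal_table(amplitude = c(30, 22),
                        ppm_H = c(6.70, 6.70 + sep_ppm),
                        ppm_C = c(105, 105), fwhm_H = c(80, 80),
                        fwhm_C = c(80, 80))
  clean <- synthesize_spectrum(truth, axes, ops)
  set.seed(11)
  # iid Gaussian measurement noise at SNR 50 on the peak height
  M <- clean + matrix(rnorm(length(clean), 0, max(clean) / 50),
                      nrow(clean))
  init <- truth
  init$amplitude <- init$amplitude * c(1.3, 0.6)
  init$ppm_H <- init$ppm_H + c(0.004, -0.004)
  out <- refine_model(spectrum_grid(M, axes$C, axes$H), init,
                      prototype_config(80, 80), rois, ops)
  expect_equal(out$amplitude, truth$amplitude, tolerance = 0.05)
  expect_lt(max(abs(out$ppm_H - truth$ppm_H)) * axes$H$sfrq / 80, 0.1)
})

test_that("noise-free ensembles deconvolve to the exact generating model", {
  fx <- tiny_truth_ensemble()
  rois <- rbind_rois(one_roi("r1", 6.5, 6.9, 102, 106),
                     one_roi("r2", 6.8, 7.15, 109, 113),
                     one_roi("r3", 7.0, 7.4, 126, 130))
  dec <- deconvolve_ensemble(fx$ensemble, rois, prototype_config(80, 80),
                             fx$ops)
  expect_identical(nrow(dec$signals), 6L)
  expect_identical(dec$n_parameters, 30L)
  um <- fmlr2d:::roi_union_mask(rois, fx$axes$C, fx$axes$H)
  tallest <- max(fx$ensemble[[1]]$intensities)
  resid <- max(vapply(dec$residual,
                      function(sp) max(abs(sp$intensities[um])), numeric(1)))
  expect_lt(resid, 1e-6 * tallest)
})

test_that("deconvolution is deterministic and keeps its bookkeeping invariants", {
  set.seed(5)
  sim <- simulate_ensemble(list(sim_group("g", 2, c(S = 40, G = 40, H = 20))),
                           snr = 15, seed = 5)
  rois <- bundled_roi_template()
  ops <- default_ops(default_axes())
  d1 <- deconvolve_ensemble(sim$ensemble, rois, prototype_config(80, 80), ops)
  d2 <- deconvolve_ensemble(sim$ensemble, rois, prototype_config(80, 80), ops)
  expect_identical(d1$signals, d2$signals)
  expect_identical(d1$n_parameters, 5L * nrow(d1$signals))
  expect_lte(d1$iterations_run, d1$config$max_iterations)
  # monotone improvement of the ROI-restricted squared residual
  expect_true(all(diff(d1$rss_history) <= 1e-8 * d1$rss_history[1]))
  # every fitted linewidth inside the box
  lw <- linewidth_bounds(d1$prototype)
  expect_true(all(d1$signals$fwhm_H >= lw$H[1] & d1$signals$fwhm_H <= lw$H[2]))
  expect_true(all(d1$signals$fwhm_C >= lw$C[1] & d1$signals$fwhm_C <= lw$C[2]))
  # threshold-based stop implies the schedule fell below the floor
  if (d1$iterations_run < d1$config$max_iterations)
    expect_lt(d1$threshold_final, d1$config$snr_stop * d1$noise_sd)
})

test_that("configuration guards reject invalid settings", {
  expect_error(deconvolution_config(snr_stop = 0), "snr_stop")
  expect_error(deconvolution_config(threshold_decay = 1), "threshold_decay")
  expect_error(deconvolution_config(max_iterations = 0), "max_iterations")
  expect_error(prototype_config(80, 80, low_factor = 1.5), "low_factor")
})
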