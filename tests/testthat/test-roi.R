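test_that("ROI tables round-trip through CSV and validate their bounds", {
  rois <- rbind_rois(one_roi("a", 6.5000, 7.0000, 102.0000, 112.0000,
                             role = "S", label = "S2/6"),
                     one_roi("b", 7.1000, 7.4000, 120.0000, 125.0000))
  path <- withr::local_tempfile(fileext = ".csv")
  save_roi_table(rois, path)
  back <- load_roi_table(path)
  expect_equal(as.data.frame(back), as.data.frame(rois))
  # invariant violations name the offender
  bad <- data.frame(roi_id = "bad1", label = "", role = "other",
                    h_min_ppm = 7.5, h_max_ppm = 7.0,
                    c_min_ppm = 100, c_max_ppm = 110)
  expect_error(roi_table(bad), "bad1")
  dup <- as.data.frame(rbind_rois(one_roi("x", 1, 2, 3, 4),
                                  one_roi("y", 1, 2, 3, 4)))
  dup$roi_id <- "x"
  expect_error(roi_table(dup), "duplicated")
  expect_error(roi_table(transform(as.data.frame(rois), role = "Z")), "role")
  # constant ppm offset on load
  shifted <- load_roi_table(path, h_offset = 0.02)
  expect_equal(shifted$h_min_ppm, rois$h_min_ppm + 0.02)
  expect_equal(shifted$c_min_ppm, rois$c_min_ppm)
})

test_that("containment uses closed intervals in table order", {
  rois <- rbind_rois(one_roi("a", 6.0, 7.0, 100, 110),
                     one_roi("b", 7.0, 8.0, 100, 110),
                     one_roi("c", 5.0, 5.5, 90, 95))
  expect_identical(containing_rois(6.5, 105, rois), "a")
  # a point on the shared boundary belongs to both boxes
  expect_identical(containing_rois(7.0, 105, rois), c("a", "b"))
  expect_identical(containing_rois(4.0, 80, rois), character(0))
})

test_that("gravity assignment follows the metric, ties and fallback rules", {
  rois <- rbind_rois(one_roi("A", 6.0, 7.0, 100, 110),
                     one_roi("B", 6.5, 7.5, 105, 115))
  scale <- gravity_scale(rois)
  src <- data.frame(amplitude = 5, ppm_H = 6.75, ppm_C = 107)
  # peers only in A
  peers <- data.frame(amplitude = c(2, 3), ppm_H = c(6.2, 6.3),
                      ppm_C = c(102, 103), roi_id = c("A", "A"))
  expect_identical(gravity_assign(src, c("A", "B"), peers, rois, scale), "A")
  # exactly symmetric construction (offsets representable in binary):
  # tie resolves to the first candidate in table order
  peers2 <- data.frame(amplitude = c(2, 2), ppm_H = c(6.5, 7.0),
                       ppm_C = c(107, 107), roi_id = c("A", "B"))
  expect_identical(gravity_assign(src, c("A", "B"), peers2, rois, scale), "A")
  expect_identical(gravity_assign(src, c("B", "A"), peers2, rois, scale), "B")
  # no peers anywhere: nearest-centre fallback with a warning
  expect_warning(
    win <- gravity_assign(src, c("A", "B"), peers2[0, ], rois, scale),
    "fallback|nearest")
  expect_identical(win, "A")   # A's centre is nearer in scaled ppm distance
  expect_error(gravity_assign(src, "A", peers, rois, scale), "candidates")
})

test_that("gravity metric equals its brute-force recomputation on random cases", {
  set.seed(77)
  rois <- rbind_rois(one_roi("A", 6.0, 7.0, 100, 110),
                     one_roi("B", 6.5, 7.5, 105, 115),
                     one_roi("C", 6.4, 7.2, 103, 112))
  scale <- gravity_scale(rois)
  for (k in 1:200) {
    src <- data.frame(amplitude = runif(1, 0.5, 10),
                      ppm_H = runif(1, 6.5, 7.0), ppm_C = runif(1, 105, 110))
    n <- sample(3:12, 1)
    peers <- data.frame(amplitude = runif(n, 0.1, 10),
                        ppm_H = runif(n, 6.0, 7.5),
                        ppm_C = runif(n, 100, 115),
                        roi_id = sample(c("A", "B", "C"), n, replace = TRUE))
    g <- vapply(c("A", "B", "C"), function(id)
      brute_gravity(src, id, peers, scale), numeric(1))
    want <- c("A", "B", "C")[which.max(g)]
    expect_identical(gravity_assign(src, c("A", "B", "C"), peers, rois, scale),
                     want)
  }
})

test_that("two-pass assignment is stable under ROI enlargement", {
  rois <- rbind_rois(one_roi("A", 6.0, 7.0, 100, 110),
                     one_roi("B", 7.2, 7.8, 112, 118))
  sig <- signal_table(amplitude = c(4, 6), ppm_H = c(6.5, 7.5),
                      ppm_C = c(105, 115), fwhm_H = c(80, 80),
                      fwhm_C = c(80, 80))
  a1 <- assign_signals(sig, rois)
  expect_identical(a1$roi_id, c("A", "B"))
  # enlarging A so it still contains signal 1 must not change assignments
  big <- as.data.frame(rois); big$h_max_ppm[1] <- 7.1; big$c_max_ppm[1] <- 111
  a2 <- assign_signals(sig, roi_table(big))
  expect_identical(a2$roi_id, a1$roi_id)
})

test_that("feature matrices sum assigned amplitudes and conserve the total", {
  rois <- rbind_rois(one_roi("A", 6.0, 7.0, 100, 110),
                     one_roi("B", 7.2, 7.8, 112, 118))
  empty <- build_feature_matrix(signal_table(), rois, c("s1", "s2"))
  expect_equal(unname(empty$values), matrix(0, 2, 2))
  sig <- signal_table(amplitude = c(1, 2, 4), ppm_H = rep(6.5, 3),
                      ppm_C = rep(105, 3), fwhm_H = rep(80, 3),
                      fwhm_C = rep(80, 3), roi_id = rep("A", 3))
  fm <- build_feature_matrix(sig, rois, "s1")
  expect_identical(fm$values["A", "s1"], 7)
  # conservation on random fixtures, including unassigned signals
  set.seed(12)
  for (k in 1:20) {
    n <- sample(5:25, 1)
    sig <- signal_table(amplitude = runif(n, 0, 10),
                        ppm_H = runif(n, 5.5, 8),
                        ppm_C = runif(n, 95, 125),
                        fwhm_H = rep(80, n), fwhm_C = rep(80, n),
                        spectrum_index = sample(1:3, n, replace = TRUE))
    sig <- assign_signals(sig, rois)
    fm <- build_feature_matrix(sig, rois, paste0("s", 1:3))
    expect_equal(sum(fm$values) + fm$unassigned$amplitude,
                 sum(sig$amplitude))
  }
})

test_that("direct ROI integration sums grid intensities", {
  axes <- tiny_axes()
  ones <- nmr_ensemble(list(spectrum_grid(
    matrix(1, axes$C$n_freq, axes$H$n_freq), axes$C, axes$H)))
  roi <- one_roi("u", 6.5, 6.8, 104, 108)
  k <- sum(fmlr2d:::roi_mask_one(roi[1, ], axes$C, axes$H))
  fm <- integrate_rois(ones, roi)
  expect_identical(unname(fm$values[1, 1]), as.numeric(k))
  off <- one_roi("off", 20, 21, 300, 301)
  expect_error(integrate_rois(ones, off), "off")
})

test_that("integration of a contained peak matches amplitude times basis mass", {
  axes <- default_axes(); ops <- default_ops(axes)
  sig <- signal_table(amplitude = 12, ppm_H = 6.7, ppm_C = 104,
                      fwhm_H = 80, fwhm_C = 80)
  M <- synthesize_spectrum(sig, axes, ops)
  ens <- nmr_ensemble(list(spectrum_grid(M, axes$C, axes$H)))
  roi <- one_roi("wide", 6.2, 7.2, 98.6, 110)
  fm <- integrate_rois(ens, roi)
  # closed form: the integral is the amplitude times the basis-plane mass
  # over the box (separable outer product)
  b <- fmlr2d:::signal_bases(sig[1, ], axes, ops, c(H = 1, C = 1), NULL)
  ph <- ppm_axis(axes$H); pc <- ppm_axis(axes$C)
  mass <- 12 * sum(b$bC[pc >= 98.6 & pc <= 110]) *
    sum(b$bH[ph >= 6.2 & ph <= 7.2])
  expect_equal(unname(fm$values[1, 1]), mass, tolerance = 0.01)
})
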