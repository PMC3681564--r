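test_that("total-intensity normalization is idempotent and scale-invariant", {
  axes <- tiny_axes()
  M <- matrix(2, axes$C$n_freq, axes$H$n_freq)
  sp <- normalize_spectrum_total(spectrum_grid(M, axes$C, axes$H))
  expect_equal(sum(sp$intensities[sp$intensities > 0]), 1)
  sp2 <- normalize_spectrum_total(sp)
  expect_equal(sp2$intensities, sp$intensities, tolerance = 1e-15)
  # two spectra differing by a 10x concentration factor coincide afterwards
  set.seed(2)
  n <- axes$C$n_freq * axes$H$n_freq
  A <- matrix(rnorm(n, mean = 3), axes$C$n_freq, axes$H$n_freq)
  a <- normalize_spectrum_total(spectrum_grid(A, axes$C, axes$H))
  b <- normalize_spectrum_total(spectrum_grid(10 * A, axes$C, axes$H))
  expect_equal(a$intensities, b$intensities, tolerance = 1e-12)
  expect_error(normalize_spectrum_total(spectrum_grid(
    matrix(-1, axes$C$n_freq, axes$H$n_freq), axes$C, axes$H)),
    "non-positive")
})

test_that("lignin content applies the 1,1,2,2,1 role weights", {
  roles <- c("S", "S'", "G", "G'", "H")
  fm <- fm_from_values(matrix(1, 5, 1), roles = roles)
  expect_equal(unname(lignin_content(fm)), 7)
  vals <- matrix(0, 5, 1); vals[3, 1] <- 3   # only G2 = 3
  expect_equal(unname(lignin_content(fm_from_values(vals, roles))), 6)
  # random amplitudes against a spreadsheet-style recomputation
  set.seed(8)
  v <- matrix(runif(15, 0.1, 5), 5, 3)
  fm3 <- fm_from_values(v, roles)
  expect_equal(unname(lignin_content(fm3)),
               v[1, ] + v[2, ] + 2 * v[3, ] + 2 * v[4, ] + v[5, ])
  # missing role is named
  expect_error(lignin_content(fm_from_values(matrix(1, 4, 1),
                                             roles = c("S", "S'", "G", "G'"))),
               "H")
})

test_that("SGH percentages follow the weights and always sum to 100", {
  roles <- c("S", "S'", "G", "G'", "H")
  sgh <- sgh_percentages(fm_from_values(matrix(1, 5, 1), roles))
  expect_equal(sgh$pct_S, 200 / 7)
  expect_equal(sgh$pct_G, 400 / 7)
  expect_equal(sgh$pct_H, 100 / 7)
  vals <- matrix(c(2, 1, 1.5, 0.5, 0), 5, 1)   # H absent
  sgh0 <- sgh_percentages(fm_from_values(vals, roles))
  expect_equal(sgh0$pct_H, 0)
  expect_equal(sgh0$pct_S + sgh0$pct_G, 100)
  set.seed(3)
  v <- matrix(runif(25, 0.05, 4), 5, 5)
  s <- sgh_percentages(fm_from_values(v, roles))
  expect_equal(s$pct_S + s$pct_G + s$pct_H, rep(100, 5), tolerance = 1e-9)
})

test_that("lignin normalization divides by L and is scale invariant", {
  roles <- c("S", "S'", "G", "G'", "H", "other")
  set.seed(4)
  v <- matrix(runif(18, 0.5, 4), 6, 3)
  fm <- fm_from_values(v, roles)
  L <- lignin_content(fm)
  nf <- normalize_features_by_lignin(fm)
  expect_equal(nf$values, sweep(v, 2, L, "/"), ignore_attr = TRUE)
  expect_identical(nf$normalization, "lignin_normalized")
  # rescaling one spectrum's amplitudes leaves its normalized column alone
  v2 <- v; v2[, 2] <- 3.7 * v2[, 2]
  nf2 <- normalize_features_by_lignin(fm_from_values(v2, roles))
  expect_equal(nf2$values[, 2], nf$values[, 2], tolerance = 1e-12)
})

test_that("internal-standard normalization divides by the standard row", {
  v <- matrix(c(4, 2, 6, 2, 8, 4), 2, 3)   # row 2 is the standard
  fm <- fm_from_values(v, ids = c("x", "std"))
  nf <- normalize_by_internal_standard(fm, "std")
  expect_equal(unname(nf$values["x", ]), c(2, 3, 2))
  expect_equal(unname(nf$values["std", ]), c(1, 1, 1))
  # renormalizing by the now-unit standard changes nothing
  nf2 <- normalize_by_internal_standard(nf, "std")
  expect_equal(nf2$values, nf$values)
  v0 <- v; v0[2, 2] <- 0
  expect_error(normalize_by_internal_standard(fm_from_values(v0, ids = c("x", "std")),
                                              "std"), "s2")
})

test_that("Dunnett comparisons handle the degenerate all-equal case", {
  fm <- fm_from_values(matrix(3, 1, 9), groups = rep(c("ref", "a", "b"), each = 3))
  dd <- dunnett_many_to_one(fm, "ref")
  expect_equal(dd$delta, c(0, 0))
  expect_equal(dd$p_adj, c(1, 1))
  expect_true(all(dd$ci_low <= dd$delta & dd$delta <= dd$ci_high))
  # differing means with zero within-group variance has no error scale
  fm2 <- fm_from_values(matrix(rep(c(1, 2, 3), each = 3), 1),
                        groups = rep(c("ref", "a", "b"), each = 3))
  expect_error(dunnett_many_to_one(fm2, "ref"), "variance")
})

test_that("a single Dunnett comparison reduces to the pooled t-test", {
  set.seed(5)
  y <- rnorm(10)
  g <- rep(c("ref", "t"), each = 5)
  dd <- dunnett_many_to_one(fm_from_values(matrix(y, 1), groups = g), "ref",
                            n_draws = 4e5)
  tt <- stats::t.test(y[g == "t"], y[g == "ref"], var.equal = TRUE)
  expect_lt(abs(dd$p_adj - tt$p.value), 5e-3)   # Monte Carlo error scale
  expect_equal(dd$delta, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
})

test_that("Dunnett adjustment agrees with the multcomp reference and is monotone", {
  skip_if_not_installed("multcomp")
  set.seed(21)
  g <- factor(rep(c("ref", "a", "b", "c"), each = 5),
              levels = c("ref", "a", "b", "c"))
  y <- rnorm(20) + rep(c(0, 0.5, 1, 0), each = 5)
  dd <- dunnett_many_to_one(fm_from_values(matrix(y, 1), groups = as.character(g)),
                            "ref", n_draws = 2e5)
  fit <- stats::aov(y ~ g)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
  sm <- summary(gl)
  ci <- stats::confint(gl)$confint
  ord <- match(dd$group, sub("(.*) - ref", "\\1", rownames(ci)))
  expect_equal(dd$delta, as.numeric(sm$test$coefficients)[ord], tolerance = 1e-10)
  expect_lt(max(abs(dd$p_adj - as.numeric(sm$test$pvalues)[ord])), 0.01)
  expect_lt(max(abs(dd$ci_low - as.numeric(ci[ord, "lwr"]))), 0.03)
  expect_lt(max(abs(dd$ci_high - as.numeric(ci[ord, "upr"]))), 0.03)
  # adjusted p is never smaller than the per-comparison t-test p
  for (i in seq_len(nrow(dd))) {
    tt <- stats::t.test(y[g == dd$group[i]], y[g == "ref"], var.equal = TRUE)
    expect_gte(dd$p_adj[i] + 5e-3, tt$p.value)
  }
})

test_that("Pearson correlation screen matches the textbook formula", {
  set.seed(6)
  v <- matrix(rnorm(40), 4, 10)
  v[4, ] <- -v[1, ] + rnorm(10, sd = 1e-3)   # engineered anti-correlation
  fm <- fm_from_values(v)
  out <- pearson_correlations(fm, c("r1", "r2"))
  expect_equal(out$r[out$roi_a == "r1" & out$roi_b == "r1"], 1)
  expect_lt(out$r[out$roi_a == "r4" & out$roi_b == "r1"], -0.99)
  for (i in seq_len(nrow(out))) {
    x <- v[match(out$roi_a[i], fm$roi_ids), ]
    y <- v[match(out$roi_b[i], fm$roi_ids), ]
    r_manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(out$r[i], r_manual, tolerance = 1e-12)
  }
  # zero-variance rows are reported as missing, not as errors
  v0 <- v; v0[2, ] <- 5
  out0 <- pearson_correlations(fm_from_values(v0), "r1")
  expect_true(is.na(out0$r[out0$roi_a == "r2"]))
  expect_match(out0$note[out0$roi_a == "r2"], "variance")
})
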