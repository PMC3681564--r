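#' Total-intensity spectrum normalization
#'
#' Divides every intensity point by the sum of the spectrum's positive
#' intensity points, removing concentration-driven scale differences between
#' samples so one intensity threshold can serve the whole ensemble. After
#' normalization the positive-point sum is exactly 1; the map is idempotent.
#'
#' @param spectrum a [spectrum_grid()].
#' @return the normalized [spectrum_grid()].
#' @export
normalize_spectrum_total <- function(spectrum) {
  s <- sum(spectrum$intensities[spectrum$intensities > 0])
  if (!is.finite(s) || s <= 0)
    stop("spectrum has non-positive total intensity; cannot normalize")
  spectrum$intensities <- spectrum$intensities / s
  spectrum
}

#' @rdname normalize_spectrum_total
#' @param ensemble an [nmr_ensemble()].
#' @export
normalize_ensemble_total <- function(ensemble)
  nmr_ensemble(lapply(ensemble, normalize_spectrum_total))

# sum feature rows by lignin role; returns role x spectrum matrix
role_amplitudes <- function(fm, roles = c("S", "S'", "G", "G'", "H")) {
  out <- matrix(0, length(roles), ncol(fm$values),
                dimnames = list(roles, fm$sample_ids))
  for (r in roles) {
    idx <- which(fm$roles == r)
    if (length(idx))
      out[r, ] <- colSums(fm$values[idx, , drop = FALSE])
  }
  out
}

#' Lignin content of each spectrum
#'
#' The per-spectrum normalizer `L` is the weighted sum of the aromatic
#' lignin ROI amplitudes,
#' `L = [S2/6] + [S'2/6] + 2[G2] + 2[G'2] + [H2/6]`,
#' where the weights reflect the number of proton/carbon pairs contributing
#' to each spectral region (S and H aromatic rings contribute two
#' equivalent C-H pairs to their 2/6 cross peak, the G ring one C2-H pair,
#' hence the factor 2 on the G terms). Roles with several ROIs are summed
#' before weighting.
#'
#' @param fm a [feature_matrix()] whose `roles` include at least one ROI for
#'   each of S, S', G, G', H.
#' @return named numeric vector of `L` values, one per spectrum.
#' @export
lignin_content <- function(fm) {
  roles <- c("S", "S'", "G", "G'", "H")
  missing_roles <- roles[!roles %in% fm$roles]
  if (length(missing_roles))
    stop("no ROI carries role(s): ", paste(missing_roles, collapse = ", "))
  a <- role_amplitudes(fm, roles)
  L <- a["S", ] + a["S'", ] + 2 * a["G", ] + 2 * a["G'", ] + a["H", ]
  bad <- !is.finite(L) | L <= 0
  if (any(bad))
    stop("non-positive lignin content for sample(s): ",
         paste(fm$sample_ids[bad], collapse = ", "))
  L
}

#' S:G:H lignin composition
#'
#' Percentage composition implied by the lignin-content weights:
#' `%S = 100 ([S2/6] + [S'2/6]) / L`, `%G = 100 (2[G2] + 2[G'2]) / L`,
#' `%H = 100 [H2/6] / L`. The three percentages sum to 100 by construction.
#'
#' @param fm a [feature_matrix()] (raw amplitudes).
#' @return data frame with `sample_id`, `group`, `L`, `pct_S`, `pct_G`,
#'   `pct_H`.
#' @export
sgh_percentages <- function(fm) {
  L <- lignin_content(fm)
  a <- role_amplitudes(fm)
  data.frame(sample_id = fm$sample_ids, group = fm$group_labels,
             L = as.numeric(L),
             pct_S = as.numeric(100 * (a["S", ] + a["S'", ]) / L),
             pct_G = as.numeric(100 * 2 * (a["G", ] + a["G'", ]) / L),
             pct_H = as.numeric(100 * a["H", ] / L),
             stringsAsFactors = FALSE)
}

#' Normalize a feature matrix by lignin content
#'
#' Divides each spectrum's column by its `L`, expressing every ROI amplitude
#' as a fraction of lignin content. Rescaling all amplitudes of one spectrum
#' by a positive constant leaves its normalized column unchanged.
#'
#' @param fm a raw [feature_matrix()].
#' @return the normalized [feature_matrix()].
#' @export
normalize_features_by_lignin <- function(fm) {
  L <- lignin_content(fm)
  fm$values <- sweep(fm$values, 2, L, "/")
  fm$normalization <- "lignin_normalized"
  fm
}

#' Normalize a feature matrix by an internal-standard ROI
#'
#' For ensembles with a fixed-concentration internal standard (e.g. DSS or
#' formate), each column is divided by the standard ROI's amplitude in that
#' spectrum.
#'
#' @param fm a [feature_matrix()].
#' @param standard_roi_id roi_id of the internal-standard ROI.
#' @return the normalized [feature_matrix()].
#' @export
normalize_by_internal_standard <- function(fm, standard_roi_id) {
  i <- match(standard_roi_id, fm$roi_ids)
  if (is.na(i)) stop("internal standard ROI not present: ", standard_roi_id)
  std <- fm$values[i, ]
  bad <- !is.finite(std) | std <= 0
  if (any(bad))
    stop("internal standard amplitude non-positive in sample(s): ",
         paste(fm$sample_ids[bad], collapse = ", "))
  fm$values <- sweep(fm$values, 2, std, "/")
  fm$normalization <- "internal_standard"
  fm
}

#' Many-to-one Dunnett comparisons of ROI amplitudes
#'
#' For every ROI row, fits a one-way ANOVA of amplitude on group (pooled
#' within-group variance) and compares each group with the reference using
#' the Dunnett many-to-one adjustment. The joint distribution of the
#' comparison statistics is the multivariate t with the design's
#' correlation matrix; adjusted p-values and simultaneous `1 - alpha`
#' confidence intervals are evaluated by seeded Monte Carlo integration of
#' that distribution (`n_draws` samples of the maximal absolute statistic,
#' shared across all ROIs and comparisons of the call). With a single
#' comparison the adjustment reduces to the two-sided pooled t-test.
#'
#' If every observation of an ROI is identical the comparisons are
#' degenerate and reported as delta 0, CI [0, 0], adjusted p 1; if group
#' means differ but the pooled within-group variance is zero there is no
#' error scale and an error is raised.
#'
#' @param fm a [feature_matrix()] with group labels.
#' @param reference_group label of the reference (e.g. wild-type) group;
#'   needs >= 2 replicates.
#' @param alpha overall error level for the simultaneous intervals.
#' @param seed seed of the Monte Carlo integration, recorded so reported
#'   p-values and intervals are reproducible.
#' @param n_draws Monte Carlo sample size (>= 1e5 recommended).
#' @return data frame with one row per (ROI, non-reference group):
#'   `roi_id`, `label`, `group`, `delta`, `ci_low`, `ci_high`, `p_adj`,
#'   `n_ref`, `n_group`.
#' @export
dunnett_many_to_one <- function(fm, reference_group, alpha = 0.05, seed = 1L,
                                n_draws = 1e5) {
  g <- factor(fm$group_labels)
  if (!reference_group %in% levels(g))
    stop("reference group not present: ", reference_group)
  g <- stats::relevel(g, ref = reference_group)
  cnt <- table(g)
  if (cnt[[reference_group]] < 2)
    stop("reference group needs >= 2 replicates")
  if (nlevels(g) < 2) stop("need at least one non-reference group")
  others <- setdiff(levels(g), reference_group)
  n0 <- cnt[[reference_group]]
  ni <- as.numeric(cnt[others])
  df <- length(g) - nlevels(g)
  if (df < 1) stop("no residual degrees of freedom")
  # correlation of the comparison statistics: shared reference mean
  v <- 1 / ni + 1 / n0
  R <- outer(rep(1 / n0, length(ni)), rep(1, length(ni))) / sqrt(outer(v, v))
  diag(R) <- 1
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * length(ni)), n_draws) %*% chol(R)
  maxZ <- do.call(pmax, as.data.frame(abs(Z)))
  maxT <- maxZ / sqrt(stats::rchisq(n_draws, df) / df)
  qcrit <- as.numeric(stats::quantile(maxT, 1 - alpha, type = 8))
  out <- vector("list", nrow(fm$values))
  for (r in seq_len(nrow(fm$values))) {
    y <- fm$values[r, ]
    if (diff(range(y)) == 0) {
      out[[r]] <- data.frame(roi_id = fm$roi_ids[r], label = fm$labels[r],
                             group = others, delta = 0, ci_low = 0,
                             ci_high = 0, p_adj = 1,
                             n_ref = as.integer(n0),
                             n_group = as.integer(cnt[others]),
                             stringsAsFactors = FALSE)
      next
    }
    fit <- stats::aov(y ~ g, data = data.frame(y = y, g = g))
    s2 <- stats::deviance(fit) / df
    if (s2 <= 1e-12 * stats::var(y))
      stop("zero within-group variance with differing group means for ROI ",
           fm$roi_ids[r], "; no error scale for the comparisons")
    means <- tapply(y, g, mean)
    delta <- as.numeric(means[others] - means[[reference_group]])
    se <- sqrt(s2 * v)
    tstat <- delta / se
    p_adj <- vapply(abs(tstat), function(a) mean(maxT >= a), numeric(1))
    out[[r]] <- data.frame(roi_id = fm$roi_ids[r], label = fm$labels[r],
                           group = others, delta = delta,
                           ci_low = delta - qcrit * se,
                           ci_high = delta + qcrit * se,
                           p_adj = p_adj,
                           n_ref = as.integer(n0),
                           n_group = as.integer(cnt[others]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Dunnett comparisons of S:G:H composition
#'
#' Convenience wrapper: computes per-spectrum S, G and H percentages and
#' runs the many-to-one comparisons on each percentage.
#'
#' @inheritParams dunnett_many_to_one
#' @return data frame as [dunnett_many_to_one()], with `roi_id` in
#'   `pct_S`, `pct_G`, `pct_H`.
#' @export
dunnett_sgh <- function(fm, reference_group, alpha = 0.05, seed = 1L) {
  sgh <- sgh_percentages(fm)
  vals <- t(as.matrix(sgh[, c("pct_S", "pct_G", "pct_H")]))
  rois <- roi_table(data.frame(roi_id = c("pct_S", "pct_G", "pct_H"),
                               label = c("%S", "%G", "%H"), role = "other",
                               h_min_ppm = 0, h_max_ppm = 1,
                               c_min_ppm = 0, c_max_ppm = 1))
  pm <- feature_matrix(vals, rois, fm$sample_ids, fm$group_labels,
                       normalization = "internal_standard")
  dunnett_many_to_one(pm, reference_group, alpha, seed)
}

#' Pearson correlation of every ROI with anchor ROIs
#'
#' Sample Pearson correlation (and two-sided p-value) of each ROI amplitude
#' profile across spectra against each anchor ROI, the screen used to relate
#' unassigned regions to the lignin compounds.
#'
#' @param fm a [feature_matrix()] with >= 3 spectra.
#' @param anchor_roi_ids roi_ids of the anchors.
#' @return data frame `roi_a`, `roi_b`, `r`, `p`, `n`, `note` (`note`
#'   explains missing values for zero-variance rows).
#' @export
pearson_correlations <- function(fm, anchor_roi_ids) {
  n <- ncol(fm$values)
  if (n < 3) stop("need >= 3 spectra for correlation")
  miss <- setdiff(anchor_roi_ids, fm$roi_ids)
  if (length(miss)) stop("unknown anchor roi_id(s): ", paste(miss, collapse = ", "))
  rows <- list(); k <- 0L
  for (a in fm$roi_ids) {
    for (b in anchor_roi_ids) {
      x <- fm$values[a, ]; y <- fm$values[b, ]
      k <- k + 1L
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        rows[[k]] <- data.frame(roi_a = a, roi_b = b, r = NA_real_,
                                p = NA_real_, n = n,
                                note = "zero variance", stringsAsFactors = FALSE)
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        rows[[k]] <- data.frame(roi_a = a, roi_b = b,
                                r = unname(ct$estimate), p = ct$p.value,
                                n = n, note = "", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
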