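two_group_design <- function(n_per = 10) {
  sample_design(sprintf("s%02d", 1:(2 * n_per)),
                rep(c("DMSO", "BPA"), each = n_per),
                rep(c("control", "high"), each = n_per))
}

centered <- function(x) sweep(x, 2, colMeans(x))

test_that("PCA explains collinear data with one component and flags outliers", {
  t <- seq(-2, 2, length.out = 20)
  X <- centered(cbind(t, 2 * t, -t))
  p <- pca_screen(X, n_components = 1)
  expect_gt(p$explained_variance[1], 1 - 1e-12)

  set.seed(5)
  X2 <- matrix(stats::rnorm(30 * 8), 30, 8)
  X2[7, ] <- X2[7, ] + 10   # one sample displaced ~10 pooled SDs
  X2 <- centered(X2)
  p2 <- pca_screen(X2, n_components = 2, alpha = 0.05)
  expect_true(p2$outlier_flags[7])
  expect_equal(sum(p2$outlier_flags), 1)

  p3 <- pca_screen(X2, n_components = 2, alpha = 1.0)
  expect_true(all(p3$outlier_flags))
  expect_error(pca_screen(X2[1:2, ], 1), "n >= 3")
})

test_that("OSC removes a planted confounder and reconstructs the input", {
  d <- default_design()
  sp <- simulate_spectra(d, ten_bin_signatures(), n_bins = 150, noise_sd = 1,
                         confounder_sd = 12, seed = 21)
  planted_share <- attr(sp, "planted")$confounder_variance_share
  scaled <- scale_spectra(normalize_total_area(sp), "center_pareto")
  res <- osc_filter(scaled$intensities, d, n_osc = 1)

  y <- outer(d$group, sort(unique(d$group)), `==`) * 1
  y <- sweep(y, 2, colMeans(y))
  expect_lt(max(abs(stats::cor(res$removed_scores[, 1], y))), 1e-6)

  recon <- res$filtered_X + res$removed_scores %*% t(res$removed_loadings)
  expect_lt(max(abs(recon - scaled$intensities)), 1e-8)
  expect_lt(abs(res$variance_removed[1] - planted_share),
            0.2 * planted_share)
})

test_that("OSC without a confounder barely touches predictive ability", {
  d <- default_design()
  sp <- simulate_spectra(d, ten_bin_signatures(3), n_bins = 100,
                         noise_sd = 1, confounder_sd = 0, seed = 31)
  scaled <- scale_spectra(normalize_total_area(sp), "center_pareto")
  x0 <- scaled$intensities
  res <- osc_filter(x0, d, n_osc = 1)
  q2_raw <- cross_validated_q2(x0, d, A = 2, seed = 5)$q2_cumulative
  q2_osc <- cross_validated_q2(res$filtered_X, d, A = 2, seed = 5)$q2_cumulative
  expect_gt(q2_osc, q2_raw - 0.05)
  expect_error(osc_filter(x0, d, n_osc = 0), "n_osc")
})

test_that("a perfect class predictor gives R2Y = 1", {
  d <- two_group_design()
  y <- as.numeric(d$group == "BPA_high")
  yc <- y - mean(y)
  X <- cbind(yc, 2 * yc)
  fit <- fit_plsda(X, d, A = 1)
  expect_equal(fit$r2y, 1, tolerance = 1e-10)
})

test_that("PLS-DA is invariant to joint sample reordering and validates input", {
  d <- default_design()
  sp <- simulate_spectra(d, ten_bin_signatures(), n_bins = 60, seed = 13)
  x <- centered(sp$intensities)
  fit <- fit_plsda(x, d, A = 2)
  set.seed(2); perm <- sample(nrow(x))
  d2 <- d[perm, ]; class(d2) <- class(d)
  fit2 <- fit_plsda(x[perm, ], d2, A = 2)
  expect_equal(fit2$r2y, fit$r2y, tolerance = 1e-10)

  d_one <- d[d$group == "control", ]
  expect_error(fit_plsda(x[d$group == "control", ], d_one, A = 1), "groups")
  expect_error(fit_plsda(centered(matrix(stats::rnorm(20), 10, 2)),
                         two_group_design(5), A = 5), "rank|exceeds")
})

test_that("one-component weights align with the between-group mean difference", {
  d <- two_group_design(12)
  set.seed(77)
  X <- centered(matrix(stats::rnorm(24 * 30), 24, 30) +
                  outer(as.numeric(d$group == "BPA_high"), runif(30, 0, 2)))
  fit <- fit_plsda(X, d, A = 1)
  delta <- colMeans(X[d$group == "BPA_high", ]) -
    colMeans(X[d$group == "control", ])
  delta <- delta / sqrt(sum(delta^2))
  expect_lt(max(abs(abs(fit$W[, 1]) - abs(delta))), 1e-8)
})

test_that("scores are orthogonal, weights unit norm, R2Y in [0, 1]", {
  d <- default_design()
  sp <- simulate_spectra(d, ten_bin_signatures(), n_bins = 70, seed = 17)
  x <- centered(sp$intensities)
  fit <- fit_plsda(x, d, A = 3)
  expect_lt(max(abs(colSums(fit$W^2) - 1)), 1e-10)
  tcross <- crossprod(fit$T)
  off <- tcross - diag(diag(tcross))
  expect_lt(max(abs(off)) / max(diag(tcross)), 1e-8)
  expect_gte(fit$r2y, 0); expect_lte(fit$r2y, 1)
  expect_true(all(fit$ssy_explained >= 0))
  r2_prev <- fit_plsda(x, d, A = 1)$r2y
  expect_gte(fit$r2y, r2_prev - 1e-12)
})

test_that("Q2 never exceeds R2Y", {
  for (seed in 1:4) {
    d <- two_group_design(9)
    set.seed(seed)
    X <- centered(matrix(stats::rnorm(18 * 40), 18, 40))
    fit <- fit_plsda(X, d, A = 2)
    q2 <- cross_validated_q2(X, d, A = 2, seed = seed)$q2_cumulative
    expect_lte(q2, fit$r2y)
  }
})

test_that("strong signal meets the robustness rule, pure noise fails it", {
  d <- default_design()   # 17 controls + 3 x 12, as in the reference design
  sp <- simulate_spectra(d, dose_pattern_signatures(3), n_bins = 120,
                         noise_sd = 1, confounder_sd = 0, seed = 41)
  scaled <- scale_spectra(normalize_total_area(sp), "center_pareto")
  fit <- fit_plsda(scaled, d, A = 2)
  q2 <- cross_validated_q2(scaled, d, A = 2, seed = 41)$q2_cumulative
  expect_gt(fit$r2y, 0.5)
  expect_gt(q2, 0.4)

  set.seed(43)
  Xn <- centered(matrix(stats::rnorm(24 * 50), 24, 50))
  dn <- two_group_design(12)
  fitn <- fit_plsda(Xn, dn, A = 2)
  q2n <- cross_validated_q2(Xn, dn, A = 2, seed = 43)$q2_cumulative
  expect_gt(fitn$r2y, 0)      # overfit on training data
  expect_lte(q2n, 0.4)        # but no predictive ability
})

test_that("permutation p attains its floor for separated groups", {
  d <- two_group_design(10)
  set.seed(3)
  X <- centered(matrix(stats::rnorm(20 * 30), 20, 30) +
                  outer(as.numeric(d$group == "BPA_high"), rep(3, 30)))
  res <- permutation_test(X, d, A = 1, n_perm = 19, seed = 3)
  expect_length(res$permuted_q2, 19)
  expect_length(res$permuted_r2y, 19)
  expect_equal(res$empirical_p_q2, 1 / 20)
})

test_that("permutation p is calibrated under the null", {
  ok <- vapply(1:30, function(s) {
    set.seed(s)
    X <- centered(matrix(stats::rnorm(18 * 20), 18, 20))
    d <- two_group_design(9)
    permutation_test(X, d, A = 1, folds = 6, n_perm = 39,
                     seed = s)$empirical_p_q2 > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.85)
})

test_that("VIP matches its closed form and normalization", {
  d <- two_group_design(8)
  y <- as.numeric(d$group == "BPA_high"); yc <- y - mean(y)
  # weights proportional to (0.8, 0.6) by construction
  X <- cbind(0.8 * yc, 0.6 * yc)
  fit <- fit_plsda(X, d, A = 1)
  v <- vip_scores(fit)
  expect_equal(v$vip, sqrt(2) * c(0.8, 0.6), tolerance = 1e-8)

  Xe <- cbind(yc, yc, yc, yc)
  ve <- vip_scores(fit_plsda(Xe, d, A = 1))
  expect_equal(ve$vip, rep(1, 4), tolerance = 1e-10)

  sp <- simulate_spectra(default_design(), ten_bin_signatures(), n_bins = 50,
                         seed = 19)
  xs <- scale_spectra(normalize_total_area(sp), "center_pareto")
  vfull <- vip_scores(fit_plsda(xs, default_design(), A = 2))
  expect_equal(sum(vfull$vip^2), 50, tolerance = 1e-8)
})

test_that("Kruskal-Wallis matches the hand-computed example", {
  d <- sample_design(sprintf("s%d", 1:6), rep(c("DMSO", "T"), each = 3),
                     rep(c("control", "high"), each = 3))
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), d)
  expect_equal(res$H, 27 / 7, tolerance = 1e-10)
  expect_equal(res$p, stats::pchisq(27 / 7, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(kruskal_wallis(rep(2, 6), d), list(H = 0, p = 1))
  res2 <- kruskal_wallis(10 * c(1, 2, 3, 4, 5, 6), d)
  expect_equal(res2$H, res$H)
})

test_that("controls separate from exposed groups along component 1", {
  d <- default_design()
  sig <- lapply(1:8, function(i)
    signature_spec(paste0("M", i), 0.6 + i, c(control = 0, "BPA_1e-6M" = 3,
                                              "BPA_1e-9M" = 2,
                                              "BPA_1e-12M" = 1.2),
                   direction = if (i %% 2) 1 else -1))
  sp <- simulate_spectra(d, sig, n_bins = 120, seed = 29)
  scaled <- scale_spectra(normalize_total_area(sp), "center_pareto")
  fit <- fit_plsda(scaled, d, A = 2)
  sil <- silhouette_1d(fit$T[, 1], d$group == "control")
  expect_gt(sil, 0)
})
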