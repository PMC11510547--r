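test_that("generators are deterministic given a seed and record it", {
  d <- full_factorial_design(factorial_factors, TRUE, TRUE)
  tr <- example_truth("quality", seed = 33)
  a1 <- simulate_areas(d, tr)
  a2 <- simulate_areas(d, tr)
  expect_identical(a1, a2)
  expect_equal(attr(a1, "ground_truth")$seed_used, 33L)
  s1 <- simulate_spectra(d, ground_truth(seed = 9))
  s2 <- simulate_spectra(d, ground_truth(seed = 9))
  expect_identical(s1$absorbance, s2$absorbance)
  y1 <- simulate_dpph(face_centered_ccd(ccd_factors),
                      example_truth("dpph", seed = 4))
  y2 <- simulate_dpph(face_centered_ccd(ccd_factors),
                      example_truth("dpph", seed = 4))
  expect_identical(y1, y2)
  expect_false(identical(a1, simulate_areas(d, tr, seed = 34)))
})

test_that("noise-free generation is recovered exactly by the model fit", {
  d <- full_factorial_design(factorial_factors)
  b <- example_truth("quality")$true_coefficients
  # per-response coefficient matrix, zero noise
  B <- cbind(r1 = b, r2 = 0.5 * b)
  tr <- ground_truth(coefficients = B, noise_sd = 0, seed = 1)
  ar <- simulate_areas(d, tr, n_responses = 2)
  fit <- fit_quadratic(d, ar[, 2])
  expect_equal(fit$coefficients, 0.5 * b, tolerance = 1e-10,
               ignore_attr = TRUE)
  # antioxidant surface, zero noise
  dc <- face_centered_ccd(ccd_factors, TRUE, TRUE)
  trd <- example_truth("dpph")
  trd$noise_sd <- 0
  trd$t0 <- 1  # keep the surface clear of the [0, t0] clip
  y <- simulate_dpph(dc, trd)
  fit2 <- fit_quadratic(dc, y)
  expect_equal(fit2$coefficients, trd$true_coefficients, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("correlated-response mode yields one-signed PC1 loadings", {
  d <- full_factorial_design(factorial_factors, TRUE, TRUE)
  one_signed <- vapply(1:50, function(s) {
    ar <- simulate_areas(d, example_truth("quality", seed = 400 + s))
    p <- pca_model(autoscale(ar), n_components = 1)
    all(p$loadings[, 1] > 0)
  }, NA)
  expect_gte(mean(one_signed), 0.95)
})

test_that("the antioxidant truth surface peaks at high quantity, short time, mid temperature", {
  dc <- face_centered_ccd(ccd_factors, TRUE, TRUE)
  trd <- example_truth("dpph")
  trd$noise_sd <- 0
  fit <- fit_quadratic(dc, simulate_dpph(dc, trd))
  opt <- optimize_response(fit, grid_step = 0.05)
  expect_equal(unname(opt$optimum_coded["Q"]), 1)
  expect_equal(unname(opt$optimum_coded["t"]), -1)
  expect_lt(abs(opt$optimum_coded["T"]), 0.8)
  expect_warning(
    simulate_dpph(dc, ground_truth(coefficients = c("(Intercept)" = 1, T = 0,
                                                    t = 0, Q = 0, "T^2" = 0.5),
                                   seed = 1)),
    "no interior maximum")
})

test_that("simulated spectra carry factor-linked bands removable by SNV", {
  d <- full_factorial_design(factorial_factors, TRUE, TRUE)
  # zero factor dependence -> all effect percentages near zero
  bands0 <- chemoextract:::default_band_spec(c("T", "t", "Q"))
  for (i in seq_along(bands0)) bands0[[i]]$coef[] <- 0
  sp0 <- simulate_spectra(d, ground_truth(band_spec = bands0, seed = 2))
  dec0 <- asca_decompose(snv(sp0))
  # with no injected effect each share stays near its null expectation
  expect_true(all(dec0$effect_variance_pct < 15))
  expect_gt(dec0$ss[["residual"]] / dec0$ss[["total"]], 0.6)

  # flavone band raised only at low temperature: SC1 separates that level
  # with negative loadings concentrated in 330-370 nm
  bands <- bands0
  bands$flavone$coef["T"] <- -0.6
  sp <- simulate_spectra(d, ground_truth(band_spec = bands, seed = 7))
  sps <- snv(sp)
  dec <- asca_decompose(sps)
  ep <- effect_pca(dec, "T", 1)
  lev_scores <- tapply(ep$scores[, 1], sps$factors$T, mean)
  expect_true(sign(lev_scores[["15"]]) != sign(lev_scores[["25"]]))
  band_region <- sps$wavelengths >= 330 & sps$wavelengths <= 370
  low_T_score <- lev_scores[["15"]]
  band_loadings <- ep$loadings[band_region, 1]
  # the low-temperature level and the flavone-band loadings have the same
  # orientation: their product reconstructs a positive band amplitude
  expect_gt(low_T_score * mean(band_loadings), 0)

  # scatter on vs off: SNV brings the spectra back together
  tr_scatter <- ground_truth(band_spec = bands, seed = 5)
  tr_clean <- ground_truth(band_spec = bands,
                           scatter_spec = list(gain_sdlog = 0, baseline_sd = 0,
                                               noise_sd = 0.005), seed = 5)
  s_sc <- simulate_spectra(d, tr_scatter)
  s_cl <- simulate_spectra(d, tr_clean)
  expect_gt(max(abs(s_sc$absorbance - s_cl$absorbance)), 0.05)
  expect_lt(max(abs(snv(s_sc$absorbance) - snv(s_cl$absorbance))), 0.2)
})
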