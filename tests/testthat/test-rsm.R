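truth_b <- c("(Intercept)" = 2, T = 0.5, t = -1, Q = 1.5, "T:t" = -0.8,
             "T:Q" = 0.2, "t:Q" = 0.3, "T^2" = 0.6, "t^2" = -0.4, "Q^2" = 0.1)

surface_on <- function(design, b) {
  M <- chemoextract:::rsm_model_matrix(coded_levels(design), names(b),
                                       colnames(coded_levels(design)))
  drop(M %*% b)
}

test_that("noise-free responses are interpolated to machine precision", {
  d <- full_factorial_design(factorial_factors)
  fit <- fit_quadratic(d, surface_on(d, truth_b))
  expect_equal(fit$coefficients, truth_b, tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("QR solution matches the explicit normal-equations oracle", {
  tab <- load_ccd_table()
  fit <- fit_quadratic(tab$design, tab$response)
  M <- chemoextract:::rsm_model_matrix(coded_levels(tab$design), fit$terms,
                                       c("T", "t", "Q"))
  y <- as.numeric(tab$response)
  oracle <- solve(crossprod(M), crossprod(M, y))  # (M'M) b = M'y
  expect_equal(unname(fit$coefficients), unname(drop(oracle)), tolerance = 1e-8)
  expect_equal(unname(fit$Cii), unname(diag(solve(crossprod(M)))), tolerance = 1e-8)
  # fit is invariant to run order
  perm <- rev(seq_along(y))
  d2 <- design_from_levels(coded_levels(tab$design)[perm, ], ccd_factors,
                           scale = "coded",
                           run_id = tab$design$runs$run_id[perm])
  fit2 <- fit_quadratic(d2, tab$response[perm])
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-10)
})

test_that("pooled variance pools within-group sums of squares", {
  pv <- pooled_variance(c(0.207, 0.228), c("a", "a"))
  expect_equal(pv$s2, 2.205e-4, tolerance = 1e-10)
  expect_equal(pv$df, 1L)
  expect_equal(pooled_variance(c(3, 3, 5, 5), c("a", "a", "b", "b"))$s2, 0)
  # published composite table as printed: seven duplicated conditions
  tab <- load_ccd_table()
  pv3 <- pooled_variance(tab$response, tab$design$runs$replicate_group)
  expect_equal(pv3$df, 7L)
  expect_error(pooled_variance(1:3, c("a", "b", "c")), "no replicated group")
})

test_that("coefficient t tests follow Sc = sqrt(s2 * Cii) with pooled DF", {
  d <- full_factorial_design(factorial_factors)
  y <- surface_on(d, truth_b)
  fit <- fit_quadratic(d, y)
  # hand case: Cii for a linear term of the 27-run factorial is 1/18
  tests <- coefficient_tests(fit, s2 = 1, df = 6)
  i <- match("T", tests$term)
  expect_equal(tests$sc[i], sqrt(1 / 18), tolerance = 1e-10)
  expect_equal(tests$t[i], 0.5 / sqrt(1 / 18), tolerance = 1e-10)
  expect_equal(tests$p[i], 2 * pt(-abs(0.5 / sqrt(1 / 18)), 6), tolerance = 1e-12)
  # a null coefficient gives t = 0, p = 1
  b0 <- truth_b; b0["t:Q"] <- 0
  t0 <- coefficient_tests(fit_quadratic(d, surface_on(d, b0)), s2 = 1, df = 6)
  j <- match("t:Q", t0$term)
  expect_equal(t0$t[j], 0, tolerance = 1e-10)
  expect_equal(t0$p[j], 1, tolerance = 1e-10)
  # Sc scales linearly with the pooled standard deviation
  t4 <- coefficient_tests(fit, s2 = 4, df = 6)
  expect_equal(t4$sc, 2 * tests$sc, tolerance = 1e-12)
  expect_error(coefficient_tests(fit, s2 = 0, df = 6), "degenerate")
})

test_that("hierarchical reduction removes exactly the unprotected terms", {
  d <- full_factorial_design(factorial_factors)
  # truth with null t^2, Q^2, t:Q and T:Q; T^2 and T:t strong
  b <- c("(Intercept)" = 2, T = 0.1, t = -1, Q = 1.5, "T:t" = -0.8,
         "T:Q" = 0, "t:Q" = 0, "T^2" = 0.6, "t^2" = 0, "Q^2" = 0)
  fit <- fit_quadratic(d, surface_on(d, b))
  red <- reduce_hierarchical(fit, s2 = 0.01, df = 6)
  expect_setequal(red$eliminated, c("t^2", "Q^2", "t:Q"))
  # T:Q is null but one parent quadratic (T^2) survives -> protected
  expect_true("T:Q" %in% red$terms)
  expect_setequal(red$terms, c("(Intercept)", "T", "t", "Q", "T:t", "T:Q", "T^2"))
  # all terms significant -> nothing eliminated
  full <- reduce_hierarchical(fit_quadratic(d, surface_on(d, truth_b)),
                              s2 = 1e-6, df = 6)
  expect_length(full$eliminated, 0)
})

test_that("ANOVA splits residual into lack of fit and pure error additively", {
  d <- full_factorial_design(factorial_factors, TRUE, TRUE)
  set.seed(11)
  y <- surface_on(d, truth_b) + rnorm(36, 0, 0.7)
  fit <- fit_quadratic(d, y, terms = c("(Intercept)", "T", "t", "Q"))
  an <- anova_lack_of_fit(fit)
  expect_equal(an["Total", "ss"],
               an["Regression", "ss"] + an["LackOfFit", "ss"] + an["PureError", "ss"],
               tolerance = 1e-8 * an["Total", "ss"])
  expect_equal(an["Total", "df"],
               an["Regression", "df"] + an["LackOfFit", "df"] + an["PureError", "df"])
  expect_equal(an["PureError", "df"], 9L)
  expect_lte(attr(an, "adj_r_squared"), attr(an, "r_squared"))
  # exact model on noise-free data
  d0 <- full_factorial_design(factorial_factors)
  an0 <- suppressWarnings(anova_lack_of_fit(fit_quadratic(d0, surface_on(d0, truth_b))))
  expect_equal(an0["Residual", "ss"], 0, tolerance = 1e-18)
  expect_equal(attr(an0, "adj_r_squared"), 1)
  # replicate-free designs warn and omit the split
  expect_warning(anova_lack_of_fit(fit_quadratic(d0, surface_on(d0, truth_b) +
                                                   rnorm(27))),
                 "no replicated runs")
})

test_that("grid optimization finds known optima", {
  d <- full_factorial_design(factorial_factors)
  # concave surface with vertex at coded (0.3, -0.2, 0.5)
  v <- c(0.3, -0.2, 0.5)
  b <- c("(Intercept)" = 5, T = 2 * v[1], t = 2 * v[2], Q = 2 * v[3],
         "T:t" = 0, "T:Q" = 0, "t:Q" = 0, "T^2" = -1, "t^2" = -1, "Q^2" = -1)
  fit <- fit_quadratic(d, surface_on(d, b))
  opt <- optimize_response(fit, grid_step = 0.05)
  expect_true(all(abs(opt$optimum_coded - v) <= 0.05 + 1e-9))
  expect_equal(unname(stationary_point(fit)), v, tolerance = 1e-8)
  # monotone (linear-only) surface peaks at a domain vertex
  blin <- c("(Intercept)" = 1, T = 1, t = -2, Q = 0.5)
  flin <- fit_quadratic(d, surface_on(d, blin), terms = names(blin))
  optl <- optimize_response(flin, grid_step = 0.1)
  expect_equal(unname(abs(optl$optimum_coded)), c(1, 1, 1))
  # pinning a factor restricts the search
  optf <- optimize_response(fit, grid_step = 0.1, fixed = c(Q = 1))
  expect_equal(unname(optf$optimum_coded["Q"]), 1)
  expect_error(optimize_response(fit, grid_step = 3), "empty grid")
})

test_that("collinear model matrices raise a singular-design error naming terms", {
  coded <- cbind(T = c(-1, 0, 1, -1, 0, 1), t = c(-1, 0, 1, -1, 0, 1),
                 Q = c(-1, -1, -1, 1, 1, 1))
  d <- design_from_levels(coded, factorial_factors, scale = "coded")
  expect_error(fit_quadratic(d, rnorm(6), terms = c("(Intercept)", "T", "t", "Q")),
               "singular design.*t")
})

test_that("coefficient estimates are unbiased with calibrated coverage", {
  d <- full_factorial_design(factorial_factors, TRUE, TRUE)
  mu <- surface_on(d, truth_b)
  sigma <- 0.66
  n_sim <- 200
  set.seed(314)
  est <- matrix(NA_real_, n_sim, length(truth_b))
  cover <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    fit <- fit_quadratic(d, mu + rnorm(length(mu), 0, sigma))
    est[i, ] <- fit$coefficients
    ct <- coefficient_tests(fit)
    cover[i] <- mean(truth_b[ct$term] >= ct$ci_lower &
                       truth_b[ct$term] <= ct$ci_upper)
  }
  se <- apply(est, 2, sd) / sqrt(n_sim)
  expect_true(all(abs(colMeans(est) - truth_b) < 3 * se + 1e-12))
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})
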