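test_that("SNV standardizes rows and ignores affine scatter", {
  r <- snv(rbind(c(1, 2, 3, 4)))
  expect_equal(drop(r), c(-1.1619, -0.3873, 0.3873, 1.1619), tolerance = 1e-4)
  set.seed(3)
  X <- matrix(rnorm(40, 1, 0.2), 4, 10)
  expect_equal(snv(1.7 * X + 0.3), snv(X), tolerance = 1e-12)
  expect_equal(snv(snv(X)), snv(X), tolerance = 1e-12)
  expect_true(all(abs(rowMeans(snv(X))) < 1e-12))
  expect_equal(unname(apply(snv(X), 1, sd)), rep(1, 4))
  Xf <- X; Xf[2, ] <- 5
  rownames(Xf) <- paste0("run", 1:4)
  expect_error(snv(Xf), "flat spectrum.*run2")
})

test_that("a two-level effect splits into symmetric deviations", {
  fct <- data.frame(g = rep(c("lo", "hi"), each = 3))
  X <- matrix(0, 6, 5)
  X[fct$g == "hi", 3] <- 1  # level means differ by 1 at wavelength 3
  dec <- asca_decompose(X, fct)
  expect_equal(unname(dec$effects$g[1, ]), c(0, 0, -0.5, 0, 0))
  expect_equal(unname(dec$effects$g[4, ]), c(0, 0, 0.5, 0, 0))
})

test_that("the decomposition reconstructs X exactly with orthogonal, additive parts", {
  fct <- balanced_labels(n_rep = 2)
  set.seed(8)
  n <- nrow(fct)
  X <- matrix(rnorm(n * 30), n, 30)
  # add structured effects on top of noise
  X[fct$A == "a1", 1:10] <- X[fct$A == "a1", 1:10] + 1
  X[fct$B == "b3", 21:30] <- X[fct$B == "b3", 21:30] - 0.7
  dec <- asca_decompose(X, fct, terms = c("A", "B", "C", "A:B"))
  recon <- sweep(Reduce(`+`, dec$effects) + dec$residual, 2,
                 dec$grand_mean, `+`)
  expect_lt(max(abs(X - recon)), 1e-10)
  # balanced design: SS additivity and pairwise orthogonality
  ss <- dec$ss
  expect_equal(sum(ss[setdiff(names(ss), "total")]), ss[["total"]],
               tolerance = 1e-8)
  for (a in names(dec$effects)) for (b in names(dec$effects)) if (a < b) {
    cp <- sum(dec$effects[[a]] * dec$effects[[b]])
    expect_lt(abs(cp) / ss[["total"]], 1e-8)
  }
  # pure-noise spectra: residual dominates, each effect small
  X0 <- matrix(rnorm(n * 30), n, 30)
  dec0 <- asca_decompose(X0, fct)
  expect_gt(dec0$ss[["residual"]] / dec0$ss[["total"]], 0.7)
  expect_true(all(dec0$effect_variance_pct < 15))
})

test_that("interaction terms are estimable only with full cell coverage", {
  fct <- balanced_labels()[, c("A", "B")]
  set.seed(2)
  X <- matrix(rnorm(nrow(fct) * 8), nrow(fct), 8)
  dec <- asca_decompose(X, fct, terms = c("A", "B", "A:B"))
  expect_true("A:B" %in% names(dec$effects))
  drop_rows <- fct$A == "a1" & fct$B == "b1"
  expect_error(asca_decompose(X[!drop_rows, ], fct[!drop_rows, ],
                              terms = c("A", "B", "A:B")),
               "not estimable")
})

test_that("effect PCA localizes a known band and projects residual scatter", {
  bd <- make_band_spectra(n_rep = 4, noise_sd = 0.02, seed = 12)
  dec <- asca_decompose(bd$X, bd$factors)
  ep <- effect_pca(dec, "T", n_components = 2)
  # three levels -> rank-2 effect; SC1 carries nearly all of it
  expect_gt(ep$explained_variance_pct[1], 90)
  # level mean scores separate the high-amplitude level from the others
  sc1 <- tapply(ep$scores[, 1], bd$factors$T, mean)
  expect_gt(max(abs(diff(sort(sc1)))), 0)
  expect_false(any(duplicated(round(sc1, 6))))
  # loadings concentrate inside the injected band
  l1 <- abs(ep$loadings[, 1])
  expect_gt(sum(l1[bd$in_band]^2), 0.95)
  # residual-augmented projections average back to the level-mean score
  proj_means <- tapply(ep$projected[, 1], bd$factors$T, mean)
  expect_equal(unname(proj_means), unname(sc1), tolerance = 1e-8)
  expect_error(effect_pca(dec, "T", n_components = 5), "rank")
  # single two-level factor -> rank-1 effect explains 100%
  fct2 <- data.frame(g = rep(c("x", "y"), each = 3))
  dec2 <- asca_decompose(matrix(rnorm(48), 6, 8), fct2)
  expect_equal(effect_pca(dec2, "g", 1)$explained_variance_pct[1], 100,
               tolerance = 1e-8)
})

test_that("permutation p-values behave for strong, null, and tiny cases", {
  bd <- make_band_spectra(n_rep = 4, noise_sd = 0.02, seed = 4)
  strong <- permutation_test(bd$X, "T", n_perm = 999, seed = 17,
                             factors = bd$factors)
  expect_equal(strong$p, 1 / 1000)
  # invariant to wavelength reordering
  set.seed(6)
  shuf <- sample(ncol(bd$X))
  strong2 <- permutation_test(bd$X[, shuf], "T", n_perm = 199, seed = 17,
                              factors = bd$factors)
  strong3 <- permutation_test(bd$X, "T", n_perm = 199, seed = 17,
                              factors = bd$factors)
  expect_equal(strong2$p, strong3$p)
  expect_equal(strong2$ss_observed, strong3$ss_observed, tolerance = 1e-10)

  # 6-run two-level case: Monte-Carlo p within binomial error of the
  # exhaustive enumeration over all 20 label arrangements
  fct <- data.frame(g = c("a", "a", "a", "b", "b", "b"))
  set.seed(30)
  Xs <- matrix(rnorm(6 * 12), 6, 12)
  Xs[fct$g == "b", ] <- Xs[fct$g == "b", ] + 0.8
  obs <- chemoextract:::main_effect_ss(Xs, fct, "g")
  combos <- combn(6, 3)
  exhaustive <- apply(combos, 2, function(idx) {
    f2 <- fct
    f2$g <- replace(rep("b", 6), idx, "a")
    chemoextract:::main_effect_ss(Xs, f2, "g")
  })
  p_exact <- mean(exhaustive >= obs - 1e-12)
  p_mc <- permutation_test(Xs, "g", n_perm = 999, seed = 8, factors = fct)$p
  se <- sqrt(p_exact * (1 - p_exact) / 999)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / 1000)
  expect_error(permutation_test(Xs, "g", n_perm = 10, seed = 1, factors = fct),
               "at least 99")
  expect_error(permutation_test(Xs, "g", n_perm = 199, factors = fct),
               "seed")
})

test_that("bootstrap flags the injected band and spares null wavelengths", {
  bd <- make_band_spectra(n_rep = 8, noise_sd = 0.03, seed = 22)
  bl <- bootstrap_loadings(bd$X, "T", n_boot = 300, seed = 5,
                           factors = bd$factors)
  expect_gte(mean(bl$significant[bd$in_band]), 0.8)
  # null coverage: exclusion rate near the nominal level
  level <- 0.95
  rate <- mean(bl$significant[!bd$in_band])
  expect_lte(rate, (1 - level) + 3 * sqrt(level * (1 - level) / 300) + 0.05)
  expect_equal(eval(formals(bootstrap_loadings)$n_boot), 1000L)
  # single-run cells fall back to the residual bootstrap with a warning
  bd1 <- make_band_spectra(n_rep = 1, noise_sd = 0.03, seed = 2)
  expect_warning(
    bootstrap_loadings(bd1$X, "T", n_boot = 100, seed = 3,
                       factors = bd1$factors),
    "residual bootstrap")
})
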