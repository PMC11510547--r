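#' Ground truth for the synthetic-data generators
#'
#' Bundles everything a generator needs so that simulated datasets carry a
#' machine-readable record of how they were made: the second-order surface
#' coefficients, the response noise, the spectral band specification, the
#' scatter model, and the seed.
#'
#' @param coefficients Named numeric vector of second-order coefficients
#'   (names as produced by [quadratic_terms()]), or a terms x responses
#'   matrix for per-response surfaces.
#' @param noise_sd Standard deviation of the additive Gaussian response
#'   noise (>= 0).
#' @param band_spec List of absorption-band classes; each class is a list
#'   with `centers` (nm), `width` (nm), `base` (amplitude at the design
#'   center) and `coef` (named amplitude change per coded unit of each
#'   factor). `NULL` selects bands typical of the polyphenol classes seen in
#'   chamomile extracts (hydroxybenzoic ~250/290 nm, hydroxycinnamic ~320 nm,
#'   flavone/flavonol 330-370 nm).
#' @param scatter_spec List with `gain_sdlog` (log-normal multiplicative
#'   scatter), `baseline_sd` (additive offset) and `noise_sd` (white noise,
#'   AU); set the first two to 0 for scatter-free spectra.
#' @param t0 Blank DPPH absorbance used to clip simulated responses (AU).
#' @param seed Integer seed recorded and used by the generators.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(coefficients = NULL, noise_sd = 0, band_spec = NULL,
                         scatter_spec = list(gain_sdlog = 0.1,
                                             baseline_sd = 0.05,
                                             noise_sd = 0.005),
                         t0 = 0.532, seed = 1L) {
  stopifnot(noise_sd >= 0)
  structure(list(true_coefficients = coefficients, noise_sd = noise_sd,
                 band_spec = band_spec, scatter_spec = scatter_spec,
                 t0 = t0, seed = as.integer(seed)),
            class = "ground_truth")
}

# Band amplitudes rise ~35% per coded unit of the temperature-like factor for
# the hydroxybenzoic bands, fall for the flavone band (low temperature
# favours glycosylated flavones/flavonols), and all classes grow with the
# quantity-like factor.
default_band_spec <- function(fnames) {
  cf <- function(v) stats::setNames(v, fnames[seq_along(v)])
  list(
    hydroxybenzoic  = list(centers = c(250, 290), width = 12, base = 1.0,
                           coef = cf(c(0.35, 0.00, 0.25))),
    hydroxycinnamic = list(centers = 320, width = 15, base = 0.9,
                           coef = cf(c(0.25, -0.20, 0.25))),
    flavone         = list(centers = 350, width = 18, base = 1.0,
                           coef = cf(c(-0.45, -0.15, 0.25)))
  )
}

# Evaluate a named second-order coefficient vector on coded levels.
eval_surface <- function(coded, coefficients, fnames) {
  M <- rsm_model_matrix(coded, names(coefficients), fnames)
  drop(M %*% coefficients)
}

#' Simulate a multiresponse chromatographic area table
#'
#' Each response follows the second-order surface at the run's coded levels
#' plus Gaussian noise. With a single coefficient vector the responses share
#' one latent "extract quality" surface through positive per-response
#' loadings, mimicking a peak table where every peak grows with overall
#' extract strength (and hence loads with one sign on PC1); a coefficient
#' matrix gives fully independent per-response surfaces.
#'
#' @param design A `doe_design`.
#' @param truth A [ground_truth()] whose `true_coefficients` is a named
#'   vector (shared latent surface) or terms x `n_responses` matrix.
#' @param n_responses Number of response columns (default 18).
#' @param seed Overrides `truth$seed` when given.
#' @return Runs x responses matrix (rownames = run ids) with attribute
#'   `ground_truth` recording coefficients, realized loadings/offsets, noise
#'   and seed.
#' @export
simulate_areas <- function(design, truth, n_responses = 18L, seed = NULL) {
  stopifnot(inherits(design, "doe_design"), inherits(truth, "ground_truth"))
  seed <- seed %||% truth$seed
  fnames <- factor_names(design$factors)
  coefs <- truth$true_coefficients
  if (is.null(coefs)) stop("truth must carry coefficients", call. = FALSE)
  n <- nrow(design$coded)
  out <- with_seed(seed, {
    if (is.matrix(coefs)) {
      if (ncol(coefs) != n_responses)
        stop("coefficient matrix must have n_responses columns", call. = FALSE)
      mu <- apply(coefs, 2L, function(b) eval_surface(design$coded, b, fnames))
      vals <- mu + matrix(stats::rnorm(n * n_responses, 0, truth$noise_sd), n)
      list(vals = vals, meta = list())
    } else {
      quality <- eval_surface(design$coded, coefs, fnames)
      loadings <- stats::runif(n_responses, 0.5, 1.5)
      base <- stats::runif(n_responses, 5, 20)
      vals <- outer(quality, loadings) +
        matrix(base, n, n_responses, byrow = TRUE) +
        matrix(stats::rnorm(n * n_responses, 0, truth$noise_sd), n)
      list(vals = vals, meta = list(loadings = loadings, base = base))
    }
  })
  vals <- out$vals
  rownames(vals) <- design$runs$run_id
  colnames(vals) <- sprintf("A%02d", seq_len(n_responses))
  attr(vals, "ground_truth") <- c(truth, out$meta, list(seed_used = seed))
  vals
}

#' Simulate UV-Vis spectra tied to a design
#'
#' Builds each spectrum as a sum of Gaussian absorption bands whose
#' amplitudes depend linearly on the coded factor levels, then applies a
#' multiplicative scatter gain, an additive baseline offset and white noise.
#' The scatter terms are exactly what SNV pretreatment is meant to remove.
#' Gaussian bands are an adequate stand-in for band-localization tests; no
#' spectro-physical realism is claimed.
#'
#' @inheritParams simulate_areas
#' @param wavelengths Acquisition grid in nm (default 220-400 at 1 nm).
#' @return A `spectra_set` whose factor labels are the runs' natural levels;
#'   attribute `ground_truth` records the band specification and seed.
#' @export
simulate_spectra <- function(design, truth, wavelengths = 220:400, seed = NULL) {
  stopifnot(inherits(design, "doe_design"), inherits(truth, "ground_truth"))
  seed <- seed %||% truth$seed
  fnames <- factor_names(design$factors)
  bands <- truth$band_spec %||% default_band_spec(fnames)
  for (b in bands)
    if (any(b$centers < min(wavelengths) | b$centers > max(wavelengths)))
      stop("band center outside the wavelength window", call. = FALSE)
  sc <- truth$scatter_spec
  n <- nrow(design$coded)
  p <- length(wavelengths)
  shapes <- lapply(bands, function(b)
    rowSums(vapply(b$centers,
                   function(ctr) exp(-0.5 * ((wavelengths - ctr) / b$width)^2),
                   numeric(p))))
  amps <- vapply(bands, function(b) {
    a <- b$base + drop(design$coded[, names(b$coef), drop = FALSE] %*% b$coef)
    pmax(a, 0)
  }, numeric(n))
  clean <- Reduce(`+`, lapply(seq_along(bands),
                              function(b) outer(amps[, b], shapes[[b]])))
  X <- with_seed(seed, {
    gain <- exp(stats::rnorm(n, 0, sc$gain_sdlog))
    baseline <- stats::rnorm(n, 0, sc$baseline_sd)
    clean * gain + baseline +
      matrix(stats::rnorm(n * p, 0, sc$noise_sd), n)
  })
  rownames(X) <- design$runs$run_id
  fct <- as.data.frame(natural_levels(design))
  fct[] <- lapply(fct, as.character)
  out <- spectra_set(wavelengths, X, fct)
  attr(out, "ground_truth") <- c(truth, list(band_spec_used = bands,
                                             seed_used = seed))
  out
}

#' Simulate an antioxidant (absorbance-drop) DOE response
#'
#' Draws the response from the second-order surface plus Gaussian noise and
#' clips it to the physically admissible range \[0, t0\] of an absorbance
#' difference. For the surface to carry an interior optimum like the one
#' studied, the quadratic coefficients of the temperature- and quantity-like
#' factors should be negative; a warning is issued otherwise.
#'
#' @inheritParams simulate_areas
#' @return Named response vector (names = run ids) with attribute
#'   `ground_truth`.
#' @export
simulate_dpph <- function(design, truth, seed = NULL) {
  stopifnot(inherits(design, "doe_design"), inherits(truth, "ground_truth"))
  seed <- seed %||% truth$seed
  coefs <- truth$true_coefficients
  if (!is.numeric(coefs) || is.matrix(coefs))
    stop("truth must carry a single named coefficient vector", call. = FALSE)
  quad <- grep("\\^2$", names(coefs), value = TRUE)
  if (length(quad) && any(coefs[quad] > 0))
    warning("positive quadratic coefficient(s): surface may have no interior maximum",
            call. = FALSE)
  fnames <- factor_names(design$factors)
  mu <- eval_surface(design$coded, coefs, fnames)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, truth$noise_sd))
  y <- pmin(pmax(y, 0), truth$t0)
  names(y) <- design$runs$run_id
  attr(y, "ground_truth") <- c(truth, list(seed_used = seed))
  y
}

#' Study-condition ground truths
#'
#' Ready-made [ground_truth()] objects for the two default simulated layouts:
#' `"quality"` mimics a composite chromatographic-quality surface (positive
#' quantity effect, negative time effect, temperature acting through its
#' quadratic term and its interaction with time), `"dpph"` mimics a concave
#' antioxidant surface with its maximum at high quantity, short time and mid
#' temperature.
#'
#' @param which `"quality"` or `"dpph"`.
#' @param factors Factor list (names are used for the coefficient labels);
#'   defaults to the package's standard factorial / composite factors.
#' @param seed Seed stored in the truth object.
#' @return A `ground_truth`.
#' @export
example_truth <- function(which = c("quality", "dpph"), factors = NULL,
                          seed = 1L) {
  which <- match.arg(which)
  if (which == "quality") {
    factors <- factors %||% chamomile_factors("factorial")
    nm <- factor_names(check_factor_list(factors))
    b <- stats::setNames(
      c(2.0, 0.15, -1.0, 1.5, -0.8, 0.2, 0, 0.6, 0, 0),
      c("(Intercept)", nm, paste(nm[1], nm[2], sep = ":"),
        paste(nm[1], nm[3], sep = ":"), paste(nm[2], nm[3], sep = ":"),
        paste0(nm, "^2")))
    ground_truth(coefficients = b, noise_sd = 0.66, seed = seed)
  } else {
    factors <- factors %||% chamomile_factors("ccd")
    nm <- factor_names(check_factor_list(factors))
    b <- stats::setNames(
      c(0.41, -0.023, -0.052, 0.145, -0.015, -0.011, 0.003, -0.024, 0, -0.059),
      c("(Intercept)", nm, paste(nm[1], nm[2], sep = ":"),
        paste(nm[1], nm[3], sep = ":"), paste(nm[2], nm[3], sep = ":"),
        paste0(nm, "^2")))
    ground_truth(coefficients = b, noise_sd = 0.012, seed = seed)
  }
}

#' Standard factor sets of the two studied designs
#'
#' The factorial layout studies temperature 15-25 C, time 32-72 min and
#' quantity 1.5-2.5 g; the composite (antioxidant) layout widens these to
#' 15-35 C, 32-92 min and 0.5-2.5 g.
#'
#' @param design `"factorial"` or `"ccd"`.
#' @return List of three [factor_spec()] objects named T, t, Q.
#' @export
chamomile_factors <- function(design = c("factorial", "ccd")) {
  design <- match.arg(design)
  if (design == "factorial")
    list(factor_spec("T", 15, 25, "C"), factor_spec("t", 32, 72, "min"),
         factor_spec("Q", 1.5, 2.5, "g"))
  else
    list(factor_spec("T", 15, 35, "C"), factor_spec("t", 32, 92, "min"),
         factor_spec("Q", 0.5, 2.5, "g"))
}
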