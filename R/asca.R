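#' Bundle spectra with their design factor labels
#'
#' @param wavelengths Strictly increasing numeric grid (nm).
#' @param absorbance Runs x wavelengths numeric matrix (AU).
#' @param factors Data frame, one row per run, one column per design factor
#'   (levels as labels, e.g. `"15"`, `"20"`, `"25"`).
#' @return A `spectra_set`.
#' @export
spectra_set <- function(wavelengths, absorbance, factors) {
  wavelengths <- as.numeric(wavelengths)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("'wavelengths' must be strictly increasing", call. = FALSE)
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavelengths))
    stop("absorbance columns must match the wavelength grid", call. = FALSE)
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != nrow(absorbance))
    stop("one row of factor labels per spectrum is required", call. = FALSE)
  factors[] <- lapply(factors, as.character)
  colnames(absorbance) <- wavelengths
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 factors = factors), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra, %d wavelengths (%g-%g nm), factors %s\n",
              nrow(x$absorbance), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), paste(names(x$factors), collapse = ", ")))
  invisible(x)
}

#' Restrict a spectra set to a wavelength window
#'
#' @param x A `spectra_set`.
#' @param from,to Window bounds in nm (inclusive).
#' @return A `spectra_set` on the restricted grid.
#' @export
crop_spectra <- function(x, from, to) {
  stopifnot(inherits(x, "spectra_set"))
  keep <- x$wavelengths >= from & x$wavelengths <= to
  if (!any(keep)) stop("empty wavelength window", call. = FALSE)
  spectra_set(x$wavelengths[keep], x$absorbance[, keep, drop = FALSE], x$factors)
}

#' Standard normal variate pretreatment
#'
#' Standardizes each spectrum (row) to mean 0 and standard deviation 1
#' (n-1 denominator), removing multiplicative scatter and additive baseline
#' offsets: `snv(a*x + b)` equals `snv(x)` for any `a > 0`.
#'
#' @param x Runs x wavelengths matrix, or a `spectra_set`.
#' @return Object of the same kind with SNV-transformed rows.
#' @export
snv <- function(x) {
  if (inherits(x, "spectra_set")) {
    x$absorbance <- snv(x$absorbance)
    return(x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("at least 2 wavelengths per spectrum are required", call. = FALSE)
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) {
    bad <- rownames(x)[s == 0] %||% which(s == 0)
    stop("flat spectrum (sd = 0) in run(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  (x - m) / s
}

as_spectra_input <- function(x, factors) {
  if (inherits(x, "spectra_set")) {
    list(X = x$absorbance, factors = x$factors, wavelengths = x$wavelengths)
  } else {
    if (is.null(factors)) stop("'factors' is required for a plain matrix", call. = FALSE)
    X <- as.matrix(x)
    factors <- as.data.frame(factors, stringsAsFactors = FALSE)
    factors[] <- lapply(factors, as.character)
    if (nrow(factors) != nrow(X))
      stop("'factors' must have one row per spectrum", call. = FALSE)
    wl <- suppressWarnings(as.numeric(colnames(X)))
    list(X = X, factors = factors,
         wavelengths = if (anyNA(wl) || !length(wl)) seq_len(ncol(X)) else wl)
  }
}

# Unweighted cell means over the full factor crossing (Type-III-like under
# mild unbalance; identical to plain means for balanced layouts). Cells are
# keyed with a separator that cannot occur in level labels.
cell_mean_matrix <- function(X, factors) {
  key <- do.call(paste, c(factors, list(sep = "\r")))
  ukey <- sort(unique(key))
  fkey <- factor(key, levels = ukey)
  counts <- as.vector(table(fkey))
  cm <- rowsum(X, fkey, reorder = TRUE) / counts
  list(key = key, fkey = fkey, means = cm, counts = counts,
       cell_levels = factors[match(ukey, key), , drop = FALSE])
}

# Level means of one factor as unweighted means of cell means; rows sorted by
# level label.
level_effect <- function(cmi, fac) {
  lv <- cmi$cell_levels[[fac]]
  flv <- factor(lv, levels = sort(unique(lv)))
  rowsum(cmi$means, flv, reorder = TRUE) / as.vector(table(flv))
}

#' ANOVA-simultaneous component analysis: effect decomposition
#'
#' Splits a (pretreated) spectral matrix into a grand-mean row, one effect
#' matrix per design term, and a residual, following the ANOVA decomposition
#' `X = X_mean + X_alpha + X_beta + ... + X_E`. Main-effect rows hold the
#' deviation of the run's level-mean spectrum from the grand mean; two-way
#' interaction rows hold cell-mean deviations net of the main effects. Level
#' and grand means are unweighted means of cell means, so mildly unbalanced
#' layouts (dropped runs) keep their interpretation. Reconstruction is exact
#' by construction; effect sums of squares are additive for balanced layouts.
#'
#' @param x A `spectra_set`, or a runs x wavelengths matrix.
#' @param factors Data frame of per-run factor labels (ignored when `x` is a
#'   `spectra_set`).
#' @param terms Character vector of main-effect names and optional `"a:b"`
#'   interactions; default all main effects (interactions off).
#' @return An `asca_decomposition`: `grand_mean`, `effects` (named list of
#'   runs x wavelengths matrices), `residual`, `ss` (per term, residual and
#'   centered total), `effect_variance_pct`, plus the inputs.
#' @export
asca_decompose <- function(x, factors = NULL, terms = NULL) {
  inp <- as_spectra_input(x, factors)
  X <- inp$X; fct <- inp$factors
  if (is.null(terms)) terms <- names(fct)
  main <- terms[!grepl(":", terms, fixed = TRUE)]
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  if (!all(main %in% names(fct)))
    stop("unknown factor(s): ", paste(setdiff(main, names(fct)), collapse = ", "),
         call. = FALSE)
  for (f in names(fct))
    if (length(unique(fct[[f]])) < 2L)
      stop("factor '", f, "' needs at least 2 levels", call. = FALSE)
  cmi <- cell_mean_matrix(X, fct)
  grand <- colMeans(cmi$means)
  Xc <- sweep(X, 2L, grand)
  effects <- list()
  for (f in main) {
    lm_ <- sweep(level_effect(cmi, f), 2L, grand)
    effects[[f]] <- lm_[fct[[f]], , drop = FALSE]
  }
  for (tm in inter) {
    fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(fs) != 2L || !all(fs %in% names(fct)))
      stop("interaction term '", tm, "' is not a pair of known factors", call. = FALSE)
    pair_key_cells <- do.call(paste, c(cmi$cell_levels[fs], list(sep = "\r")))
    full_cells <- length(unique(fct[[fs[1]]])) * length(unique(fct[[fs[2]]]))
    if (length(unique(pair_key_cells)) < full_cells)
      stop("interaction '", tm, "' not estimable: empty design cell(s)", call. = FALSE)
    upair <- sort(unique(pair_key_cells))
    fpair <- factor(pair_key_cells, levels = upair)
    pair_mean <- rowsum(cmi$means, fpair, reorder = TRUE) / as.vector(table(fpair))
    run_pair <- do.call(paste, c(fct[fs], list(sep = "\r")))
    effects[[tm]] <- sweep(pair_mean, 2L, grand)[run_pair, , drop = FALSE] -
      effects[[fs[1]]] - effects[[fs[2]]]
  }
  resid <- if (length(effects)) Xc - Reduce(`+`, effects) else Xc
  ss <- vapply(effects, function(e) sum(e^2), 0)
  ss_tot <- sum(Xc^2)
  ss <- c(ss, residual = sum(resid^2), total = ss_tot)
  rownames(resid) <- rownames(X)
  structure(list(grand_mean = grand, effects = effects, residual = resid,
                 ss = ss, effect_variance_pct = 100 * ss[names(effects)] / ss_tot,
                 terms = names(effects), factors = fct, X = X,
                 wavelengths = inp$wavelengths),
            class = "asca_decomposition")
}

#' @export
print.asca_decomposition <- function(x, ...) {
  cat("<asca_decomposition>\n")
  pct <- c(x$effect_variance_pct, residual = 100 * x$ss[["residual"]] / x$ss[["total"]])
  print(round(pct, 2))
  invisible(x)
}

#' PCA of one ASCA effect matrix
#'
#' The scores of the effect matrix collapse to one point per factor level
#' (the level-mean spectrum); projecting the effect-plus-residual rows onto
#' the same loadings adds the per-sample scatter around those level means, as
#' conventionally plotted for ASCA score plots.
#'
#' @param decomp An `asca_decomposition`.
#' @param term Which effect to analyse (e.g. `"T"`).
#' @param n_components Number of components (default 2, capped at the effect
#'   matrix rank).
#' @return A `pca_model` with extra elements `projected` (effect + residual
#'   scores per run) and `term`; explained variance is relative to the
#'   effect's own sum of squares.
#' @export
effect_pca <- function(decomp, term, n_components = 2L) {
  stopifnot(inherits(decomp, "asca_decomposition"))
  if (!term %in% names(decomp$effects))
    stop("no such effect: '", term, "'", call. = FALSE)
  E <- decomp$effects[[term]]
  s <- svd(E)
  rank <- sum(s$d > max(dim(E)) * max(s$d) * .Machine$double.eps)
  if (n_components > rank)
    stop("n_components exceeds effect-matrix rank (", rank, ")", call. = FALSE)
  keep <- seq_len(n_components)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], n_components)
  loadings <- s$v[, keep, drop = FALSE]
  colnames(scores) <- colnames(loadings) <- paste0("SC", keep)
  rownames(scores) <- rownames(decomp$X)
  rownames(loadings) <- decomp$wavelengths
  o <- orient_components(scores, loadings)
  projected <- (E + decomp$residual) %*% o$loadings
  rownames(projected) <- rownames(decomp$X)
  structure(list(scores = o$scores, loadings = o$loadings,
                 explained_variance_pct = 100 * s$d[keep]^2 / sum(s$d^2),
                 projected = projected, term = term,
                 wavelengths = decomp$wavelengths),
            class = c("asca_effect_pca", "pca_model"))
}

# Sum of squares of one main effect under the unweighted cell-mean scheme;
# cheap enough to call thousands of times inside the permutation loop.
main_effect_ss <- function(X, fct, term) {
  cmi <- cell_mean_matrix(X, fct)
  grand <- colMeans(cmi$means)
  dev <- sweep(level_effect(cmi, term), 2L, grand)
  n_runs <- table(fct[[term]])[rownames(dev)]
  sum(as.vector(n_runs) * rowSums(dev^2))
}

#' Permutation test for an ASCA main effect
#'
#' Builds the null distribution of the effect's sum of squares by randomly
#' permuting that factor's level labels across runs (other factors fixed)
#' and reports `p = (1 + #{SS_perm >= SS_obs}) / (n_perm + 1)`.
#'
#' @param x `spectra_set` or matrix (then supply `factors`).
#' @param term Main-effect name to test.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed (mandatory: resampling must be reproducible).
#' @param factors Data frame of factor labels when `x` is a matrix.
#' @return List with `p`, `ss_observed`, `ss_permuted` (length `n_perm`).
#' @export
permutation_test <- function(x, term, n_perm = 999L, seed, factors = NULL) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_perm < 99L) stop("n_perm must be at least 99", call. = FALSE)
  inp <- as_spectra_input(x, factors)
  X <- inp$X; fct <- inp$factors
  if (!term %in% names(fct)) stop("unknown factor '", term, "'", call. = FALSE)
  if (grepl(":", term, fixed = TRUE) || length(unique(fct[[term]])) < 2L)
    stop("'term' must be a main effect with at least 2 levels", call. = FALSE)
  obs <- main_effect_ss(X, fct, term)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      f2 <- fct
      f2[[term]] <- sample(f2[[term]])
      main_effect_ss(X, f2, term)
    }, 0)
  })
  list(p = (1 + sum(perm >= obs)) / (n_perm + 1), ss_observed = obs,
       ss_permuted = perm)
}

#' Bootstrap significance of ASCA loadings
#'
#' Resamples runs with replacement within design cells (or, when some cell
#' has a single run, resamples residual rows around the fitted effect
#' structure), recomputes the effect PCA each cycle, aligns the resampled
#' loading vector's sign to the point estimate, and flags a wavelength
#' significant when the percentile interval excludes zero.
#'
#' @inheritParams permutation_test
#' @param component Which component's loadings to assess (default 1).
#' @param n_boot Number of bootstrap cycles (>= 100; default 1000).
#' @param level Confidence level of the percentile interval (default 0.95).
#' @param method `"auto"` (within-cell when every cell has >= 2 runs, else
#'   residual with a warning), `"cells"`, or `"residual"`.
#' @param terms Decomposition terms (default all main effects).
#' @return Data frame: `wavelength`, `loading` (point estimate), `lower`,
#'   `upper`, `significant`.
#' @export
bootstrap_loadings <- function(x, term, component = 1L, n_boot = 1000L, seed,
                               level = 0.95, method = c("auto", "cells", "residual"),
                               factors = NULL, terms = NULL) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_boot < 100L) stop("n_boot must be at least 100", call. = FALSE)
  method <- match.arg(method)
  inp <- as_spectra_input(x, factors)
  X <- inp$X; fct <- inp$factors
  decomp <- asca_decompose(X, fct, terms = terms)
  point <- effect_pca(decomp, term, n_components = component)
  l0 <- point$loadings[, component]
  cell <- interaction(fct, drop = TRUE)
  if (method == "auto") {
    if (min(table(cell)) < 2L) {
      warning("cell(s) with a single run: falling back to residual bootstrap",
              call. = FALSE)
      method <- "residual"
    } else method <- "cells"
  } else if (method == "cells" && min(table(cell)) < 2L) {
    warning("cell(s) with a single run: within-cell resampling is degenerate there",
            call. = FALSE)
  }
  n <- nrow(X)
  fitted <- sweep(Reduce(`+`, decomp$effects), 2L, decomp$grand_mean, `+`)
  cell_idx <- split(seq_len(n), cell)
  boot <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, ncol(X))
    for (b in seq_len(n_boot)) {
      if (method == "cells") {
        idx <- unlist(lapply(cell_idx, function(ii)
          ii[sample.int(length(ii), length(ii), replace = TRUE)]),
          use.names = FALSE)
        Xb <- X[idx, , drop = FALSE]
        fb <- fct[idx, , drop = FALSE]
      } else {
        Xb <- fitted + decomp$residual[sample.int(n, n, replace = TRUE), ,
                                       drop = FALSE]
        fb <- fct
      }
      db <- asca_decompose(Xb, fb, terms = terms)
      pb <- effect_pca(db, term, n_components = component)
      lb <- pb$loadings[, component]
      if (sum(lb * l0) < 0) lb <- -lb
      out[b, ] <- lb
    }
    out
  })
  a <- (1 - level) / 2
  ci <- apply(boot, 2L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(wavelength = inp$wavelengths, loading = unname(l0),
             lower = ci[1, ], upper = ci[2, ],
             significant = ci[1, ] > 0 | ci[2, ] < 0)
}
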