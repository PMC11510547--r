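#' Autoscale a response table
#'
#' Column-wise standardization to mean 0 and unit standard deviation (n-1
#' denominator) — the conventional pretreatment before PCA of a multiresponse
#' table so that every peak, whatever its absolute area, weighs equally.
#'
#' @param x Numeric matrix or data frame (runs x responses).
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (any(scl == 0)) {
    bad <- colnames(x)[scl == 0] %||% which(scl == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- sweep(sweep(x, 2L, ctr, `-`), 2L, scl, `/`)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

# Deterministic sign orientation: flip each component so most loadings are
# positive; exact ties broken by the sign of the largest-magnitude loading.
orient_components <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    l <- loadings[, j]
    npos <- sum(l > 0); nneg <- sum(l < 0)
    flip <- if (npos != nneg) nneg > npos else l[which.max(abs(l))] < 0
    if (flip) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis by singular value decomposition
#'
#' Decomposes an already-centered (typically autoscaled) matrix: scores are
#' `U d`, loadings `V`, explained variance per component is the squared
#' singular value as a share of the total. Every component's sign is fixed by
#' a majority-positive-loadings rule, so results are deterministic across SVD
#' implementations.
#'
#' @param x Numeric matrix, rows = samples; pass it through [autoscale()]
#'   (or at least center it) first.
#' @param n_components Number of components to retain (default
#'   `min(nrow - 1, ncol)`).
#' @return A `pca_model`: `scores` (samples x components), `loadings`
#'   (variables x components, orthonormal columns), `explained_variance_pct`.
#' @export
pca_model <- function(x, n_components = NULL) {
  x <- as.matrix(x)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- kmax
  if (n_components < 1L || n_components > kmax)
    stop("n_components must be between 1 and min(nrow - 1, ncol) = ", kmax,
         call. = FALSE)
  s <- svd(x)
  expl <- 100 * s$d^2 / sum(s$d^2)
  keep <- seq_len(n_components)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], n_components)
  loadings <- s$v[, keep, drop = FALSE]
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("PC", keep)
  o <- orient_components(scores, loadings)
  structure(list(scores = o$scores, loadings = o$loadings,
                 explained_variance_pct = expl[keep],
                 center = attr(x, "center"), scale = attr(x, "scale")),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d samples x %d components; explained %% = %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.2f", x$explained_variance_pct), collapse = ", ")))
  invisible(x)
}

#' First principal component scores as the single DOE response
#'
#' When every monitored peak loads with the same sign on PC1, the PC1 score
#' is a composite "overall quality" response: runs with uniformly larger
#' areas score higher. The orientation rule in [pca_model()] guarantees the
#' majority of PC1 loadings are positive, so larger is better by construction.
#'
#' @param model A `pca_model`.
#' @return Named numeric vector of oriented PC1 scores (names = run ids when
#'   the input matrix had rownames).
#' @export
pc1_response <- function(model) {
  stopifnot(inherits(model, "pca_model"), ncol(model$scores) >= 1L)
  stats::setNames(model$scores[, 1L], rownames(model$scores))
}
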