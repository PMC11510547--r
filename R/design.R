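#' Define an experimental factor
#'
#' A factor is described by its name, the natural-unit bounds of the studied
#' range, and (optionally) its unit. Coded levels are always the affine map of
#' the natural range onto \[-1, +1\].
#'
#' @param name Single character label (e.g. `"T"`, `"t"`, `"Q"`).
#' @param low,high Natural-unit bounds of the studied range; `low < high`.
#' @param unit Optional unit string (e.g. `"C"`, `"min"`, `"g"`).
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("T", 15, 25, "C")
#' @export
factor_spec <- function(name, low, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("factor '", name, "': 'low' must be strictly less than 'high'", call. = FALSE)
  structure(list(name = name, low = low, high = high, unit = as.character(unit)),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s: [%g, %g] %s\n", x$name, x$low, x$high, x$unit))
  invisible(x)
}

check_factor_list <- function(factors) {
  if (inherits(factors, "factor_spec")) factors <- list(factors)
  if (!length(factors) || !all(vapply(factors, inherits, TRUE, "factor_spec")))
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  nm <- vapply(factors, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("factor names must be unique", call. = FALSE)
  names(factors) <- nm
  factors
}

factor_names <- function(factors) unname(vapply(factors, `[[`, "", "name"))

# condition label shared by replicated runs, e.g. "T+1.t-1.Q+1"
condition_label <- function(coded, factors) {
  apply(coded, 1L, function(r)
    paste(sprintf("%s%+g", factor_names(factors), r), collapse = "."))
}

new_doe_design <- function(coded, factors, type, seed = NULL) {
  coded <- as.matrix(coded)
  colnames(coded) <- factor_names(factors)
  grp <- condition_label(coded, factors)
  df <- data.frame(run_id = sprintf("R%02d", seq_len(nrow(coded))),
                   replicate_group = grp, stringsAsFactors = FALSE)
  structure(list(runs = df, coded = coded, factors = factors,
                 type = type, seed = seed),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %s: %d runs, %d distinct conditions, factors %s\n",
              x$type, nrow(x$coded), length(unique(x$runs$replicate_group)),
              paste(factor_names(x$factors), collapse = ", ")))
  invisible(x)
}

#' @rdname coded_levels
#' @export
natural_levels <- function(design) {
  coded_to_natural(design$coded, design$factors)
}

#' Extract coded / natural level matrices from a design
#'
#' @param design A `doe_design`.
#' @return A runs-by-factors numeric matrix of coded (`coded_levels`) or
#'   natural-unit (`natural_levels`) factor levels.
#' @export
coded_levels <- function(design) design$coded

#' Convert between coded and natural factor levels
#'
#' Coded levels are `(natural - mid) / half_range` per factor, so the studied
#' range maps onto \[-1, +1\]; the two functions are exact inverses. Natural
#' values outside a factor's range are converted with a warning (extrapolation
#' is allowed but flagged).
#'
#' @param x Numeric matrix (runs x factors) or vector of length `length(factors)`.
#' @param factors List of [factor_spec()] objects, in column order.
#' @return Matrix (or vector) of the same shape on the other scale.
#' @examples
#' tf <- list(factor_spec("T", 15, 25, "C"), factor_spec("t", 32, 72, "min"),
#'            factor_spec("Q", 1.5, 2.5, "g"))
#' coded_to_natural(c(1, -1, 1), tf)    # 25 C, 32 min, 2.5 g
#' @export
coded_to_natural <- function(x, factors) {
  factors <- check_factor_list(factors)
  vec <- is.null(dim(x))
  x <- rbind2mat(x, length(factors))
  mid <- vapply(factors, function(f) (f$low + f$high) / 2, 0)
  half <- vapply(factors, function(f) (f$high - f$low) / 2, 0)
  out <- sweep(sweep(x, 2L, half, `*`), 2L, mid, `+`)
  colnames(out) <- factor_names(factors)
  if (vec) drop(out) else out
}

#' @rdname coded_to_natural
#' @export
natural_to_coded <- function(x, factors) {
  factors <- check_factor_list(factors)
  vec <- is.null(dim(x))
  x <- rbind2mat(x, length(factors))
  low <- vapply(factors, `[[`, 0, "low")
  high <- vapply(factors, `[[`, 0, "high")
  out_of_domain <- sweep(x, 2L, low, `<`) | sweep(x, 2L, high, `>`)
  if (any(out_of_domain))
    warning("natural value(s) outside the studied range for factor(s): ",
            paste(unique(factor_names(factors)[col(out_of_domain)[out_of_domain]]),
                  collapse = ", "), call. = FALSE)
  mid <- (low + high) / 2; half <- (high - low) / 2
  out <- sweep(sweep(x, 2L, mid, `-`), 2L, half, `/`)
  colnames(out) <- factor_names(factors)
  if (vec) drop(out) else out
}

rbind2mat <- function(x, k) {
  if (is.null(dim(x))) x <- matrix(x, ncol = k)
  x <- as.matrix(x)
  if (ncol(x) != k) stop("expected ", k, " factor columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

append_replicates <- function(coded, replicate_vertices, replicate_center) {
  extra <- NULL
  if (replicate_vertices) {
    v <- coded[rowSums(abs(coded) == 1) == ncol(coded), , drop = FALSE]
    extra <- rbind(extra, v)
  }
  if (replicate_center) {
    ctr <- coded[rowSums(coded == 0) == ncol(coded), , drop = FALSE]
    extra <- rbind(extra, ctr)
  }
  rbind(coded, extra)
}

drop_conditions <- function(coded, drop) {
  if (is.null(drop)) return(coded)
  if (!is.list(drop)) drop <- list(drop)
  for (d in drop) {
    if (length(d) != ncol(coded))
      stop("each 'drop' entry needs one coded level per factor", call. = FALSE)
    keep <- rowSums(abs(sweep(coded, 2L, as.numeric(d), `-`)) > 1e-9) > 0
    if (all(keep))
      warning("drop condition (", paste(d, collapse = ", "),
              ") not present in design", call. = FALSE)
    coded <- coded[keep, , drop = FALSE]
  }
  coded
}

finalize_design <- function(coded, factors, type, drop, seed) {
  coded <- drop_conditions(coded, drop)
  if (!is.null(seed)) {
    coded <- with_seed(seed, coded[sample.int(nrow(coded)), , drop = FALSE])
  }
  new_doe_design(coded, factors, type, seed)
}

#' Build a three-level full factorial design
#'
#' Enumerates all 3^3 combinations of coded levels \{-1, 0, +1\} for exactly
#' three factors, in standard order (last factor varying fastest). Replicate
#' runs can be appended at the 8 vertices and at the center, and individual
#' conditions can be dropped (e.g. aborted runs).
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param replicate_vertices,replicate_center Append one replicate run at each
#'   cube vertex / at the center point.
#' @param drop Optional list of coded-level vectors identifying conditions to
#'   remove (all runs at that condition).
#' @param seed Optional integer; when given, the run order is randomized
#'   reproducibly. Default is the deterministic standard order.
#' @return A `doe_design` with runs, coded levels, and replicate-group labels
#'   (runs at the same condition share a label).
#' @examples
#' tf <- list(factor_spec("T", 15, 25, "C"), factor_spec("t", 32, 72, "min"),
#'            factor_spec("Q", 1.5, 2.5, "g"))
#' d <- full_factorial_design(tf, replicate_vertices = TRUE, replicate_center = TRUE)
#' nrow(coded_levels(d))  # 36
#' @export
full_factorial_design <- function(factors, replicate_vertices = FALSE,
                                  replicate_center = FALSE, drop = NULL,
                                  seed = NULL) {
  factors <- check_factor_list(factors)
  if (length(factors) != 3L)
    stop("unsupported design: exactly 3 factors are required", call. = FALSE)
  g <- expand.grid(x3 = c(-1, 0, 1), x2 = c(-1, 0, 1), x1 = c(-1, 0, 1))
  coded <- as.matrix(g[, c("x1", "x2", "x3")])
  dimnames(coded) <- NULL
  coded <- append_replicates(coded, replicate_vertices, replicate_center)
  finalize_design(coded, factors, "full_factorial_3level", drop, seed)
}

#' Build a face-centered central composite design
#'
#' 2^3 = 8 cube vertices, 6 face-center axial points (axial distance 1) and
#' one center point: 15 distinct conditions for three factors.
#'
#' @inheritParams full_factorial_design
#' @return A `doe_design`.
#' @examples
#' cf <- list(factor_spec("Q", 0.5, 2.5, "g"), factor_spec("t", 32, 92, "min"),
#'            factor_spec("T", 15, 35, "C"))
#' face_centered_ccd(cf)
#' @export
face_centered_ccd <- function(factors, replicate_vertices = FALSE,
                              replicate_center = FALSE, drop = NULL,
                              seed = NULL) {
  factors <- check_factor_list(factors)
  if (length(factors) != 3L)
    stop("unsupported design: exactly 3 factors are required", call. = FALSE)
  vertices <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))[, 3:1]
  axial <- rbind(diag(3), -diag(3))
  coded <- rbind(vertices, axial, rep(0, 3))
  dimnames(coded) <- NULL
  coded <- append_replicates(coded, replicate_vertices, replicate_center)
  finalize_design(coded, factors, "face_centered_ccd", drop, seed)
}

#' Assemble a design from an existing table of levels
#'
#' Used when runs come from a file or a printed table rather than from the
#' builders; levels may be given on either scale.
#'
#' @param levels Runs x factors matrix or data frame of levels.
#' @param factors List of [factor_spec()] objects matching the columns.
#' @param scale Whether `levels` are `"natural"` (default) or `"coded"`.
#' @param run_id Optional run labels (default `R01`, `R02`, ...).
#' @return A `doe_design`.
#' @export
design_from_levels <- function(levels, factors, scale = c("natural", "coded"),
                               run_id = NULL) {
  factors <- check_factor_list(factors)
  scale <- match.arg(scale)
  coded <- rbind2mat(as.matrix(levels), length(factors))
  if (scale == "natural") coded <- natural_to_coded(coded, factors)
  d <- new_doe_design(coded, factors, "custom")
  if (!is.null(run_id)) {
    run_id <- as.character(run_id)
    if (anyDuplicated(run_id))
      stop("duplicate run_id: ", run_id[duplicated(run_id)][1L], call. = FALSE)
    d$runs$run_id <- run_id
  }
  d
}

#' Maximum variance inflation factor of a design
#'
#' Diagnostic for near-orthogonality after dropping runs: VIFs of the
#' non-intercept columns of the second-order model matrix. An intact design
#' keeps all VIFs near 1; mild damage raises the maximum only slightly.
#'
#' @param design A `doe_design`.
#' @param terms Model terms (default full second-order set).
#' @return Largest VIF across non-intercept terms.
#' @export
design_vif <- function(design, terms = quadratic_terms(design$factors)) {
  M <- rsm_model_matrix(design$coded, terms, factor_names(design$factors))
  M <- M[, colnames(M) != "(Intercept)", drop = FALSE]
  R <- stats::cor(M)
  max(diag(solve(R)))
}
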