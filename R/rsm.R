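#' Full second-order term set for a factor list
#'
#' Term labels are built from factor names: linear (`"T"`), two-way
#' interactions (`"T:t"`), and pure quadratics (`"T^2"`), plus the intercept.
#'
#' @param factors List of [factor_spec()] objects (or a character vector of
#'   factor names).
#' @return Character vector of term labels in canonical order.
#' @export
quadratic_terms <- function(factors) {
  nm <- if (is.character(factors)) factors else factor_names(check_factor_list(factors))
  k <- length(nm)
  inter <- if (k > 1) {
    idx <- utils::combn(k, 2)
    paste(nm[idx[1, ]], nm[idx[2, ]], sep = ":")
  } else character()
  c("(Intercept)", nm, inter, paste0(nm, "^2"))
}

# Build the coded model matrix for a set of term labels.
rsm_model_matrix <- function(coded, terms, fnames = colnames(coded)) {
  coded <- as.matrix(coded)
  colnames(coded) <- fnames
  cols <- lapply(terms, function(tm) {
    if (tm == "(Intercept)") return(rep(1, nrow(coded)))
    if (grepl("\\^2$", tm)) {
      f <- sub("\\^2$", "", tm)
      if (!f %in% fnames) stop("unknown factor in term '", tm, "'", call. = FALSE)
      return(coded[, f]^2)
    }
    if (grepl(":", tm, fixed = TRUE)) {
      fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
      if (!all(fs %in% fnames)) stop("unknown factor in term '", tm, "'", call. = FALSE)
      return(coded[, fs[1]] * coded[, fs[2]])
    }
    if (!tm %in% fnames) stop("unknown term '", tm, "'", call. = FALSE)
    coded[, tm]
  })
  M <- do.call(cbind, cols)
  colnames(M) <- terms
  M
}

interaction_parents <- function(tm) paste0(strsplit(tm, ":", fixed = TRUE)[[1]], "^2")

#' Fit a second-order response surface model on coded levels
#'
#' Ordinary least squares of the response on the coded model matrix, solved by
#' QR decomposition. The diagonal of the inverse cross-product matrix (Cii) is
#' retained because the pooled-variance coefficient test needs it explicitly:
#' the standard deviation of coefficient i is `sqrt(s2_pooled * Cii)`.
#'
#' @param design A `doe_design`.
#' @param response Numeric response vector; if named, it is aligned to the
#'   design's `run_id` before fitting.
#' @param terms Term labels (default: full second-order set). The intercept
#'   and all linear terms are required.
#' @return A `quadratic_model` with elements `terms`, `coefficients`, `Cii`,
#'   `sigma2` (residual mean square), `df_residual`, `fitted`, `residuals`,
#'   `design`, `response`.
#' @export
fit_quadratic <- function(design, response, terms = NULL) {
  stopifnot(inherits(design, "doe_design"))
  fnames <- factor_names(design$factors)
  if (is.null(terms)) terms <- quadratic_terms(design$factors)
  if (!"(Intercept)" %in% terms || !all(fnames %in% terms))
    stop("the intercept and all linear terms must be in the model", call. = FALSE)
  if (!is.null(names(response))) {
    if (!setequal(names(response), design$runs$run_id))
      stop("response names do not match design run_id", call. = FALSE)
    response <- response[design$runs$run_id]
  }
  response <- as.numeric(response)
  if (length(response) != nrow(design$coded))
    stop("response length does not match number of runs", call. = FALSE)
  if (anyNA(response)) stop("response contains missing values", call. = FALSE)
  M <- rsm_model_matrix(design$coded, terms, fnames)
  if (nrow(M) < ncol(M))
    stop("fewer runs than model terms", call. = FALSE)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    bad <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop("singular design: collinear term(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  beta <- qr.coef(q, response)
  fitted <- drop(M %*% beta)
  res <- response - fitted
  xtx_inv <- chol2inv(qr.R(q))
  ord <- order(q$pivot)
  Cii <- diag(xtx_inv)[ord]
  names(Cii) <- colnames(M)
  df_res <- nrow(M) - ncol(M)
  structure(list(terms = terms, coefficients = beta, Cii = Cii,
                 sigma2 = if (df_res > 0) sum(res^2) / df_res else NA_real_,
                 df_residual = df_res, fitted = fitted, residuals = res,
                 design = design, response = response),
            class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> %d terms, %d runs, residual MS %.4g (%d DF)\n",
              length(x$terms), length(x$response), x$sigma2, x$df_residual))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' Pooled pure-error variance from replicated runs
#'
#' Pools the within-group sums of squares over every group of replicated
#' conditions: `s2 = sum_g SS_within_g / sum_g (n_g - 1)`.
#'
#' @param response Numeric vector of observed responses.
#' @param groups Replicate-group labels (same length as `response`); groups
#'   with a single member carry no pure-error information and are ignored.
#' @return List with `s2` (pooled variance) and `df` (`sum_g (n_g - 1)`).
#' @examples
#' pooled_variance(c(0.207, 0.228), c("a", "a"))  # s2 = 2.205e-4, df = 1
#' @export
pooled_variance <- function(response, groups) {
  stopifnot(length(response) == length(groups))
  sp <- split(as.numeric(response), as.character(groups))
  sp <- sp[lengths(sp) >= 2L]
  if (!length(sp))
    stop("no replicated group: pure error cannot be estimated", call. = FALSE)
  ss <- sum(vapply(sp, function(v) sum((v - mean(v))^2), 0))
  df <- sum(lengths(sp) - 1L)
  list(s2 = ss / df, df = df)
}

model_pooled_variance <- function(model) {
  pooled_variance(model$response, model$design$runs$replicate_group)
}

#' Pooled-variance t tests of model coefficients
#'
#' Each coefficient's standard deviation is `Sc = sqrt(s2 * Cii)` with `s2`
#' the replicate-based pooled variance, and the two-sided t test uses the
#' pooled degrees of freedom (not the residual DF); this keeps the test valid
#' when the model underfits. Residual-based testing is available via
#' `variance = "residual"`.
#'
#' @param model A `quadratic_model`.
#' @param s2,df Variance estimate and its degrees of freedom; by default the
#'   pooled variance computed from the design's replicate groups.
#' @param alpha Level for the reported confidence intervals and stars.
#' @param variance `"pooled"` (default) or `"residual"`.
#' @return Data frame with one row per term: `term`, `estimate`, `sc`, `t`,
#'   `df`, `p`, `stars`, `ci_lower`, `ci_upper`.
#' @export
coefficient_tests <- function(model, s2 = NULL, df = NULL, alpha = 0.05,
                              variance = c("pooled", "residual")) {
  variance <- match.arg(variance)
  if (is.null(s2) || is.null(df)) {
    if (variance == "residual") {
      s2 <- model$sigma2; df <- model$df_residual
    } else {
      pv <- model_pooled_variance(model)
      s2 <- pv$s2; df <- pv$df
    }
  }
  if (df < 1) stop("at least 1 degree of freedom is required", call. = FALSE)
  if (s2 < 0) stop("variance must be nonnegative", call. = FALSE)
  if (s2 == 0)
    stop("degenerate variance (s2 = 0): coefficient tests undefined", call. = FALSE)
  sc <- sqrt(s2 * model$Cii)
  tval <- model$coefficients / sc
  p <- 2 * stats::pt(-abs(tval), df)
  tcrit <- stats::qt(1 - alpha / 2, df)
  data.frame(term = model$terms, estimate = unname(model$coefficients),
             sc = unname(sc), t = unname(tval), df = df, p = unname(p),
             stars = as.character(significance_stars(unname(p))),
             ci_lower = unname(model$coefficients - tcrit * sc),
             ci_upper = unname(model$coefficients + tcrit * sc),
             stringsAsFactors = FALSE)
}

#' Hierarchical backward reduction of a second-order model
#'
#' Repeats until stable: test all coefficients; remove every non-significant
#' pure quadratic term; remove a non-significant interaction only when both of
#' its parent quadratic terms are already out of the model; refit. The
#' intercept and all linear terms are always retained, so the reduced model
#' stays well-defined under shifts and rotations of the factor axes.
#'
#' @inheritParams coefficient_tests
#' @param alpha Significance level for elimination (default 0.05).
#' @return The reduced `quadratic_model`, with `eliminated` (term labels in
#'   removal order) and `tests` (final coefficient table) attached.
#' @export
reduce_hierarchical <- function(model, alpha = 0.05, s2 = NULL, df = NULL,
                                variance = c("pooled", "residual")) {
  variance <- match.arg(variance)
  if (variance == "pooled" && (is.null(s2) || is.null(df))) {
    pv <- model_pooled_variance(model)  # fixed across refits: pure error only
    s2 <- pv$s2; df <- pv$df
  }
  eliminated <- character()
  repeat {
    tests <- if (variance == "residual")
      coefficient_tests(model, alpha = alpha, variance = "residual")
    else coefficient_tests(model, s2 = s2, df = df, alpha = alpha)
    terms <- model$terms
    nonsig <- tests$term[tests$p > alpha]
    rm_quad <- intersect(nonsig, grep("\\^2$", terms, value = TRUE))
    inter <- grep(":", terms, fixed = TRUE, value = TRUE)
    rm_int <- Filter(function(tm) tm %in% nonsig &&
                       !any(interaction_parents(tm) %in% terms), inter)
    removable <- c(rm_quad, rm_int)
    if (!length(removable)) break
    eliminated <- c(eliminated, removable)
    model <- fit_quadratic(model$design, model$response,
                           setdiff(terms, removable))
  }
  model$eliminated <- eliminated
  model$tests <- tests
  model
}

#' F ratio of two mean squares
#'
#' Assembles mean squares from sums of squares and degrees of freedom and
#' returns the upper-tail F probability — the building block of the regression
#' and lack-of-fit tests.
#'
#' @param ss_num,df_num Numerator sum of squares and DF.
#' @param ss_den,df_den Denominator sum of squares and DF.
#' @return List with `ms_num`, `ms_den`, `f`, `p`.
#' @examples
#' variance_ratio(253.357, 6, 41.066, 26)  # F = 26.73, p < 1e-4
#' @export
variance_ratio <- function(ss_num, df_num, ss_den, df_den) {
  ms1 <- ss_num / df_num
  ms2 <- ss_den / df_den
  f <- ms1 / ms2
  list(ms_num = ms1, ms_den = ms2, f = f,
       p = stats::pf(f, df_num, df_den, lower.tail = FALSE))
}

#' ANOVA with lack-of-fit split for a response surface model
#'
#' Partitions the total sum of squares about the mean into regression and
#' residual; the residual is further split into lack of fit and pure error
#' using the design's replicate groups. Regression DF is the number of
#' non-intercept terms.
#'
#' @param model A `quadratic_model`.
#' @return An `rsm_anova` data frame with rows Regression, Residual,
#'   LackOfFit, PureError, Total and columns `df`, `ss`, `ms`, `f`, `p`;
#'   attributes `r_squared` and `adj_r_squared`. Lack-of-fit rows are omitted
#'   (with a warning) when the design has no replicated condition.
#' @export
anova_lack_of_fit <- function(model) {
  y <- model$response
  n <- length(y)
  ybar <- mean(y)
  ss_tot <- sum((y - ybar)^2); df_tot <- n - 1L
  ss_res <- sum(model$residuals^2); df_res <- model$df_residual
  ss_reg <- ss_tot - ss_res; df_reg <- length(model$terms) - 1L
  reg <- variance_ratio(ss_reg, df_reg, ss_res, df_res)
  tab <- data.frame(df = c(df_reg, df_res), ss = c(ss_reg, ss_res),
                    ms = c(reg$ms_num, reg$ms_den), f = c(reg$f, NA),
                    p = c(reg$p, NA),
                    row.names = c("Regression", "Residual"))
  grp <- model$design$runs$replicate_group
  has_reps <- any(duplicated(grp))
  if (has_reps) {
    pv <- pooled_variance(y, grp)
    ss_pe <- pv$s2 * pv$df; df_pe <- pv$df
    ss_lof <- ss_res - ss_pe; df_lof <- df_res - df_pe
    lof <- variance_ratio(ss_lof, df_lof, ss_pe, df_pe)
    tab <- rbind(tab,
                 LackOfFit = data.frame(df = df_lof, ss = ss_lof,
                                        ms = lof$ms_num, f = lof$f, p = lof$p),
                 PureError = data.frame(df = df_pe, ss = ss_pe,
                                        ms = lof$ms_den, f = NA, p = NA))
  } else {
    warning("no replicated runs: lack-of-fit rows omitted", call. = FALSE)
  }
  tab <- rbind(tab, Total = data.frame(df = df_tot, ss = ss_tot, ms = NA,
                                       f = NA, p = NA))
  attr(tab, "r_squared") <- 1 - ss_res / ss_tot
  attr(tab, "adj_r_squared") <-
    1 - (ss_res / df_res) / (ss_tot / df_tot)
  class(tab) <- c("rsm_anova", "data.frame")
  tab
}

#' @export
print.rsm_anova <- function(x, ...) {
  print.data.frame(round(as.data.frame(x), 4))
  cat(sprintf("R-squared %.4f, adjusted R-squared %.4f\n",
              attr(x, "r_squared"), attr(x, "adj_r_squared")))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' @param object A `quadratic_model`.
#' @param coded Matrix (points x factors) or vector of coded levels; default
#'   the fitting design.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.quadratic_model <- function(object, coded = NULL, ...) {
  fnames <- factor_names(object$design$factors)
  if (is.null(coded)) coded <- object$design$coded
  coded <- rbind2mat(coded, length(fnames))
  drop(rsm_model_matrix(coded, object$terms, fnames) %*% object$coefficients)
}

#' Stationary point of the fitted quadratic surface
#'
#' Solves the gradient system of the second-order polynomial. Terms absent
#' from a reduced model contribute zero curvature, which can make the system
#' singular; `NA` is returned for such directions.
#'
#' @param model A `quadratic_model`.
#' @return Coded coordinates of the stationary point (may lie outside the
#'   design cube), or `NA`s when curvature is singular.
#' @export
stationary_point <- function(model) {
  fnames <- factor_names(model$design$factors)
  k <- length(fnames)
  b <- model$coefficients
  B <- matrix(0, k, k, dimnames = list(fnames, fnames))
  g <- stats::setNames(numeric(k), fnames)
  for (tm in model$terms) {
    if (tm == "(Intercept)") next
    if (grepl("\\^2$", tm)) {
      f <- sub("\\^2$", "", tm); B[f, f] <- b[tm]
    } else if (grepl(":", tm, fixed = TRUE)) {
      fs <- strsplit(tm, ":", fixed = TRUE)[[1]]
      B[fs[1], fs[2]] <- B[fs[2], fs[1]] <- b[tm] / 2
    } else g[tm] <- b[tm]
  }
  out <- tryCatch(drop(solve(-2 * B, g)),
                  error = function(e) stats::setNames(rep(NA_real_, k), fnames))
  out
}

#' Grid search of the fitted surface over the coded domain
#'
#' Evaluates the model on a regular coded grid over \[-1, +1\] per free
#' factor (optionally pinning factors, e.g. quantity at its maximum, as done
#' for contour plots) and returns the optimum.
#'
#' @param model A `quadratic_model`.
#' @param grid_step Coded-grid increment (default 0.05).
#' @param fixed Named numeric vector of coded levels to pin (e.g. `c(Q = 1)`).
#' @param maximize Maximize (default) or minimize.
#' @return List with `grid` (data frame of coded levels + `predicted`),
#'   `optimum_coded`, `optimum_natural`, `value`.
#' @export
optimize_response <- function(model, grid_step = 0.05, fixed = NULL,
                              maximize = TRUE) {
  if (grid_step > 2) stop("empty grid: grid_step exceeds the coded range", call. = FALSE)
  fnames <- factor_names(model$design$factors)
  if (!is.null(fixed) && !all(names(fixed) %in% fnames))
    stop("'fixed' names must be factor names", call. = FALSE)
  axes <- lapply(fnames, function(f) {
    if (f %in% names(fixed)) fixed[[f]] else seq(-1, 1, by = grid_step)
  })
  names(axes) <- fnames
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  pred <- predict(model, grid)
  idx <- if (maximize) which.max(pred) else which.min(pred)
  opt <- grid[idx, ]
  out <- data.frame(grid, predicted = pred, check.names = FALSE)
  list(grid = out,
       optimum_coded = opt,
       optimum_natural = coded_to_natural(opt, model$design$factors),
       value = pred[idx])
}
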