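#' DPPH inhibition percentage
#'
#' Percentage decrease of the 516 nm DPPH absorbance after reaction:
#' `100 * (t0 - t1) / t0`. Values outside \[0, 100\] are possible for noisy
#' inputs and are flagged with a warning, not clipped.
#'
#' @param t0 Blank-time absorbance of the DPPH working solution (AU, > 0).
#' @param t1 Absorbance after 1 h of reaction (AU); replicates should be
#'   averaged beforehand.
#' @return Inhibition percentage(s).
#' @examples
#' inhibition_percent(0.532, 0.0505)  # 90.5
#' @export
inhibition_percent <- function(t0, t1) {
  if (any(t0 <= 0)) stop("invalid blank: t0 must be positive", call. = FALSE)
  out <- 100 * (t0 - t1) / t0
  if (any(out < 0 | out > 100))
    warning("inhibition outside [0, 100]%: check absorbance inputs", call. = FALSE)
  out
}

#' Inhibition-versus-concentration calibration line and IC50
#'
#' Ordinary least squares of mean inhibition percentage on extract
#' concentration; the IC50 is read off the line as `(50 - intercept)/slope`
#' and its standard error follows by first-order propagation from the
#' coefficient covariance matrix.
#'
#' @param concentration Extract concentrations (mg dry material per mL).
#' @param inhibition Mean inhibition percentages, one per concentration.
#' @return A `dpph_calibration`: `slope` (% per mg/mL), `intercept` (%),
#'   `r_squared`, `ic50` (mg/mL), `ic50_se`, and the underlying `lm` fit.
#'   A non-positive slope warns (no scavenging trend) and sets `ic50` to `NA`.
#' @examples
#' fit_inhibition_line(c(1.5, 1.88, 3, 3.75, 7.5), c(25, 28, 36.6, 50, 90.5))
#' @export
fit_inhibition_line <- function(concentration, inhibition) {
  concentration <- as.numeric(concentration)
  inhibition <- as.numeric(inhibition)
  stopifnot(length(concentration) == length(inhibition))
  if (length(unique(concentration)) < 3L)
    stop("at least 3 distinct concentrations are required", call. = FALSE)
  if (any(concentration <= 0))
    stop("concentrations must be positive", call. = FALSE)
  fit <- stats::lm(inhibition ~ concentration)
  b <- stats::coef(fit)
  slope <- unname(b[2]); intercept <- unname(b[1])
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((inhibition - mean(inhibition))^2)
  if (slope <= 0) {
    warning("non-positive slope: no scavenging trend, IC50 undefined", call. = FALSE)
    ic50 <- NA_real_; se <- NA_real_
  } else {
    ic50 <- (50 - intercept) / slope
    grad <- c(-1 / slope, -(50 - intercept) / slope^2)
    s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
    V <- s2 * solve(crossprod(stats::model.matrix(fit)))
    se <- sqrt(drop(t(grad) %*% V %*% grad))
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 ic50 = ic50, ic50_se = se, fit = fit),
            class = "dpph_calibration")
}

#' @export
print.dpph_calibration <- function(x, ...) {
  cat(sprintf(
    "<dpph_calibration> inhibition%% = %.3f + %.3f * conc; R2 = %.4f\nIC50 = %.3f +/- %.3f mg/mL\n",
    x$intercept, x$slope, x$r_squared, x$ic50, x$ic50_se))
  invisible(x)
}

#' Absorbance-difference response for the antioxidant DOE
#'
#' The response optimized on the composite design is the raw absorbance drop
#' `Y = t0_mean - t1` at 516 nm (not the percentage), with `t0_mean` the mean
#' blank-time absorbance of the DPPH working solution.
#'
#' @param t0_mean Mean blank absorbance (AU, > 0).
#' @param t1 Reacted absorbance(s) at 1 h (AU).
#' @return `t0_mean - t1`.
#' @examples
#' ccd_response(0.532, 0.031)  # 0.501
#' @export
ccd_response <- function(t0_mean, t1) {
  if (any(t0_mean <= 0)) stop("invalid blank: t0_mean must be positive", call. = FALSE)
  t0_mean - t1
}
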