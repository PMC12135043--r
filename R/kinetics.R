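#' Pseudo-first-order insertion kinetics fit
#'
#' Fits the surface-pressure increase after solute injection to
#' \deqn{\Delta\pi(t) = \Delta\pi_{max} (1 - e^{-\beta t})}
#' by unweighted Levenberg-Marquardt least squares, with the `t = 0` point
#' included. Starting values come from the late-time plateau (for
#' \eqn{\Delta\pi_{max}}) and the initial slope (for \eqn{\beta}).
#'
#' @param trace An [insertion_trace()] with at least 10 points.
#'
#' @return A list of class `kinetics_fit` with elements `delta_pi_max`
#'   (mN/m), `beta` (1/s), their standard errors `se_delta_pi_max` and
#'   `se_beta`, `rms_residual` (mN/m), `pi_zero`, and the `fitted` values.
#' @export
fit_insertion_kinetics <- function(trace) {
  if (!inherits(trace, "insertion_trace"))
    stop("`trace` must be an insertion_trace object")
  t <- trace$time
  y <- trace$delta_pi
  if (length(t) < 10L) stop("insertion fit needs at least 10 points")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("non-finite values in insertion trace")

  # plateau guess: mean of the last decile; slope guess from the first decile
  ntail <- max(3L, length(y) %/% 10L)
  dmax0 <- mean(utils::tail(y, ntail))
  if (!is.finite(dmax0) || dmax0 == 0) dmax0 <- max(abs(y)) * sign(y[which.max(abs(y))])
  head_idx <- seq_len(max(3L, length(y) %/% 10L))
  slope0 <- stats::coef(stats::lm(y[head_idx] ~ t[head_idx]))[[2L]]
  beta0 <- slope0 / dmax0
  if (!is.finite(beta0) || beta0 <= 0) beta0 <- 1 / max(t[t > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ dmax * (1 - exp(-beta * t)),
                      start = list(dmax = dmax0, beta = beta0),
                      lower = c(-Inf, .Machine$double.eps),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("insertion kinetics fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(dmax = NA_real_, beta = NA_real_))
  res <- stats::residuals(fit)
  if (max(t) < 2 / cf[["beta"]])
    warning("trace spans less than 2/beta; plateau poorly constrained")
  structure(list(delta_pi_max = cf[["dmax"]],
                 beta = cf[["beta"]],
                 se_delta_pi_max = unname(se[["dmax"]]),
                 se_beta = unname(se[["beta"]]),
                 rms_residual = sqrt(mean(res^2)),
                 pi_zero = attr(trace, "pi_zero"),
                 fitted = stats::fitted(fit)),
            class = "kinetics_fit")
}

#' Exclusion surface pressure from maximum insertion responses
#'
#' Regresses the maximum surface-pressure increase \eqn{\Delta\pi_{max}}
#' on the initial surface pressure \eqn{\pi_0} by ordinary least squares.
#' The abscissa intercept of the fitted line is the exclusion surface
#' pressure: the film pressure above which the solute no longer inserts.
#' A non-negative slope means no extrapolated intercept exists and the
#' result is flagged undefined.
#'
#' @param pi_zero Numeric vector of initial surface pressures, mN/m. At
#'   least two distinct values are required.
#' @param delta_pi_max Numeric vector of maximum pressure increases, mN/m.
#'
#' @return A list of class `exclusion_result` with elements `slope`,
#'   `intercept` (mN/m), `pi_exclusion` (mN/m, `NA` when undefined) and
#'   the logical flag `defined`.
#' @export
exclusion_pressure <- function(pi_zero, delta_pi_max) {
  stopifnot(is.numeric(pi_zero), is.numeric(delta_pi_max))
  if (length(pi_zero) != length(delta_pi_max))
    stop("pi_zero and delta_pi_max must have equal length")
  if (length(unique(pi_zero)) < 2L)
    stop("need at least 2 distinct pi_zero values")
  fit <- stats::lm(delta_pi_max ~ pi_zero)
  b <- unname(stats::coef(fit))
  intercept <- b[1L]
  slope <- b[2L]
  defined <- is.finite(slope) && slope < 0
  structure(list(slope = slope,
                 intercept = intercept,
                 pi_exclusion = if (defined) -intercept / slope else NA_real_,
                 defined = defined),
            class = "exclusion_result")
}
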