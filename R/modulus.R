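#' Elastic compression modulus of a monolayer isotherm
#'
#' Computes the elastic compression modulus
#' \deqn{C_s^{-1} = -A \left(\frac{\partial \pi}{\partial A}\right)_T}
#' pointwise along a compression isotherm. Because numerical
#' differentiation amplifies noise, the derivative is taken from a local
#' polynomial fitted in a sliding window around each point (centred at
#' interior points, one-sided at the ends); the window works on the actual,
#' possibly non-uniform, area grid.
#'
#' Low values of \eqn{C_s^{-1}} flag fluid or phase-coexistence regions: an
#' LE/LC transition plateau appears as a minimum of the modulus.
#'
#' @param iso An [isotherm()].
#' @param smooth_window Odd number of points in the local fit window.
#' @param smooth_order Polynomial order of the local fit; the window must
#'   contain at least `smooth_order + 2` points.
#'
#' @return An object of class `modulus_curve`: a data frame with columns
#'   `surface_pressure` (mN/m) and `cs_inverse` (mN/m), ordered by
#'   increasing surface pressure along the compression branch.
#' @export
compression_modulus <- function(iso, smooth_window = 11L, smooth_order = 3L) {
  if (!inherits(iso, "isotherm")) stop("`iso` must be an isotherm object")
  smooth_window <- as.integer(smooth_window)
  smooth_order <- as.integer(smooth_order)
  if (smooth_window %% 2L == 0L) stop("smooth_window must be odd")
  if (smooth_window < smooth_order + 2L)
    stop("smooth_window must be at least smooth_order + 2")
  A <- iso$area_per_molecule
  p <- iso$surface_pressure
  n <- length(A)
  if (n < smooth_window)
    stop("isotherm has fewer points than the smoothing window")
  if (any(diff(A) >= 0))
    stop("area grid is not strictly decreasing after sorting (duplicate areas?)")

  half <- smooth_window %/% 2L
  dpidA <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    # keep the window size fixed at the ends by sliding it inward
    if (hi - lo + 1L < smooth_window) {
      if (lo == 1L) hi <- min(n, smooth_window) else lo <- max(1L, n - smooth_window + 1L)
    }
    x <- A[lo:hi] - A[i]
    X <- outer(x, 0:smooth_order, `^`)
    fit <- stats::lm.fit(X, p[lo:hi])
    dpidA[i] <- fit$coefficients[2L]
  }
  out <- data.frame(surface_pressure = p, cs_inverse = -A * dpidA)
  out <- out[order(out$surface_pressure), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("modulus_curve", "data.frame"))
}

#' Locate a monolayer phase transition from the modulus curve
#'
#' A first-order transition (e.g. liquid-expanded to liquid-condensed)
#' shows up as an interior local minimum of \eqn{C_s^{-1}} vs. surface
#' pressure. The search is restricted to a pressure window; when the
#' modulus is monotone inside the window no transition is reported.
#'
#' Because a coexistence plateau produces a flat-bottomed valley (and the
#' smoothed derivative can undershoot at the plateau edges), the reported
#' pressure is the centroid of the valley floor: the contiguous run of
#' points around the minimum whose modulus lies within a small fraction
#' (`floor_frac`) of the valley depth. This targets the plateau center
#' rather than an arbitrary point of a near-flat bottom, and is
#' deterministic.
#'
#' @param mc A `modulus_curve` from [compression_modulus()].
#' @param search_range Numeric length-2 vector `c(pi_low, pi_high)` in mN/m;
#'   must overlap the curve's pressure span.
#' @param floor_frac Fraction of the valley depth defining the valley
#'   floor used for the centroid.
#' @param min_depth Minimum relative valley depth (drop from the shallower
#'   window edge to the minimum, as a fraction of the largest modulus in
#'   the window) for a minimum to count as a transition; guards against
#'   numerical wiggles on a flat single-phase curve.
#'
#' @return The transition surface pressure in mN/m, or `NA_real_` when no
#'   (sufficiently deep) interior minimum exists in the range.
#' @export
detect_transition <- function(mc, search_range, floor_frac = 0.05,
                              min_depth = 0.1) {
  if (!inherits(mc, "modulus_curve")) stop("`mc` must be a modulus_curve")
  if (length(search_range) != 2L || search_range[1L] >= search_range[2L])
    stop("search_range must be c(pi_low, pi_high) with pi_low < pi_high")
  p <- mc$surface_pressure
  cs <- mc$cs_inverse
  sel <- which(p >= search_range[1L] & p <= search_range[2L])
  if (length(sel) == 0L) stop("search range does not overlap the modulus curve")
  if (length(sel) < 3L) return(NA_real_)
  ps <- p[sel]
  css <- cs[sel]
  i <- which.min(css)
  if (i == 1L || i == length(sel)) return(NA_real_)  # monotone in the window
  depth <- min(css[1L], css[length(sel)]) - css[i]
  if (max(css) <= 0 || depth < min_depth * max(css)) return(NA_real_)
  # centroid of the contiguous valley floor around the minimum
  thr <- css[i] + floor_frac * (max(css) - css[i])
  lo <- i; while (lo > 1L && css[lo - 1L] <= thr) lo <- lo - 1L
  hi <- i; while (hi < length(sel) && css[hi + 1L] <= thr) hi <- hi + 1L
  mean(ps[lo:hi])
}
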