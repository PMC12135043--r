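#' Polarized absorbance spectrum
#'
#' ATR absorbances measured with p- and s-polarised light on a common
#' wavenumber grid. Ascending or descending grids are accepted; the object
#' stores the grid ascending.
#'
#' @param wavenumber Strictly monotone numeric grid, 1/cm.
#' @param absorbance_p,absorbance_s Absorbance with p- and s-polarised
#'   light, same length as the grid.
#' @return An object of class `polarized_spectrum` (a data frame).
#' @export
polarized_spectrum <- function(wavenumber, absorbance_p, absorbance_s) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance_p),
            is.numeric(absorbance_s))
  n <- length(wavenumber)
  if (length(absorbance_p) != n || length(absorbance_s) != n)
    stop("wavenumber and absorbance series must have equal length")
  if (any(!is.finite(wavenumber)) || any(!is.finite(absorbance_p)) ||
      any(!is.finite(absorbance_s)))
    stop("non-finite values in spectrum")
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0)))
    stop("wavenumber grid must be strictly monotone")
  if (d[1L] < 0) {
    wavenumber <- rev(wavenumber)
    absorbance_p <- rev(absorbance_p)
    absorbance_s <- rev(absorbance_s)
  }
  structure(data.frame(wavenumber = wavenumber,
                       absorbance_p = absorbance_p,
                       absorbance_s = absorbance_s),
            class = c("polarized_spectrum", "data.frame"))
}

#' Read a polarized spectrum from a delimited text file
#'
#' Expects three columns with header `wavenumber_cm1,abs_p,abs_s` (comma or
#' tab separated); `#` comment lines are ignored.
#'
#' @param path File path.
#' @return A [polarized_spectrum()].
#' @export
read_polarized_spectrum <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         comment.char = "#")
  polarized_spectrum(d[[1L]], d[[2L]], d[[3L]])
}

#' Vibrational band model
#'
#' A set of pseudo-Voigt bands shared between the two polarizations:
#' center, full width at half maximum and Gaussian/Lorentzian mix describe
#' the vibration itself and are common to p and s; the amplitudes (peak
#' heights) differ because the two polarizations project the transition
#' dipole differently.
#'
#' @param center Band centers, 1/cm.
#' @param width Full widths at half maximum, 1/cm, positive.
#' @param shape_mix Lorentzian fraction in `[0, 1]` (0 = pure Gaussian).
#' @param amplitude_p,amplitude_s Peak absorbances, non-negative.
#' @return An object of class `band_model` (a data frame, one row per
#'   band) with derived columns `area_p` and `area_s` (integrated band
#'   areas).
#' @export
band_model <- function(center, width, shape_mix = 0,
                       amplitude_p = 1, amplitude_s = 1) {
  n <- length(center)
  width <- rep_len(width, n); shape_mix <- rep_len(shape_mix, n)
  amplitude_p <- rep_len(amplitude_p, n); amplitude_s <- rep_len(amplitude_s, n)
  if (any(width <= 0)) stop("band widths must be positive")
  if (any(shape_mix < 0 | shape_mix > 1)) stop("shape_mix must lie in [0, 1]")
  if (any(amplitude_p < 0) || any(amplitude_s < 0))
    stop("band amplitudes must be non-negative")
  out <- data.frame(center = center, width = width, shape_mix = shape_mix,
                    amplitude_p = amplitude_p, amplitude_s = amplitude_s)
  out$area_p <- .pv_area(amplitude_p, width, shape_mix)
  out$area_s <- .pv_area(amplitude_s, width, shape_mix)
  structure(out, class = c("band_model", "data.frame"))
}

#' Pseudo-Voigt line shape (unit peak height)
#'
#' Linear combination of a Gaussian and a Lorentzian with common center
#' and FWHM: `(1 - mix) * G + mix * L`.
#'
#' @param x Evaluation grid, 1/cm.
#' @param center Band center, 1/cm.
#' @param width FWHM, 1/cm.
#' @param mix Lorentzian fraction in `[0, 1]`.
#' @return Profile values, unit height at the center.
#' @export
pseudo_voigt <- function(x, center, width, mix = 0) {
  u <- (x - center) / width
  (1 - mix) * exp(-4 * log(2) * u^2) + mix / (1 + 4 * u^2)
}

# integrated area of a unit-height pseudo-Voigt scaled by `amp`
.pv_area <- function(amp, width, mix) {
  amp * width * ((1 - mix) * 0.5 * sqrt(pi / log(2)) + mix * pi / 2)
}

.band_profile <- function(x, bands, which_pol = c("p", "s")) {
  which_pol <- match.arg(which_pol)
  amp <- if (which_pol == "p") bands$amplitude_p else bands$amplitude_s
  y <- numeric(length(x))
  for (k in seq_len(nrow(bands)))
    y <- y + amp[k] * pseudo_voigt(x, bands$center[k], bands$width[k],
                                   bands$shape_mix[k])
  y
}

#' Joint band deconvolution of a polarized spectrum
#'
#' Fits both polarizations simultaneously to a shared set of pseudo-Voigt
#' bands: centers, widths and shape mixes are common to p and s (the same
#' vibration underlies both), amplitudes are independent, and each
#' polarization gets its own polynomial baseline. Optimisation is
#' bounded Levenberg-Marquardt least squares on the concatenated p and s
#' residuals inside the fit window.
#'
#' @param spec A [polarized_spectrum()].
#' @param seeds A [band_model()] giving starting centers, widths, mixes and
#'   amplitudes; all seed centers must lie inside `window`.
#' @param window Numeric length-2 fit window `c(lo, hi)` in 1/cm, covered
#'   by the spectrum grid.
#' @param baseline_order Polynomial baseline order per polarization
#'   (0, 1 or 2).
#' @param min_width Lower bound on fitted FWHM, 1/cm; a band collapsing to
#'   this bound aborts the fit.
#'
#' @return A fitted [band_model()] with integrated areas per polarization
#'   and attributes `baseline_p`, `baseline_s` (polynomial coefficients in
#'   the window-scaled coordinate), `rms_residual` and `window`.
#' @export
deconvolve_bands <- function(spec, seeds, window, baseline_order = 1,
                             min_width = 0.5) {
  if (!inherits(spec, "polarized_spectrum"))
    stop("`spec` must be a polarized_spectrum")
  if (!inherits(seeds, "band_model")) stop("`seeds` must be a band_model")
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be c(lo, hi) with lo < hi")
  if (any(seeds$center < window[1L] | seeds$center > window[2L]))
    stop("all seed centers must lie inside the fit window")
  baseline_order <- as.integer(baseline_order)
  if (!baseline_order %in% 0:2) stop("baseline_order must be 0, 1 or 2")

  sel <- spec$wavenumber >= window[1L] & spec$wavenumber <= window[2L]
  if (sum(sel) < 5L * nrow(seeds))
    stop("spectrum grid does not cover the fit window densely enough")
  x <- spec$wavenumber[sel]
  yp <- spec$absorbance_p[sel]
  ys <- spec$absorbance_s[sel]
  # scaled baseline coordinate for conditioning
  x0 <- mean(window); hw <- diff(window) / 2
  u <- (x - x0) / hw
  nb <- nrow(seeds)
  nbl <- baseline_order + 1L

  unpack <- function(par) {
    list(center = par[seq_len(nb)],
         width  = par[nb + seq_len(nb)],
         mix    = par[2L * nb + seq_len(nb)],
         amp_p  = par[3L * nb + seq_len(nb)],
         amp_s  = par[4L * nb + seq_len(nb)],
         bl_p   = par[5L * nb + seq_len(nbl)],
         bl_s   = par[5L * nb + nbl + seq_len(nbl)])
  }
  model <- function(par) {
    q <- unpack(par)
    mp <- numeric(length(x)); ms <- numeric(length(x))
    for (k in seq_len(nb)) {
      prof <- pseudo_voigt(x, q$center[k], q$width[k], q$mix[k])
      mp <- mp + q$amp_p[k] * prof
      ms <- ms + q$amp_s[k] * prof
    }
    bl <- outer(u, 0:baseline_order, `^`)
    list(p = mp + drop(bl %*% q$bl_p), s = ms + drop(bl %*% q$bl_s))
  }
  par0 <- c(seeds$center, seeds$width, seeds$shape_mix,
            seeds$amplitude_p, seeds$amplitude_s,
            rep(0, nbl), rep(0, nbl))
  lower <- c(rep(window[1L], nb), rep(min_width, nb), rep(0, nb),
             rep(0, 2L * nb), rep(-Inf, 2L * nbl))
  upper <- c(rep(window[2L], nb), rep(diff(window), nb), rep(1, nb),
             rep(Inf, 2L * nb), rep(Inf, 2L * nbl))
  fit <- minpack.lm::nls.lm(
    par = par0,
    lower = lower, upper = upper,
    fn = function(par) { m <- model(par); c(m$p - yp, m$s - ys) },
    control = minpack.lm::nls.lm.control(maxiter = 500))
  rms <- sqrt(mean(fit$fvec^2))
  if (!fit$info %in% 1:4)
    stop("band deconvolution did not converge (", fit$message,
         "); final residual RMS = ", format(rms))
  q <- unpack(fit$par)
  if (any(q$width <= min_width * (1 + 1e-6)))
    stop("a band collapsed to zero width during the fit")
  out <- band_model(q$center, q$width, q$mix, q$amp_p, q$amp_s)
  attr(out, "baseline_p") <- q$bl_p
  attr(out, "baseline_s") <- q$bl_s
  attr(out, "rms_residual") <- rms
  attr(out, "window") <- window
  out
}

#' Dichroic ratio of fitted bands
#'
#' Ratio of the integrated p-polarised to s-polarised area of each band,
#' \eqn{R = A_p / A_s}. For a film probed through the evanescent field, a
#' band of an isotropically oriented dipole gives
#' \eqn{R_{iso} = (E_x^2 + E_z^2)/E_y^2}.
#'
#' @param bands A fitted [band_model()] (or any subset of its rows).
#' @return Numeric vector of dichroic ratios, one per band.
#' @export
dichroic_ratio <- function(bands) {
  if (!inherits(bands, "band_model")) stop("`bands` must be a band_model")
  if (any(bands$area_s <= 0))
    stop("zero s-polarised area: dichroic ratio undefined")
  bands$area_p / bands$area_s
}
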