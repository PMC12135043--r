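#' Internal-reflection optical configuration
#'
#' Geometry and refractive indices of an attenuated-total-reflection (ATR)
#' experiment: radiation travels in a dense medium (index `n1`, e.g. a Si
#' prism, 3.42) and reflects totally at the interface with a rarer medium
#' (index `n2`, e.g. a D2O electrolyte, 1.42) at incidence angle
#' `beta_inc`. Total internal reflection requires
#' `n1 * sin(beta_inc) > n2`.
#'
#' @param n1 Refractive index of the incidence medium.
#' @param n2 Refractive index of the rarer medium.
#' @param beta_inc Incidence angle in degrees, in (0, 90).
#' @param wavenumber Radiation wavenumber in 1/cm.
#' @param n_film Optional refractive index of a thin film at the interface;
#'   when given, [interface_field_intensities()] applies the three-phase
#'   thin-film correction to the normal field component.
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(n1 = 3.42, n2 = 1.42, beta_inc = 60,
                           wavenumber = 2900, n_film = NULL) {
  stopifnot(is.numeric(n1), is.numeric(n2), is.numeric(beta_inc),
            is.numeric(wavenumber))
  if (!(n1 > n2 && n2 > 0)) stop("need n1 > n2 > 0")
  if (!(beta_inc > 0 && beta_inc < 90))
    stop("incidence angle must be inside (0, 90) degrees")
  if (wavenumber <= 0) stop("wavenumber must be positive")
  if (!is.null(n_film) && n_film <= 0) stop("n_film must be positive")
  structure(list(n1 = n1, n2 = n2, beta_inc = beta_inc,
                 wavenumber = wavenumber, n_film = n_film),
            class = "optical_config")
}

.check_evanescent <- function(cfg) {
  sb <- sin(cfg$beta_inc * pi / 180)
  if (cfg$n1 * sb <= cfg$n2)
    stop("below critical angle: n1*sin(beta) <= n2, no total internal reflection")
  invisible(sb)
}

#' Penetration depth of the evanescent wave
#'
#' \deqn{d_p = \frac{\lambda}{2\pi\sqrt{n_1^2\sin^2\beta - n_2^2}}}
#' with \eqn{\lambda = 10^7/\tilde\nu} nm. Only the film within roughly one
#' penetration depth of the interface contributes to the ATR absorbance.
#'
#' @param cfg An [optical_config()].
#' @return Penetration depth in nm.
#' @export
penetration_depth <- function(cfg) {
  if (!inherits(cfg, "optical_config")) stop("`cfg` must be an optical_config")
  sb <- .check_evanescent(cfg)
  lambda_nm <- 1e7 / cfg$wavenumber
  lambda_nm / (2 * pi * sqrt(cfg$n1^2 * sb^2 - cfg$n2^2))
}

#' Relative squared interfacial electric-field amplitudes
#'
#' Squared amplitudes of the evanescent electric field at the reflecting
#' interface, relative to the incoming amplitude, in the two-phase
#' thick-film approximation with \eqn{n_{21} = n_2/n_1}:
#' \deqn{E_y^2 = \left[\frac{2\cos\beta}{\sqrt{1-n_{21}^2}}\right]^2}
#' \deqn{E_x^2 = \frac{[2\cos\beta\,\sqrt{\sin^2\beta-n_{21}^2}]^2}
#'   {(1-n_{21}^2)\,[(1+n_{21}^2)\sin^2\beta-n_{21}^2]}}
#' \deqn{E_z^2 = \frac{[2\cos\beta\,\sin\beta]^2}
#'   {(1-n_{21}^2)\,[(1+n_{21}^2)\sin^2\beta-n_{21}^2]}}
#' The interface is the xy plane and xz is the plane of incidence, so
#' s-polarised light probes \eqn{E_y} and p-polarised light probes
#' \eqn{E_x} and \eqn{E_z}.
#'
#' When the configuration carries a film index `n_film`, the three-phase
#' thin-film mode rescales the normal component by \eqn{(n_2/n_{film})^2},
#' accounting for the continuity of the normal displacement field across a
#' film much thinner than the penetration depth.
#'
#' @param cfg An [optical_config()].
#' @return A list of class `field_intensities` with elements `ex2`, `ey2`,
#'   `ez2` (dimensionless).
#' @export
interface_field_intensities <- function(cfg) {
  if (!inherits(cfg, "optical_config")) stop("`cfg` must be an optical_config")
  .check_evanescent(cfg)
  b <- cfg$beta_inc * pi / 180
  n21 <- cfg$n2 / cfg$n1
  s2 <- sin(b)^2
  cb <- cos(b)
  denom <- (1 - n21^2) * ((1 + n21^2) * s2 - n21^2)
  ey2 <- (2 * cb / sqrt(1 - n21^2))^2
  ex2 <- (2 * cb * sqrt(s2 - n21^2))^2 / denom
  ez2 <- (2 * cb * sin(b))^2 / denom
  if (!is.null(cfg$n_film)) ez2 <- ez2 * (cfg$n2 / cfg$n_film)^2
  structure(list(ex2 = ex2, ey2 = ey2, ez2 = ez2),
            class = "field_intensities")
}
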