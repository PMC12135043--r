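#' Transition-dipole order parameter from a dichroic ratio
#'
#' Under uniaxial symmetry about the interface normal, the dichroic ratio
#' \eqn{R} of a vibrational band and the interfacial field intensities give
#' an order parameter of the band's transition dipole moment (TDM):
#' \deqn{S_{dip} = \frac{E_x^2 - R E_y^2 + E_z^2}{E_x^2 - R E_y^2 - 2E_z^2}}
#' \eqn{S_{dip} = 1} means the TDM is along the normal, 0 the magic angle
#' (isotropic), and \eqn{-0.5} in-plane.
#'
#' Values that land outside \eqn{[-0.5, 1]} by less than `tol` (floating
#' point of an exact limit) are clamped with a warning; larger excursions
#' indicate inconsistent optics/ratio inputs and raise an error.
#'
#' @param R Dichroic ratio (integrated p-area / s-area), dimensionless.
#' @param f A `field_intensities` object from
#'   [interface_field_intensities()].
#' @param tol Clamping tolerance for numerically out-of-range results.
#' @return The order parameter `s_dip`, dimensionless in `[-0.5, 1]`.
#' @export
order_parameter_from_ratio <- function(R, f, tol = 1e-6) {
  if (!inherits(f, "field_intensities"))
    stop("`f` must be a field_intensities object")
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  u <- f$ex2 - R * f$ey2
  den <- u - 2 * f$ez2
  if (abs(den) < .Machine$double.eps)
    stop("degenerate optics: denominator Ex2 - R*Ey2 - 2*Ez2 is zero")
  s <- (u + f$ez2) / den
  if (s < -0.5 - tol || s > 1 + tol)
    stop("inconsistent optics/ratio: S_dip = ", format(s),
         " outside [-0.5, 1]")
  if (s < -0.5 || s > 1) {
    warning("S_dip clamped to [-0.5, 1] (numerical round-off)")
    s <- min(max(s, -0.5), 1)
  }
  s
}

#' Effective transition-dipole tilt angle from the order parameter
#'
#' Inverts \eqn{S = (3\langle\cos^2\theta\rangle - 1)/2} for a single
#' effective orientation:
#' \deqn{\theta_{dip} = \arccos\sqrt{(2 S_{dip} + 1)/3}}
#'
#' @param s_dip Order parameter in `[-0.5, 1]`.
#' @return Angle between the TDM and the interface normal, degrees in
#'   `[0, 90]`.
#' @export
dipole_angle <- function(s_dip) {
  stopifnot(is.numeric(s_dip), length(s_dip) == 1L)
  if (!is.finite(s_dip) || s_dip < -0.5 || s_dip > 1)
    stop("s_dip must lie in [-0.5, 1]")
  acos(sqrt((2 * s_dip + 1) / 3)) * 180 / pi
}

#' Acyl-chain tilt from two orthogonal transition-dipole angles
#'
#' The symmetric and antisymmetric CH2 stretching TDMs are perpendicular to
#' each other and to the chain axis, so their direction cosines with the
#' membrane normal satisfy
#' \deqn{\cos^2\theta_{tilt} + \cos^2\theta_{sym} + \cos^2\theta_{asym} = 1}
#' which yields the chain tilt directly from the two measured TDM angles.
#'
#' @param theta_sym Angle of the symmetric CH2 stretch TDM vs. the normal,
#'   degrees in `[0, 90]`.
#' @param theta_asym Angle of the antisymmetric CH2 stretch TDM, degrees in
#'   `[0, 90]`.
#' @param tol Tolerance on a slightly negative radicand before erroring.
#' @return A list of class `tilt_result` with elements `theta_tilt`,
#'   `theta_sym`, `theta_asym`, all in degrees.
#' @export
chain_tilt_from_tdm_angles <- function(theta_sym, theta_asym, tol = 1e-9) {
  stopifnot(is.numeric(theta_sym), is.numeric(theta_asym))
  if (theta_sym < 0 || theta_sym > 90 || theta_asym < 0 || theta_asym > 90)
    stop("TDM angles must lie in [0, 90] degrees")
  c2 <- 1 - cos(theta_sym * pi / 180)^2 - cos(theta_asym * pi / 180)^2
  if (c2 < -tol)
    stop("non-orthogonal TDM inputs: cos^2(sym) + cos^2(asym) > 1")
  c2 <- max(c2, 0)
  structure(list(theta_tilt = acos(sqrt(c2)) * 180 / pi,
                 theta_sym = theta_sym, theta_asym = theta_asym),
            class = "tilt_result")
}
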