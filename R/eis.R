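#' Single-frequency impedance sweep
#'
#' Imaginary impedance component vs. electrode potential, recorded at one
#' perturbation frequency on an electrode covered by a dielectric film.
#'
#' @param potential Potential in V vs. SCE.
#' @param frequency Perturbation frequency in Hz (scalar or per point),
#'   positive.
#' @param z_imag Imaginary impedance component in Ohm cm^2; negative for a
#'   capacitive response.
#' @return An object of class `impedance_sweep` (a data frame with columns
#'   `potential`, `frequency`, `z_imag`).
#' @export
impedance_sweep <- function(potential, frequency, z_imag) {
  stopifnot(is.numeric(potential), is.numeric(frequency), is.numeric(z_imag))
  n <- length(potential)
  frequency <- rep_len(frequency, n)
  if (length(z_imag) != n)
    stop("potential and z_imag must have equal length")
  if (any(frequency <= 0)) stop("frequency must be positive")
  structure(data.frame(potential = potential, frequency = frequency,
                       z_imag = z_imag),
            class = c("impedance_sweep", "data.frame"))
}

#' Read an impedance sweep from a delimited text file
#'
#' Expects three columns with header `potential_V,freq_Hz,z_imag_ohm_cm2`.
#'
#' @param path File path.
#' @return An [impedance_sweep()].
#' @export
read_impedance_sweep <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         comment.char = "#")
  impedance_sweep(d[[1L]], d[[2L]], d[[3L]])
}

#' Pseudocapacitance-potential curve from an impedance sweep
#'
#' Series-RC single-frequency model: the film capacitance at each
#' potential is
#' \deqn{C_{ps} = \frac{1}{2\pi f\,|Z''|}}
#' converted to uF/cm^2. No equivalent-circuit fitting is attempted; this
#' matches measurements that report only the imaginary component at one
#' frequency (typically 25 Hz).
#'
#' @param sweep An [impedance_sweep()]; `z_imag` must be nonzero at every
#'   potential.
#' @return An object of class `capacitance_curve`: a data frame with
#'   columns `potential` (V vs. SCE) and `c_ps` (uF/cm^2).
#' @export
pseudocapacitance_curve <- function(sweep) {
  if (!inherits(sweep, "impedance_sweep"))
    stop("`sweep` must be an impedance_sweep")
  bad <- which(sweep$z_imag == 0)
  if (length(bad))
    stop("zero imaginary impedance at potential(s) ",
         paste(format(sweep$potential[bad]), collapse = ", "))
  c_farad <- 1 / (2 * pi * sweep$frequency * abs(sweep$z_imag))  # F/cm^2
  structure(data.frame(potential = sweep$potential, c_ps = c_farad * 1e6),
            class = c("capacitance_curve", "data.frame"))
}

#' Relative dielectric thickness change from two capacitances
#'
#' For a parallel-plate dielectric of unchanged permittivity, capacitance
#' is inversely proportional to thickness, so a capacitance drop from
#' `c_ref` to `c_new` corresponds to a fractional thickness change
#' \deqn{\Delta d/d = (c_{ref}/c_{new} - 1) \times 100\%}
#' Positive values mean the film thickened (e.g. by adsorption of a
#' solute on the film surface).
#'
#' @param c_ref Reference capacitance, uF/cm^2, positive.
#' @param c_new New capacitance, uF/cm^2, positive.
#' @return Fractional thickness change in percent.
#' @export
thickness_change_from_capacitance <- function(c_ref, c_new) {
  stopifnot(is.numeric(c_ref), is.numeric(c_new))
  if (any(c_ref <= 0) || any(c_new <= 0))
    stop("capacitances must be positive")
  (c_ref / c_new - 1) * 100
}
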