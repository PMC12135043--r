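#' Langmuir compression isotherm
#'
#' Container for a surface pressure vs. area-per-molecule record measured at
#' constant temperature during monolayer compression.
#'
#' @param area_per_molecule Numeric vector, molecular area in A^2 per
#'   molecule. All values must be positive.
#' @param surface_pressure Numeric vector, surface pressure in mN/m, same
#'   length as `area_per_molecule`.
#' @param temperature Scalar temperature in degrees Celsius.
#' @param label Free-text description of the film and subphase.
#'
#' @return An object of class `isotherm`: a data frame with columns
#'   `area_per_molecule` and `surface_pressure`, and attributes
#'   `temperature` and `label`, sorted by decreasing area (the compression
#'   direction).
#' @export
isotherm <- function(area_per_molecule, surface_pressure,
                     temperature = 24, label = "") {
  stopifnot(is.numeric(area_per_molecule), is.numeric(surface_pressure))
  if (length(area_per_molecule) != length(surface_pressure))
    stop("area and surface-pressure series must have equal length")
  if (length(area_per_molecule) < 5L)
    stop("an isotherm needs at least 5 points")
  if (any(!is.finite(area_per_molecule)) || any(!is.finite(surface_pressure)))
    stop("non-finite values in isotherm")
  if (any(area_per_molecule <= 0))
    stop("all areas must be positive")
  ord <- order(area_per_molecule, decreasing = TRUE)
  out <- data.frame(area_per_molecule = area_per_molecule[ord],
                    surface_pressure  = surface_pressure[ord])
  structure(out, temperature = temperature, label = label,
            class = c("isotherm", "data.frame"))
}

#' Constant-area insertion trace
#'
#' Surface-pressure increase vs. time after injecting a solute under a
#' monolayer held at constant area and initial surface pressure `pi_zero`.
#'
#' @param time Numeric vector of times in seconds, strictly increasing,
#'   starting at 0.
#' @param delta_pi Numeric vector, surface-pressure increase in mN/m.
#' @param pi_zero Initial surface pressure pi0 in mN/m.
#' @param label Free-text description.
#'
#' @return An object of class `insertion_trace`: a data frame with columns
#'   `time` and `delta_pi` and attributes `pi_zero`, `label`.
#' @export
insertion_trace <- function(time, delta_pi, pi_zero, label = "") {
  stopifnot(is.numeric(time), is.numeric(delta_pi), is.numeric(pi_zero))
  if (length(time) != length(delta_pi))
    stop("time and delta_pi must have equal length")
  if (any(!is.finite(time)) || any(!is.finite(delta_pi)))
    stop("non-finite values in insertion trace")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (abs(time[1L]) > .Machine$double.eps)
    stop("trace must start at time 0")
  if (abs(delta_pi[1L]) > 0.5)
    warning("delta_pi(0) is not close to zero; check injection time origin")
  structure(data.frame(time = time, delta_pi = delta_pi),
            pi_zero = pi_zero, label = label,
            class = c("insertion_trace", "data.frame"))
}

#' Read an isotherm from a delimited text file
#'
#' Expects a two-column table with header `area_A2,pi_mN_m` (comma or tab
#' separated). Lines starting with `#` are treated as metadata comments of
#' the form `# key: value`; keys `temperature` and `label` are honoured.
#'
#' @param path File path.
#' @return An [isotherm()].
#' @export
read_isotherm <- function(path) {
  meta <- .read_header_meta(path)
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         comment.char = "#")
  isotherm(d[[1L]], d[[2L]],
           temperature = as.numeric(meta[["temperature"]] %||% 24),
           label = meta[["label"]] %||% "")
}

#' Read an insertion trace from a delimited text file
#'
#' Expects a two-column table with header `time_s,dpi_mN_m`; the initial
#' surface pressure must be given as a `# pi_zero: <value>` header comment
#' or via the `pi_zero` argument.
#'
#' @param path File path.
#' @param pi_zero Initial surface pressure in mN/m; overrides the header.
#' @return An [insertion_trace()].
#' @export
read_insertion_trace <- function(path, pi_zero = NULL) {
  meta <- .read_header_meta(path)
  d <- utils::read.table(path, header = TRUE, sep = .sniff_sep(path),
                         comment.char = "#")
  pz <- pi_zero %||% suppressWarnings(as.numeric(meta[["pi_zero"]]))
  if (length(pz) != 1L || !is.finite(pz))
    stop("pi_zero not found in header comments and not supplied")
  insertion_trace(d[[1L]], d[[2L]], pi_zero = pz,
                  label = meta[["label"]] %||% "")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.read_header_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (l in lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", l))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  meta
}

.sniff_sep <- function(path) {
  first <- readLines(path, n = 20L, warn = FALSE)
  first <- first[!startsWith(first, "#")][1L]
  if (grepl("\t", first)) "\t" else ","
}
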