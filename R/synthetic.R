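#' @name synthetic-data
#' @title Seeded synthetic-data generators
#' @description
#' Every input class the analysis functions consume can be generated with
#' known ground truth: two-phase compression isotherms, pseudo-first-order
#' insertion traces, polarized ATR spectra built from band parameters and
#' dipole-orientation-dependent p/s intensities, capacitance-derived
#' impedance sweeps, and toy bilayer trajectories with prescribed tilt,
#' chain order, probe position distribution and hydrogen-bond schedule.
#' Each generator is deterministic given its seed and returns the data
#' object together with a `truth` list echoing every ground-truth value.
#' The toy trajectories use ideal geometry, not a force field: they exist
#' to validate observable code, not physics.
NULL

# run `expr` under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a piecewise constant-modulus compression isotherm
#'
#' Forward model: over contiguous surface-pressure segments the area obeys
#' \eqn{A(\pi) = A_i \exp(-(\pi - \pi_i)/C_i)} with segment modulus
#' \eqn{C_i}, continuous at the joins. A liquid-expanded /
#' liquid-condensed transition is emulated by a low-modulus plateau
#' segment (the default dips to 5 mN/m around 20 mN/m). Gaussian noise is
#' added to the surface pressure.
#'
#' @param moduli Segment moduli \eqn{C_i} in mN/m (length m).
#' @param pi_breaks Interior segment boundaries in mN/m (length m - 1),
#'   strictly increasing.
#' @param pi_max Maximum surface pressure, mN/m.
#' @param a0 Area per molecule at zero pressure, A^2.
#' @param n Number of points.
#' @param noise_sd Gaussian noise s.d. on the pressure, mN/m.
#' @param area_shift Constant area offset in A^2 (emulates the isotherm
#'   shift when a solute is present in the subphase).
#' @param temperature Temperature label, degrees C.
#' @param seed Integer RNG seed.
#' @return List with elements `isotherm` (an [isotherm()]) and `truth`.
#' @export
gen_isotherm <- function(moduli = c(100, 5, 200), pi_breaks = c(19, 21),
                         pi_max = 45, a0 = 90, n = 400, noise_sd = 0,
                         area_shift = 0, temperature = 24, seed = 1) {
  m <- length(moduli)
  if (any(moduli <= 0)) stop("segment moduli must be positive")
  if (length(pi_breaks) != m - 1L)
    stop("need one interior break per segment boundary: ",
         "length(pi_breaks) must be length(moduli) - 1")
  if (m > 1L && (any(diff(pi_breaks) <= 0) || pi_breaks[1L] <= 0 ||
                 pi_breaks[length(pi_breaks)] >= pi_max))
    stop("pi_breaks must be strictly increasing inside (0, pi_max)")
  edges <- c(0, pi_breaks, pi_max)
  # segment start areas, continuous at the joins
  a_start <- numeric(m)
  a_start[1L] <- a0
  for (i in seq_len(m - 1L))
    a_start[i + 1L] <- a_start[i] * exp(-(edges[i + 1L] - edges[i]) / moduli[i])
  .with_seed(seed, {
    p <- seq(0, pi_max, length.out = n)
    seg <- findInterval(p, edges, rightmost.closed = TRUE)
    A <- a_start[seg] * exp(-(p - edges[seg]) / moduli[seg]) + area_shift
    p_obs <- p + stats::rnorm(n, 0, noise_sd)
    list(isotherm = isotherm(A, p_obs, temperature = temperature,
                             label = sprintf("synthetic %d-segment isotherm", m)),
         truth = list(moduli = moduli, pi_breaks = pi_breaks,
                      plateau_pressure = if (m == 3L) mean(pi_breaks) else NA_real_,
                      a0 = a0, area_shift = area_shift,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate pseudo-first-order insertion traces over several pi0 values
#'
#' Each trace follows \eqn{\Delta\pi(t) = \Delta\pi_{max}(\pi_0)(1 -
#' e^{-\beta t})} with the maximum response linear in the initial
#' pressure, \eqn{\Delta\pi_{max} = m\,\pi_0 + c}, so the exclusion
#' pressure ground truth is the abscissa intercept \eqn{-c/m}.
#'
#' @param pi_zeros Initial surface pressures, mN/m.
#' @param beta Pseudo-first-order rate constant, 1/s.
#' @param slope,intercept Parameters of the linear
#'   \eqn{\Delta\pi_{max}(\pi_0)} law (mN/m per mN/m, mN/m).
#' @param t_max Trace duration, s.
#' @param n Points per trace.
#' @param noise_sd Gaussian noise s.d., mN/m.
#' @param seed Integer RNG seed.
#' @return List with elements `traces` (list of [insertion_trace()]) and
#'   `truth` (including `pi_exclusion`).
#' @export
gen_insertion_traces <- function(pi_zeros = c(10, 20, 30, 40), beta = 0.01,
                                 slope = -0.2, intercept = 10,
                                 t_max = 600, n = 600, noise_sd = 0,
                                 seed = 1) {
  if (beta <= 0) stop("beta must be positive")
  .with_seed(seed, {
    traces <- lapply(pi_zeros, function(p0) {
      dmax <- slope * p0 + intercept
      t <- seq(0, t_max, length.out = n)
      y <- dmax * (1 - exp(-beta * t)) + stats::rnorm(n, 0, noise_sd)
      y[1L] <- 0   # injection time origin
      insertion_trace(t, y, pi_zero = p0,
                      label = sprintf("synthetic insertion, pi0 = %g", p0))
    })
    list(traces = traces,
         truth = list(beta = beta, slope = slope, intercept = intercept,
                      delta_pi_max = slope * pi_zeros + intercept,
                      pi_exclusion = -intercept / slope,
                      pi_zeros = pi_zeros, noise_sd = noise_sd, seed = seed))
  })
}

# orientation factor <cos^2 theta_dip> for a band: delta distribution or a
# Gaussian spread of tilt angles
.mean_cos2 <- function(theta_deg, orientation_sd = 0) {
  if (orientation_sd <= 0) return(cos(theta_deg * pi / 180)^2)
  th <- seq(0, 180, length.out = 2001L)
  w <- stats::dnorm(th, theta_deg, orientation_sd)
  sum(cos(th * pi / 180)^2 * w) / sum(w)
}

#' Generate a polarized ATR spectrum from band and orientation parameters
#'
#' Forward model of the dichroic analysis under uniaxial symmetry: a band
#' whose transition dipole makes angle `theta_dip` with the interface
#' normal (orientation factor \eqn{\langle\cos^2\theta\rangle}) absorbs
#' \deqn{A_p \propto E_x^2 (1 - \langle c^2\rangle)/2 +
#'       E_z^2 \langle c^2\rangle, \qquad
#'       A_s \propto E_y^2 (1 - \langle c^2\rangle)/2}
#' Bands are pseudo-Voigt; a polynomial baseline and Gaussian noise are
#' added per polarization.
#'
#' @param bands Data frame with columns `center` (1/cm), `width` (FWHM,
#'   1/cm), `shape_mix` in [0,1], `strength` (total oscillator strength,
#'   peak-height units) and `theta_dip` (degrees in [0, 90]).
#' @param cfg An [optical_config()] giving the field intensities.
#' @param wn_range Wavenumber range `c(lo, hi)`, 1/cm.
#' @param wn_step Grid step, 1/cm.
#' @param baseline_p,baseline_s Polynomial baseline coefficients
#'   (ascending powers of the wavenumber scaled to [-1, 1] over the range).
#' @param noise_sd Gaussian noise s.d., absorbance units.
#' @param orientation_sd Gaussian spread of the dipole tilt, degrees
#'   (0 = delta orientation).
#' @param seed Integer RNG seed.
#' @return List with `spectrum` (a [polarized_spectrum()]), `fields`, and
#'   `truth` (per-band dichroic ratio, order parameter and amplitudes).
#' @export
gen_polarized_spectra <- function(bands, cfg = optical_config(),
                                  wn_range = c(2800, 3000), wn_step = 0.5,
                                  baseline_p = 0, baseline_s = 0,
                                  noise_sd = 0, orientation_sd = 0,
                                  seed = 1) {
  stopifnot(is.data.frame(bands),
            all(c("center", "width", "shape_mix", "strength",
                  "theta_dip") %in% names(bands)))
  if (any(bands$theta_dip < 0 | bands$theta_dip > 90))
    stop("theta_dip must lie in [0, 90] degrees")
  if (any(bands$center < wn_range[1L] | bands$center > wn_range[2L]))
    stop("band center outside the wavenumber range")
  f <- interface_field_intensities(cfg)
  c2 <- vapply(bands$theta_dip, .mean_cos2, numeric(1L),
               orientation_sd = orientation_sd)
  amp_p <- bands$strength * (f$ex2 * (1 - c2) / 2 + f$ez2 * c2)
  amp_s <- bands$strength * (f$ey2 * (1 - c2) / 2)
  r_true <- amp_p / amp_s
  .with_seed(seed, {
    wn <- seq(wn_range[1L], wn_range[2L], by = wn_step)
    u <- (wn - mean(wn_range)) / (diff(wn_range) / 2)
    bl <- function(coefs) drop(outer(u, seq_along(coefs) - 1L, `^`) %*% coefs)
    yp <- bl(baseline_p); ys <- bl(baseline_s)
    for (k in seq_len(nrow(bands))) {
      prof <- pseudo_voigt(wn, bands$center[k], bands$width[k],
                           bands$shape_mix[k])
      yp <- yp + amp_p[k] * prof
      ys <- ys + amp_s[k] * prof
    }
    yp <- yp + stats::rnorm(length(wn), 0, noise_sd)
    ys <- ys + stats::rnorm(length(wn), 0, noise_sd)
    list(spectrum = polarized_spectrum(wn, yp, ys),
         fields = f,
         truth = list(theta_dip = bands$theta_dip,
                      mean_cos2 = c2,
                      dichroic_ratio = r_true,
                      s_dip = (3 * c2 - 1) / 2,
                      amplitude_p = amp_p, amplitude_s = amp_s,
                      center = bands$center, width = bands$width,
                      shape_mix = bands$shape_mix,
                      orientation_sd = orientation_sd,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a single-frequency impedance sweep from a capacitance profile
#'
#' Inverts the series-RC relation: \eqn{Z''(E) = -1/(2\pi f\,C(E))} for a
#' prescribed smooth capacitance-potential profile (a constant plus an
#' optional Gaussian defect peak), with Gaussian noise on the impedance.
#'
#' @param potentials Potential grid, V vs. SCE.
#' @param freq Measurement frequency, Hz.
#' @param c_base Baseline capacitance, uF/cm^2.
#' @param defect_amp,defect_center,defect_width Optional Gaussian peak on
#'   the capacitance (uF/cm^2, V, V); `defect_amp = 0` disables it.
#' @param noise_sd Gaussian noise s.d. on the impedance, Ohm cm^2.
#' @param seed Integer RNG seed.
#' @return List with `sweep` (an [impedance_sweep()]) and `truth` (the
#'   prescribed `c_ps` at each potential).
#' @export
gen_eis_sweep <- function(potentials = seq(-1.0, 0.4, by = 0.02), freq = 25,
                          c_base = 1.44, defect_amp = 0, defect_center = 0.2,
                          defect_width = 0.1, noise_sd = 0, seed = 1) {
  c_true <- c_base + defect_amp *
    exp(-0.5 * ((potentials - defect_center) / defect_width)^2)
  if (any(c_true <= 0)) stop("prescribed capacitance must be positive")
  .with_seed(seed, {
    z <- -1 / (2 * pi * freq * c_true * 1e-6) +
      stats::rnorm(length(potentials), 0, noise_sd)
    list(sweep = impedance_sweep(potentials, freq, z),
         truth = list(c_ps = c_true, freq = freq, c_base = c_base,
                      defect_amp = defect_amp, noise_sd = noise_sd,
                      seed = seed))
  })
}

# rotation matrix: tilt by alpha about an axis with azimuth phi, after a
# self-rotation psi about the chain axis (all radians)
.chain_rotation <- function(alpha, phi, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L)
  rz(phi) %*% ry(alpha) %*% rz(psi)
}

#' Generate a toy bilayer trajectory with prescribed ground truth
#'
#' Builds two mirrored leaflets of idealized all-trans zig-zag chains
#' (explicit hydrogens at ideal tetrahedral geometry, C-C 1.54 A, rise
#' 1.257 A) on a square lattice. Per lipid and frame, the chain tilt is
#' drawn from a folded Gaussian with prescribed mean and s.d., with
#' uniform tilt azimuth and uniform self-rotation about the chain axis, so
#' the analytic relation \eqn{S_{CD} = (3\sin^2\alpha/2 - 1)/2} holds for
#' a fixed tilt \eqn{\alpha}.
#'
#' The system optionally carries (i) a rigid O-H probe whose per-frame z
#' position is drawn from a prescribed normal or uniform distribution
#' around the membrane center, and (ii) a static O-H donor with two
#' acceptor oxygens on a deterministic hydrogen-bond schedule: acceptor 1
#' is bonded in every frame; acceptor 2 is bonded in frames where
#' `frame %% hbond_period == 1` (i.e. in `1/hbond_period` of the frames),
#' and is otherwise displaced beyond the distance cutoff.
#'
#' @param lipids_per_leaflet Lipids per leaflet (>= 4), placed on a square
#'   lattice.
#' @param n_carbons Chain carbons per lipid. An odd count keeps the first
#'   and last carbons on the same side of the zig-zag, so the
#'   first-to-last-carbon vector used by [tilt_distribution()] coincides
#'   exactly with the chain axis; an even count introduces a small
#'   (~arctan(0.9 A / chain length)) definitional offset, as it does in
#'   real chains.
#' @param n_frames Number of frames (>= 2).
#' @param tilt_mean,tilt_sd Folded-Gaussian tilt parameters, degrees.
#' @param spacing Lattice spacing, Angstrom (>= 4.5 to avoid overlap).
#' @param probe_z List describing the probe z distribution relative to the
#'   membrane center: `list(dist = "normal", mean, sd)` or
#'   `list(dist = "uniform", min, max)`; `NULL` omits the probe.
#' @param hbond_period Period of the second scheduled hydrogen bond
#'   (2 = every other frame); `NULL` omits the donor/acceptor block.
#' @param seed Integer RNG seed.
#' @return List with `trajectory`, `topology` and `truth`.
#' @export
gen_bilayer_trajectory <- function(lipids_per_leaflet = 8, n_carbons = 9,
                                   n_frames = 200, tilt_mean = 33,
                                   tilt_sd = 5, spacing = 10,
                                   probe_z = list(dist = "normal",
                                                  mean = 15, sd = 3),
                                   hbond_period = 2, seed = 1) {
  if (lipids_per_leaflet < 4L) stop("need at least 4 lipids per leaflet")
  if (n_frames < 2L) stop("need at least 2 frames")
  if (spacing < 4.5)
    stop("lattice spacing below 4.5 A would overlap neighbouring chains")
  bond_cc <- 1.54; bond_ch <- 1.09
  half_ccc <- 0.5 * 109.47 * pi / 180
  dz <- bond_cc * sin(half_ccc)        # 1.2573 A rise per carbon
  off <- bond_cc * cos(half_ccc) / 2   # 0.4445 A lateral alternation

  # local chain template: carbons along +z, C1 at the origin
  nc <- n_carbons
  c_local <- cbind(off * (-1)^(seq_len(nc) - 1L), 0, (seq_len(nc) - 1L) * dz)
  h_local <- vector("list", nc)
  for (k in seq_len(nc)) {
    b <- c((-1)^(k - 1L), 0, 0)        # midpoint -> carbon direction
    w <- c(0, 1, 0)
    h1 <- c_local[k, ] + bond_ch * (cos(half_ccc) * b + sin(half_ccc) * w)
    h2 <- c_local[k, ] + bond_ch * (cos(half_ccc) * b - sin(half_ccc) * w)
    h_local[[k]] <- rbind(h1, h2)
  }

  nside <- ceiling(sqrt(lipids_per_leaflet))
  lat <- expand.grid(ix = seq_len(nside), iy = seq_len(nside))
  lat <- lat[seq_len(lipids_per_leaflet), , drop = FALSE]
  chain_len <- (nc - 1L) * dz
  box_xy <- nside * spacing
  box_z <- 2 * (chain_len + 5) + 40

  # topology assembly -------------------------------------------------
  atoms <- list(); resid <- 0L
  add_lipid <- function(leaflet) {
    resid <<- resid + 1L
    per <- data.frame(
      name = c(paste0("C", seq_len(nc)),
               paste0("H", rep(seq_len(nc), each = 2L), rep(c("A", "B"), nc)),
               "P1"),
      resname = "LIP", resid = resid,
      group = c(rep("chain", nc), rep("chainH", 2L * nc), "head"),
      charge = c(rep(0, 3L * nc), -0.2),
      sigma = c(rep(3.40, nc), rep(2.60, 2L * nc), 3.74),
      epsilon = c(rep(0.086, nc), rep(0.015, 2L * nc), 0.20),
      mass = c(rep(12.011, nc), rep(1.008, 2L * nc), 94.97))
    per$leaflet <- leaflet
    atoms[[length(atoms) + 1L]] <<- per
  }
  for (l in seq_len(lipids_per_leaflet)) add_lipid("upper")
  for (l in seq_len(lipids_per_leaflet)) add_lipid("lower")
  n_lipid_res <- 2L * lipids_per_leaflet

  has_probe <- !is.null(probe_z)
  if (has_probe) {
    resid <- resid + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = c("O1", "H1"), resname = "PRB", resid = resid,
      group = "probe", charge = c(-0.50, 0.30),
      sigma = c(3.07, 0.40), epsilon = c(0.152, 0.046),
      mass = c(15.999, 1.008), leaflet = "none")
  }
  has_hb <- !is.null(hbond_period)
  if (has_hb) {
    resid <- resid + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = c("OD", "HD"), resname = "DON", resid = resid,
      group = "donor", charge = c(-0.50, 0.30),
      sigma = c(3.07, 0.40), epsilon = c(0.152, 0.046),
      mass = c(15.999, 1.008), leaflet = "none")
    resid <- resid + 1L
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = c("OA1", "OA2"), resname = "ACC", resid = resid,
      group = "acceptor", charge = c(-0.40, -0.40),
      sigma = c(3.07, 3.07), epsilon = c(0.152, 0.152),
      mass = c(15.999, 15.999), leaflet = "none")
  }
  at <- do.call(rbind, atoms)
  leaflet_col <- at$leaflet
  at$leaflet <- NULL
  rownames(at) <- NULL
  n_atoms <- nrow(at)

  sels <- list(
    chains = which(at$group == "chain"),
    chain_hydrogens = which(at$group == "chainH"),
    heads = which(at$group == "head"),
    lipids = which(at$resname == "LIP"),
    upper_chains = which(at$group == "chain" & leaflet_col == "upper"),
    lower_chains = which(at$group == "chain" & leaflet_col == "lower"))
  if (has_probe) sels$probe <- which(at$group == "probe")
  if (has_hb) {
    sels$donors <- which(at$name == "OD")
    sels$acceptors <- which(at$group == "acceptor")
  }
  topo <- topology(at, sels)

  # per-lipid atom index blocks, in construction order
  lipid_rows <- split(seq_len(n_atoms)[at$resname == "LIP"],
                      at$resid[at$resname == "LIP"])

  .with_seed(seed, {
    coords <- array(NA_real_, dim = c(n_atoms, 3L, n_frames))
    tilt_draws <- matrix(abs(stats::rnorm(n_lipid_res * n_frames,
                                          tilt_mean, tilt_sd)),
                         n_lipid_res, n_frames) * pi / 180
    phi_draws <- matrix(stats::runif(n_lipid_res * n_frames, 0, 2 * pi),
                        n_lipid_res, n_frames)
    psi_draws <- matrix(stats::runif(n_lipid_res * n_frames, 0, 2 * pi),
                        n_lipid_res, n_frames)
    probe_zs <- if (has_probe) {
      if (probe_z$dist == "normal") stats::rnorm(n_frames, probe_z$mean, probe_z$sd)
      else stats::runif(n_frames, probe_z$min, probe_z$max)
    } else NULL

    template <- rbind(c_local, do.call(rbind, h_local))  # carbons then H's
    # reorder H rows to match topology order H1A,H1B,H2A,H2B,...
    # (h_local already yields that order)
    for (f in seq_len(n_frames)) {
      for (r in seq_len(n_lipid_res)) {
        upper <- r <= lipids_per_leaflet
        li <- if (upper) r else r - lipids_per_leaflet
        base <- c((lat$ix[li] - 0.5) * spacing - box_xy / 2,
                  (lat$iy[li] - 0.5) * spacing - box_xy / 2,
                  if (upper) 1 else -1)
        R <- .chain_rotation(tilt_draws[r, f], phi_draws[r, f], psi_draws[r, f])
        xyz <- template %*% t(R)
        if (!upper) xyz[, 3L] <- -xyz[, 3L]    # mirror the lower leaflet
        xyz <- sweep(xyz, 2L, base, `+`)
        rows <- lipid_rows[[r]]
        # topology order: C1..Cn, H1A..HnB, P1; template holds C then H
        coords[rows[seq_len(3L * nc)], , f] <- xyz
        coords[rows[3L * nc + 1L], , f] <-
          base + c(0, 0, if (upper) -1.5 else 1.5)  # head below first carbon
      }
      if (has_probe) {
        io <- sels$probe
        o <- c(box_xy / 4, box_xy / 4, probe_zs[f])
        coords[io[1L], , f] <- o
        coords[io[2L], , f] <- o + c(0.96, 0, 0)
      }
      if (has_hb) {
        od <- sels$donors; oa <- sels$acceptors
        d0 <- c(-box_xy / 4, -box_xy / 4, chain_len + 12)
        coords[od, , f] <- d0
        coords[topo$selections$donors + 1L, , f] <- d0 + c(0.96, 0, 0) # HD
        coords[oa[1L], , f] <- d0 + c(2.80, 0, 0)   # always bonded
        bonded2 <- (f %% hbond_period) == 1L || hbond_period == 1L
        coords[oa[2L], , f] <- if (bonded2)
          d0 + 2.60 * c(cos(20 * pi / 180), sin(20 * pi / 180), 0)
        else d0 + c(0, 0, 8)                        # far beyond the cutoff
      }
    }
    traj <- trajectory(coords, c(box_xy, box_xy, box_z))
    hb_frac2 <- if (has_hb) sum((seq_len(n_frames) %% hbond_period) == 1L |
                                hbond_period == 1L) / n_frames else NA_real_
    list(trajectory = traj, topology = topo,
         truth = list(tilt_mean = tilt_mean, tilt_sd = tilt_sd,
                      n_carbons = n_carbons,
                      lipids_per_leaflet = lipids_per_leaflet,
                      n_frames = n_frames,
                      probe_z = probe_z,
                      hbond_period = hbond_period,
                      hbond_fraction_expected = if (has_hb)
                        1 + hb_frac2 else NA_real_,
                      box = c(box_xy, box_xy, box_z), seed = seed))
  })
}
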