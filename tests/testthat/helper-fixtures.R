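# shared fixtures and independent oracles

# brute-force all-pairs nonbonded oracle (double loop, minimum image),
# restricted to molecules of B with any atom within the cutoff of A
brute_force_energy <- function(xyz, box, at, ia, ib, cutoff) {
  mind <- function(i, j) {
    d <- xyz[i, ] - xyz[j, ]
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }
  within <- vapply(ib, function(j)
    any(vapply(ia, function(i) mind(i, j) <= cutoff, logical(1L))),
    logical(1L))
  keep <- ib[at$resid[ib] %in% unique(at$resid[ib][within])]
  elec <- 0; vdw <- 0
  for (i in ia) for (j in keep) {
    r <- mind(i, j)
    elec <- elec + 332.0636 * at$charge[i] * at$charge[j] / r
    s <- (at$sigma[i] + at$sigma[j]) / 2
    e <- sqrt(at$epsilon[i] * at$epsilon[j])
    vdw <- vdw + 4 * e * ((s / r)^12 - (s / r)^6)
  }
  c(elec = elec, vdw = vdw)
}

# random topology/frame for energy tests: one 10-atom molecule A and
# several 5-atom molecules B in a periodic box
random_energy_system <- function(n_atoms, box_len = 30, seed = 1) {
  set.seed(seed)
  nb <- n_atoms - 10L
  at <- data.frame(
    name = paste0("X", seq_len(n_atoms)),
    resname = rep(c("A", "B"), c(10L, nb)),
    resid = c(rep(1L, 10L), rep(seq_len(ceiling(nb / 5)) + 1L, each = 5L)[seq_len(nb)]),
    group = "g",
    charge = round(runif(n_atoms, -0.5, 0.5), 3),
    sigma = round(runif(n_atoms, 2.5, 3.5), 3),
    epsilon = round(runif(n_atoms, 0.05, 0.2), 3),
    mass = 12)
  xyz <- matrix(runif(n_atoms * 3, 0, box_len), n_atoms, 3)
  list(topo = topology(at, list(A = 1:10, B = 11:n_atoms)),
       xyz = xyz, at = at,
       traj = trajectory(list(xyz), rep(box_len, 3)))
}

# minimal two-atom probe/reference system with prescribed per-frame
# z-separations
two_atom_z_system <- function(dz, box = c(40, 40, 60)) {
  at <- data.frame(name = c("O1", "C1"), resname = c("PRB", "REF"),
                   resid = 1:2, group = c("probe", "ref"),
                   charge = 0, sigma = 3, epsilon = 0.1, mass = c(16, 12))
  n <- length(dz)
  coords <- array(0, dim = c(2, 3, n))
  coords[1, 3, ] <- dz
  list(topo = topology(at, list(probe = 1L, ref = 2L)),
       traj = trajectory(coords, box))
}

# log-linearised regression oracle for the pseudo-first-order model:
# log(dmax - dpi) = log(dmax) - beta*t, using the true plateau
loglin_kinetics_oracle <- function(t, y, dmax_true) {
  ok <- y < dmax_true & t > 0
  fit <- stats::lm(log(dmax_true - y[ok]) ~ t[ok])
  -unname(stats::coef(fit)[2L])
}

# closed-form integrated area of an amp-height pseudo-Voigt band
.pv_area_for_test <- function(amp, width, mix) {
  amp * width * ((1 - mix) * 0.5 * sqrt(pi / log(2)) + mix * pi / 2)
}
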