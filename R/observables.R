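#' Probe z-separation distribution
#'
#' For every frame, the signed z-separation between the mass-weighted
#' centers of a probe selection and a reference selection is recorded and
#' histogrammed into a probability density. When `n_closest` is given, the
#' reference is re-selected each frame as the `n_closest` reference
#' residues (e.g. lipids) whose centers of mass lie closest to the probe,
#' mirroring the "closest interacting lipids" convention of
#' membrane-adsorption analyses.
#'
#' @param traj A [trajectory()].
#' @param topo A [topology()].
#' @param probe_selection,reference_selection Selections resolvable by
#'   [select_atoms()].
#' @param bin_width Histogram bin width, Angstrom.
#' @param n_closest Optional count of closest reference residues to keep
#'   per frame; `NULL` uses the whole reference selection.
#' @return An object of class `distance_distribution`: list with `breaks`
#'   (bin edges, A), `density` (1/A, integrates to 1), `dz` (per-frame
#'   separations) and `mean`.
#' @export
z_distance_distribution <- function(traj, topo, probe_selection,
                                    reference_selection, bin_width = 1,
                                    n_closest = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  if (bin_width <= 0) stop("bin_width must be positive")
  ip <- select_atoms(topo, probe_selection)
  ir <- select_atoms(topo, reference_selection)
  mass <- topo$atoms$mass
  ref_resid <- topo$atoms$resid[ir]
  dz <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    com_p <- .center_of_mass(xyz[ip, , drop = FALSE], mass[ip])
    if (is.null(n_closest)) {
      keep <- ir
    } else {
      resids <- unique(ref_resid)
      if (n_closest > length(resids))
        stop("n_closest exceeds the number of reference residues")
      d2 <- vapply(resids, function(rr) {
        idx <- ir[ref_resid == rr]
        dxv <- .min_image(.center_of_mass(xyz[idx, , drop = FALSE], mass[idx]) - com_p,
                          traj$box[f, ])
        sum(dxv^2)
      }, numeric(1L))
      keep <- ir[ref_resid %in% resids[order(d2)][seq_len(n_closest)]]
    }
    com_r <- .center_of_mass(xyz[keep, , drop = FALSE], mass[keep])
    dz[f] <- com_p[3L] - com_r[3L]
  }
  lo <- floor(min(dz) / bin_width) * bin_width
  hi <- ceiling(max(dz) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(dz, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, density = h$density, dz = dz,
                 mean = mean(dz)),
            class = "distance_distribution")
}

# hydrogens covalently bound to a heavy atom: same residue, within bond_max
# of the heavy atom in the given frame (minimum image), and light
# (mass < 3.5 amu)
.bonded_hydrogens <- function(xyz, topo, heavy_idx, box, bond_max = 1.25) {
  at <- topo$atoms
  cand <- which(at$resid == at$resid[heavy_idx] & at$mass < 3.5)
  cand <- setdiff(cand, heavy_idx)
  if (length(cand) == 0L) return(integer(0))
  dx <- .min_image(xyz[cand, , drop = FALSE] -
                   matrix(xyz[heavy_idx, ], length(cand), 3L, byrow = TRUE), box)
  cand[sqrt(rowSums(dx^2)) <= bond_max]
}

#' Hydrogen-bond time fractions per donor
#'
#' A hydrogen bond exists in a frame when the donor-heavy to acceptor
#' distance is at most `d_max` and the D-H...A angle is at least
#' `angle_min`. For each donor heavy atom the reported fraction is the
#' total number of simultaneous bonds summed over frames, divided by the
#' number of frames — so a group holding one permanent bond plus a second
#' bond half of the time reports 1.5, and values above 1 are meaningful
#' (multiple simultaneous bonds).
#'
#' @param traj A [trajectory()].
#' @param topo A [topology()].
#' @param donors Selection of donor heavy atoms; each must carry at least
#'   one covalently bound hydrogen.
#' @param acceptors Selection of acceptor heavy atoms.
#' @param d_max Donor-acceptor distance cutoff, Angstrom.
#' @param angle_min Minimum D-H...A angle, degrees.
#' @return An object of class `hbond_report`: a data frame with one row
#'   per donor (`donor` index, `name`, `resid`, `fraction`).
#' @export
hbond_time_fractions <- function(traj, topo, donors, acceptors,
                                 d_max = 3.5, angle_min = 135) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  idon <- select_atoms(topo, donors)
  iacc <- select_atoms(topo, acceptors)
  xyz1 <- traj$coords[, , 1L]
  hyd <- lapply(idon, function(i)
    .bonded_hydrogens(xyz1, topo, i, traj$box[1L, ]))
  no_h <- idon[lengths(hyd) == 0L]
  if (length(no_h))
    stop("donor atom(s) without a bonded hydrogen: ",
         paste(no_h, collapse = ", "))
  cos_min <- cos(angle_min * pi / 180)
  counts <- numeric(length(idon))
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    box <- traj$box[f, ]
    for (k in seq_along(idon)) {
      d_at <- idon[k]
      acc <- setdiff(iacc, c(d_at, hyd[[k]]))
      if (length(acc) == 0L) next
      dda <- .min_image(xyz[acc, , drop = FALSE] -
                        matrix(xyz[d_at, ], length(acc), 3L, byrow = TRUE), box)
      rda <- sqrt(rowSums(dda^2))
      close_acc <- acc[rda <= d_max]
      if (length(close_acc) == 0L) next
      for (a_at in close_acc) {
        for (h_at in hyd[[k]]) {
          hd <- .min_image(xyz[d_at, ] - xyz[h_at, ], box)
          ha <- .min_image(xyz[a_at, ] - xyz[h_at, ], box)
          ct <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
          # D-H...A angle >= angle_min  <=>  cos(angle) <= cos(angle_min)
          if (ct <= cos_min) counts[k] <- counts[k] + 1
        }
      }
    }
  }
  structure(data.frame(donor = idon,
                       name = topo$atoms$name[idon],
                       resid = topo$atoms$resid[idon],
                       fraction = counts / traj$n_frames),
            class = c("hbond_report", "data.frame"))
}

# ideal tetrahedral C-H unit vectors for carbon k reconstructed from the
# neighbouring carbons; returns a 2 x 3 matrix of unit vectors
.reconstruct_ch <- function(r_prev, r_k, r_next) {
  u <- r_next - r_prev; u <- u / sqrt(sum(u^2))
  b <- r_k - (r_prev + r_next) / 2
  b <- b - sum(b * u) * u
  nb <- sqrt(sum(b^2))
  if (nb < 1e-8) stop("degenerate chain geometry: cannot reconstruct hydrogens")
  b <- b / nb
  w <- c(u[2L] * b[3L] - u[3L] * b[2L],
         u[3L] * b[1L] - u[1L] * b[3L],
         u[1L] * b[2L] - u[2L] * b[1L])
  half <- 0.5 * 109.47 * pi / 180
  rbind(cos(half) * b + sin(half) * w,
        cos(half) * b - sin(half) * w)
}

#' Deuterium order parameter profile of acyl chains
#'
#' For each acyl carbon index k the deuterium order parameter
#' \deqn{S_{CD}(k) = \left\langle \frac{3\cos^2\theta_{CH} - 1}{2} \right\rangle}
#' is averaged over lipids, frames, and the two C-H bonds of the carbon,
#' with \eqn{\theta_{CH}} the angle between the C-H bond and the bilayer
#' normal (the box z-axis). \eqn{S_{CD} = -0.5} for an all-trans chain
#' along the normal, 0 for isotropic orientation.
#'
#' Carbon indices are read from the digits of the atom names (C2, C3, ...).
#' Hydrogens are located by covalent distance; carbons without explicit
#' hydrogens raise an error unless `reconstruct_h = TRUE`, in which case
#' ideal tetrahedral hydrogens are rebuilt from the neighbouring carbons
#' (interior carbons only).
#'
#' @param traj A [trajectory()].
#' @param topo A [topology()].
#' @param chain_selection Selection of acyl-chain carbon atoms.
#' @param reconstruct_h Rebuild missing hydrogens at ideal geometry.
#' @param absolute Report `|SCD|` (a common presentation convention).
#' @return An object of class `order_profile`: data frame with columns
#'   `carbon` (index along the chain) and `scd`.
#' @export
scd_profile <- function(traj, topo, chain_selection, reconstruct_h = FALSE,
                        absolute = FALSE) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  ic <- select_atoms(topo, chain_selection)
  at <- topo$atoms
  cidx <- suppressWarnings(as.integer(gsub("\\D", "", at$name[ic])))
  if (any(is.na(cidx)))
    stop("chain carbon names must carry a numeric index (C1, C2, ...)")
  xyz1 <- traj$coords[, , 1L]
  hyd <- lapply(ic, function(i)
    .bonded_hydrogens(xyz1, topo, i, traj$box[1L, ]))
  # neighbour carbons within the same residue, for reconstruction
  sums <- numeric(max(cidx)); nobs <- numeric(max(cidx))
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    for (k in seq_along(ic)) {
      i <- ic[k]
      if (length(hyd[[k]])) {
        ch <- .min_image(xyz[hyd[[k]], , drop = FALSE] -
          matrix(xyz[i, ], length(hyd[[k]]), 3L, byrow = TRUE), traj$box[f, ])
        cz2 <- (ch[, 3L]^2) / rowSums(ch^2)
      } else {
        if (!reconstruct_h)
          stop("carbon atom ", i, " has no bonded hydrogens; ",
               "set reconstruct_h = TRUE to rebuild them")
        same <- ic[at$resid[ic] == at$resid[i]]
        prev <- same[cidx[match(same, ic)] == cidx[k] - 1L]
        nxt <- same[cidx[match(same, ic)] == cidx[k] + 1L]
        if (length(prev) != 1L || length(nxt) != 1L) next  # terminal carbon
        rp <- xyz[i, ] + .min_image(xyz[prev, ] - xyz[i, ], traj$box[f, ])
        rn <- xyz[i, ] + .min_image(xyz[nxt, ] - xyz[i, ], traj$box[f, ])
        chu <- .reconstruct_ch(rp, xyz[i, ], rn)
        cz2 <- chu[, 3L]^2
      }
      sums[cidx[k]] <- sums[cidx[k]] + sum((3 * cz2 - 1) / 2)
      nobs[cidx[k]] <- nobs[cidx[k]] + length(cz2)
    }
  }
  keep <- which(nobs > 0)
  scd <- sums[keep] / nobs[keep]
  if (absolute) scd <- abs(scd)
  structure(data.frame(carbon = keep, scd = scd),
            class = c("order_profile", "data.frame"))
}

#' Chain tilt-angle distribution
#'
#' Per lipid and frame, the angle between the chain vector (first to last
#' tail carbon, ordered by the numeric index in the atom names) and the
#' +z bilayer normal. Measured against a single normal, a symmetric
#' bilayer gives a two-peak distribution on [0, 180] degrees (one peak per
#' leaflet); `fold = TRUE` maps each angle to `min(theta, 180 - theta)`.
#'
#' @param traj A [trajectory()].
#' @param topo A [topology()].
#' @param chain_selection Selection of tail carbon atoms; each residue in
#'   it must contribute at least 2 atoms.
#' @param bin_width Histogram bin width, degrees.
#' @param fold Fold the distribution onto [0, 90] degrees.
#' @return An object of class `tilt_distribution`: list with `breaks`,
#'   `density` (1/degree, integrates to 1), `angles` (per lipid-frame,
#'   degrees) and `mean`.
#' @export
tilt_distribution <- function(traj, topo, chain_selection, bin_width = 2,
                              fold = FALSE) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  ic <- select_atoms(topo, chain_selection)
  at <- topo$atoms
  cidx <- suppressWarnings(as.integer(gsub("\\D", "", at$name[ic])))
  resids <- unique(at$resid[ic])
  ends <- lapply(resids, function(rr) {
    idx <- ic[at$resid[ic] == rr]
    if (length(idx) < 2L)
      stop("residue ", rr, " has fewer than 2 chain atoms")
    ki <- cidx[match(idx, ic)]
    c(idx[which.min(ki)], idx[which.max(ki)])
  })
  angles <- numeric(0)
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    a <- vapply(ends, function(e) {
      v <- .min_image(xyz[e[2L], ] - xyz[e[1L], ], traj$box[f, ])
      nv <- sqrt(sum(v^2))
      if (nv < 1e-8) stop("degenerate zero-length chain vector")
      acos(max(-1, min(1, v[3L] / nv))) * 180 / pi
    }, numeric(1L))
    angles <- c(angles, a)
  }
  if (fold) angles <- pmin(angles, 180 - angles)
  top <- if (fold) 90 else 180
  breaks <- seq(0, top, by = bin_width)
  if (breaks[length(breaks)] < top) breaks <- c(breaks, top)
  h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, density = h$density, angles = angles,
                 mean = mean(angles)),
            class = "tilt_distribution")
}

# Coulomb constant in kcal * Angstrom / (mol * e^2)
.COULOMB_K <- 332.0636

#' Cutoff-sphere nonbonded interaction energy
#'
#' Per frame, the classical nonbonded interaction energy between selection
#' A and the molecules (residues) of selection B that have at least one
#' atom within `cutoff` of any atom of A. Included molecules contribute
#' with all their selected atoms:
#' electrostatics \eqn{\sum 332.0636\, q_i q_j / r_{ij}} (kcal/mol) and
#' Lennard-Jones \eqn{\sum 4\epsilon_{ij}[(\sigma_{ij}/r_{ij})^{12} -
#' (\sigma_{ij}/r_{ij})^6]} with Lorentz-Berthelot combining
#' (\eqn{\sigma_{ij}} arithmetic, \eqn{\epsilon_{ij}} geometric mean).
#' All distances use the minimum-image convention under the frame box;
#' the cutoff truncates hard (no switching function).
#'
#' @param traj A [trajectory()].
#' @param topo A [topology()]; charges and LJ parameters must be present
#'   (non-NA) for every atom of both selections.
#' @param selection_a,selection_b Disjoint selections.
#' @param cutoff Inclusion radius for molecules of B, Angstrom.
#' @return An object of class `energy_trace`: data frame with columns
#'   `frame`, `electrostatic` and `vdw` (kcal/mol).
#' @export
pairwise_interaction_energy <- function(traj, topo, selection_a, selection_b,
                                        cutoff = 12) {
  stopifnot(inherits(traj, "trajectory"), inherits(topo, "topology"))
  ia <- select_atoms(topo, selection_a)
  ib <- select_atoms(topo, selection_b)
  if (length(intersect(ia, ib)))
    stop("selections A and B overlap; intra-selection energies are not computed")
  at <- topo$atoms
  bad <- c(ia, ib)[!is.finite(at$charge[c(ia, ib)]) |
                   !is.finite(at$sigma[c(ia, ib)]) |
                   !is.finite(at$epsilon[c(ia, ib)])]
  if (length(bad))
    stop("missing nonbonded parameters for atom(s): ",
         paste(bad, collapse = ", "))
  qa <- at$charge[ia]; qb <- at$charge[ib]
  sa <- at$sigma[ia]; sb <- at$sigma[ib]
  ea <- at$epsilon[ia]; eb <- at$epsilon[ib]
  sij <- outer(sa, sb, function(x, y) (x + y) / 2)
  eij <- outer(ea, eb, function(x, y) sqrt(x * y))
  qq <- outer(qa, qb)
  resb <- at$resid[ib]
  out_e <- numeric(traj$n_frames); out_v <- numeric(traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[, , f]
    box <- traj$box[f, ]
    # minimum-image distance matrix A x B
    r2 <- matrix(0, length(ia), length(ib))
    for (k in 1:3) {
      dk <- outer(xyz[ia, k], xyz[ib, k], `-`)
      dk <- dk - box[k] * round(dk / box[k])
      r2 <- r2 + dk^2
    }
    r <- sqrt(r2)
    # molecules of B with any atom inside the cutoff sphere around A
    within <- apply(r <= cutoff, 2L, any)
    keep_mol <- resb %in% unique(resb[within])
    if (!any(keep_mol)) next
    rk <- r[, keep_mol, drop = FALSE]
    qqk <- qq[, keep_mol, drop = FALSE]
    sk <- sij[, keep_mol, drop = FALSE]
    ek <- eij[, keep_mol, drop = FALSE]
    out_e[f] <- .COULOMB_K * sum(qqk / rk)
    sr6 <- (sk / rk)^6
    out_v[f] <- sum(4 * ek * (sr6^2 - sr6))
  }
  structure(data.frame(frame = seq_len(traj$n_frames),
                       electrostatic = out_e, vdw = out_v),
            class = c("energy_trace", "data.frame"))
}
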