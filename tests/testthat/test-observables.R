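test_that("z-distribution concentrates in one bin for a fixed separation", {
  sys <- two_atom_z_system(rep(10, 50))
  d <- z_distance_distribution(sys$traj, sys$topo, "probe", "ref",
                               bin_width = 2)
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-9)
  hot <- which(d$density > 0)
  expect_length(hot, 1L)
  expect_true(d$breaks[hot] <= 10 && 10 <= d$breaks[hot + 1L])
})

test_that("a uniform probe position gives a flat density", {
  set.seed(21)
  sys <- two_atom_z_system(runif(1e4, 0, 20))
  d <- z_distance_distribution(sys$traj, sys$topo, "probe", "ref",
                               bin_width = 2)
  inner <- d$density[d$breaks[-length(d$breaks)] >= 0 &
                     d$breaks[-1L] <= 20]
  expect_true(all(abs(inner - 0.05) < 0.01))
})

test_that("reflecting all z coordinates negates the mean separation", {
  set.seed(22)
  sys <- two_atom_z_system(rnorm(200, 8, 2))
  d1 <- z_distance_distribution(sys$traj, sys$topo, "probe", "ref")
  refl <- sys$traj
  refl$coords[, 3L, ] <- -refl$coords[, 3L, ]
  d2 <- z_distance_distribution(refl, sys$topo, "probe", "ref")
  expect_equal(d2$mean, -d1$mean, tolerance = 1e-12)
})

test_that("per-frame closest-residue reference tracks the probe", {
  # two reference residues at z = 0 and z = 30; probe near z = 28 must be
  # measured against the closer one
  at <- data.frame(name = c("O1", "C1", "C1"), resname = c("PRB", "R1", "R2"),
                   resid = 1:3, group = c("probe", "ref", "ref"),
                   charge = 0, sigma = 3, epsilon = 0.1, mass = c(16, 12, 12))
  coords <- array(0, dim = c(3, 3, 1))
  coords[1, 3, 1] <- 28; coords[3, 3, 1] <- 30
  traj <- trajectory(coords, c(40, 40, 80))
  topo <- topology(at, list(probe = 1L, ref = 2:3))
  d <- z_distance_distribution(traj, topo, "probe", "ref", n_closest = 1)
  expect_equal(d$mean, -2)
  expect_error(z_distance_distribution(traj, topo, "probe", "ref",
                                       n_closest = 5), "exceeds")
})

test_that("hydrogen-bond bookkeeping counts multiplicity over time", {
  # persistent bond plus an every-other-frame bond on the same OH -> 1.5
  g <- gen_bilayer_trajectory(lipids_per_leaflet = 4, n_carbons = 5,
                              n_frames = 20, hbond_period = 2, seed = 1)
  hb <- hbond_time_fractions(g$trajectory, g$topology, "donors", "acceptors")
  expect_equal(hb$fraction, 1.5)
  expect_equal(hb$fraction, g$truth$hbond_fraction_expected)
})

test_that("a persistent single bond gives exactly 1 and a distant one gives 0", {
  mk <- function(da_dist) {
    at <- data.frame(name = c("OD", "HD", "OA"), resname = c("DON", "DON", "ACC"),
                     resid = c(1, 1, 2), group = c("don", "don", "acc"),
                     charge = 0, sigma = 3, epsilon = 0.1,
                     mass = c(16, 1.008, 16))
    coords <- array(0, dim = c(3, 3, 8))
    coords[2, 1, ] <- 0.96
    coords[3, 1, ] <- da_dist
    list(topo = topology(at, list(donors = 1L, acceptors = 3L)),
         traj = trajectory(coords, c(30, 30, 30)))
  }
  persistent <- mk(2.8)
  expect_equal(hbond_time_fractions(persistent$traj, persistent$topo,
                                    "donors", "acceptors")$fraction, 1)
  far <- mk(3.6)  # just beyond the 3.5 A cutoff
  expect_equal(hbond_time_fractions(far$traj, far$topo,
                                    "donors", "acceptors")$fraction, 0)
  # donor without a bonded hydrogen errors
  noh <- mk(2.8)
  noh$traj$coords[2, 1, ] <- 5
  expect_error(hbond_time_fractions(noh$traj, noh$topo, "donors", "acceptors"),
               "without a bonded hydrogen")
})

test_that("aligned all-trans chains give SCD = -0.5 on every carbon", {
  g <- gen_bilayer_trajectory(lipids_per_leaflet = 4, n_carbons = 7,
                              n_frames = 5, tilt_mean = 0, tilt_sd = 0,
                              seed = 2)
  sc <- scd_profile(g$trajectory, g$topology, "chains")
  expect_equal(sc$scd, rep(-0.5, 7), tolerance = 1e-12)
  # the absolute-value presentation flips the sign
  sca <- scd_profile(g$trajectory, g$topology, "chains", absolute = TRUE)
  expect_equal(sca$scd, rep(0.5, 7), tolerance = 1e-12)
})

test_that("isotropically oriented C-H bonds average to SCD = 0", {
  # 100 C-H pairs, 1000 frames of fresh isotropic orientations = 1e5 samples
  set.seed(31)
  n_pair <- 100; n_frames <- 1000
  at <- data.frame(name = rep(c("C1", "H1"), n_pair),
                   resname = "CHX",
                   resid = rep(seq_len(n_pair), each = 2),
                   group = "chx", charge = 0, sigma = 3, epsilon = 0.1,
                   mass = rep(c(12.011, 1.008), n_pair))
  base <- cbind((seq_len(n_pair) - 1) %% 10, (seq_len(n_pair) - 1) %/% 10, 5) * 10
  coords <- array(0, dim = c(2 * n_pair, 3, n_frames))
  ci <- seq(1, 2 * n_pair, by = 2)
  for (f in seq_len(n_frames)) {
    u <- matrix(rnorm(3 * n_pair), n_pair, 3)
    u <- u / sqrt(rowSums(u^2))
    coords[ci, , f] <- base
    coords[ci + 1, , f] <- base + 1.09 * u
  }
  traj <- trajectory(coords, c(100, 100, 100))
  topo <- topology(at, list(chains = ci))
  sc <- scd_profile(traj, topo, "chains")
  expect_lt(abs(sc$scd), 0.01)
})

test_that("a rigid chain tilted by alpha follows the azimuthal closed form", {
  for (alpha in c(30, 60, 90)) {
    g <- gen_bilayer_trajectory(lipids_per_leaflet = 8, n_carbons = 9,
                                n_frames = 200, tilt_mean = alpha,
                                tilt_sd = 0, seed = 40 + alpha)
    sc <- scd_profile(g$trajectory, g$topology, "chains")
    expected <- (3 * sin(alpha * pi / 180)^2 / 2 - 1) / 2
    expect_lt(abs(mean(sc$scd) - expected), 0.005)
  }
  # alpha = 90 gives +0.25 exactly in expectation
  expect_equal((3 * sin(pi / 2)^2 / 2 - 1) / 2, 0.25)
})

test_that("hydrogen reconstruction reproduces explicit-hydrogen order parameters", {
  g <- gen_bilayer_trajectory(lipids_per_leaflet = 4, n_carbons = 7,
                              n_frames = 20, tilt_mean = 25, tilt_sd = 4,
                              seed = 8)
  sc_explicit <- scd_profile(g$trajectory, g$topology, "chains")
  # strip the hydrogens and rebuild them at ideal geometry
  keep <- which(g$topology$atoms$group != "chainH")
  at2 <- g$topology$atoms[keep, ]
  map <- match(g$topology$selections$chains, keep)
  topo2 <- topology(at2, list(chains = map))
  traj2 <- trajectory(g$trajectory$coords[keep, , , drop = FALSE],
                      g$trajectory$box)
  expect_error(scd_profile(traj2, topo2, "chains"), "no bonded hydrogens")
  sc_rebuilt <- scd_profile(traj2, topo2, "chains", reconstruct_h = TRUE)
  interior <- intersect(sc_explicit$carbon, sc_rebuilt$carbon)
  expect_equal(sc_rebuilt$scd[sc_rebuilt$carbon %in% interior],
               sc_explicit$scd[sc_explicit$carbon %in% interior],
               tolerance = 1e-6)
})

test_that("tilt distribution shows leaflet mirror symmetry and folds correctly", {
  g <- gen_bilayer_trajectory(lipids_per_leaflet = 4, n_carbons = 7,
                              n_frames = 5, tilt_mean = 0, tilt_sd = 0,
                              seed = 3)
  un <- tilt_distribution(g$trajectory, g$topology, "chains", fold = FALSE)
  expect_true(all(un$angles < 1e-6 | un$angles > 180 - 1e-6))
  fo <- tilt_distribution(g$trajectory, g$topology, "chains", fold = TRUE)
  expect_true(all(fo$angles < 1e-6))

  g33 <- gen_bilayer_trajectory(lipids_per_leaflet = 8, n_carbons = 9,
                                n_frames = 200, tilt_mean = 33, tilt_sd = 5,
                                seed = 4)
  fo33 <- tilt_distribution(g33$trajectory, g33$topology, "chains",
                            fold = TRUE)
  expect_lt(abs(fo33$mean - 33), 1)
  expect_equal(sum(fo33$density * diff(fo33$breaks)), 1, tolerance = 1e-9)
  # mirrored leaflets: unfolded distribution symmetric about 90 degrees
  up <- tilt_distribution(g33$trajectory, g33$topology, "upper_chains")
  lo <- tilt_distribution(g33$trajectory, g33$topology, "lower_chains")
  expect_lt(abs(up$mean - (180 - lo$mean)), 1)
})

test_that("point charges at 3 A reproduce Coulomb's law and the LJ anchors", {
  at <- data.frame(name = c("P1", "N1"), resname = c("A", "B"), resid = 1:2,
                   group = "g", charge = c(1, -1), sigma = 3.2,
                   epsilon = c(0, 0), mass = 20)
  coords <- array(0, dim = c(2, 3, 1))
  coords[2, 1, 1] <- 3
  traj <- trajectory(coords, c(50, 50, 50))
  topo <- topology(at, list(A = 1L, B = 2L))
  en <- pairwise_interaction_energy(traj, topo, "A", "B")
  expect_equal(en$electrostatic, -332.0636 / 3, tolerance = 1e-10)
  expect_equal(en$vdw, 0)
  # neutral LJ pair: zero at r = sigma, -epsilon at the minimum
  at2 <- at; at2$charge <- 0; at2$epsilon <- 0.2
  for (cse in list(c(3.2, 0), c(3.2 * 2^(1 / 6), -0.2))) {
    coords[2, 1, 1] <- cse[1L]
    en2 <- pairwise_interaction_energy(trajectory(coords, c(50, 50, 50)),
                                       topology(at2, list(A = 1L, B = 2L)),
                                       "A", "B")
    expect_equal(en2$vdw, cse[2L], tolerance = 1e-10)
  }
})

test_that("cutoff-sphere energies equal the brute-force all-pairs oracle", {
  for (args in list(c(60, 1), c(200, 2), c(500, 3))) {
    sys <- random_energy_system(args[1L], box_len = 30, seed = args[2L])
    en <- pairwise_interaction_energy(sys$traj, sys$topo, "A", "B",
                                      cutoff = 12)
    oracle <- brute_force_energy(sys$xyz, rep(30, 3), sys$at, 1:10,
                                 11:args[1L], 12)
    expect_equal(en$electrostatic, unname(oracle["elec"]), tolerance = 1e-8)
    expect_equal(en$vdw, unname(oracle["vdw"]), tolerance = 1e-8)
  }
})

test_that("energies are invariant under rigid translation and periodic wrapping", {
  sys <- random_energy_system(100, box_len = 30, seed = 7)
  en0 <- pairwise_interaction_energy(sys$traj, sys$topo, "A", "B")
  shifted <- sys$traj
  shifted$coords[, , 1] <- sweep(shifted$coords[, , 1], 2, c(11, -4, 23), `+`)
  en1 <- pairwise_interaction_energy(shifted, sys$topo, "A", "B")
  wrapped <- shifted
  for (k in 1:3) wrapped$coords[, k, 1] <- wrapped$coords[, k, 1] %% 30
  en2 <- pairwise_interaction_energy(wrapped, sys$topo, "A", "B")
  expect_equal(en1$electrostatic, en0$electrostatic, tolerance = 1e-10)
  expect_equal(en2$electrostatic, en0$electrostatic, tolerance = 1e-10)
  expect_equal(en2$vdw, en0$vdw, tolerance = 1e-10)
})

test_that("energy computation validates selections and parameters", {
  sys <- random_energy_system(60, seed = 9)
  expect_error(pairwise_interaction_energy(sys$traj, sys$topo, "A", 5:15),
               "overlap")
  at_bad <- sys$at
  at_bad$charge[20] <- NA
  topo_bad <- topology(within(at_bad, charge[20] <- 0),
                       list(A = 1:10, B = 11:60))
  topo_bad$atoms$charge[20] <- NA  # bypass constructor check deliberately
  expect_error(pairwise_interaction_energy(sys$traj, topo_bad, "A", "B"),
               "missing nonbonded parameters")
})

test_that("topology and PDB trajectory files round-trip", {
  skip_if_not_installed("bio3d")
  g <- gen_bilayer_trajectory(lipids_per_leaflet = 4, n_carbons = 5,
                              n_frames = 3, seed = 5)
  ftop <- tempfile(fileext = ".csv")
  at <- g$topology$atoms
  writeLines(c("index,name,resname,resid,group,charge_e,sigma_A,epsilon_kcal,mass_amu",
               paste(seq_len(nrow(at)), at$name, at$resname, at$resid,
                     at$group, at$charge, at$sigma, at$epsilon, at$mass,
                     sep = ",")), ftop)
  fsel <- tempfile(fileext = ".txt")
  writeLines(c("chains = group:chain", "probe = group:probe",
               paste("donors =", paste(g$topology$selections$donors,
                                       collapse = ","))), fsel)
  topo <- read_topology(ftop, fsel)
  expect_equal(topo$atoms$charge, at$charge)
  expect_equal(select_atoms(topo, "chains"),
               select_atoms(g$topology, "chains"))
  expect_equal(select_atoms(topo, "donors"),
               select_atoms(g$topology, "donors"))

  fpdb <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(g$trajectory, g$topology, fpdb)
  tr <- read_trajectory_pdb(fpdb)
  expect_equal(tr$n_frames, 3)
  expect_lt(max(abs(tr$coords - g$trajectory$coords)), 1e-3)  # PDB precision
  expect_equal(tr$box[1, ], g$trajectory$box[1, ], tolerance = 1e-3)
})
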