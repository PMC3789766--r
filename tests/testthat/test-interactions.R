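test_that("contact map applies the 4 Å / j>i+2 rule strictly", {
  # 5 one-bead residues; residues 1 and 4 fixed 3.9 Å apart, 1-3 at 3 Å
  m <- rbind(c(0, 0, 0), c(0, 0, 50), c(3, 0, 0), c(3.9, 0, 0),
             c(0, 0, 100))
  traj <- toy_energy_traj(list(m, m), charges = rep(0, 5))
  P <- contact_map(traj)
  expect_equal(P["1", "4"], 1)       # 3.9 < 4.0 in every frame
  expect_true(is.na(P["1", "3"]))    # j = i+2 excluded by the rule
  expect_true(is.na(P["1", "2"]))
  expect_equal(P["1", "5"], 0)
  expect_equal(P["4", "1"], P["1", "4"])  # symmetrised
  # atoms at exactly/above the cutoff are not contacts (strict <)
  m2 <- m; m2[4, 1] <- 4.1
  expect_equal(contact_map(toy_energy_traj(list(m2), rep(0, 5)))["1", "4"], 0)
  m3 <- m; m3[4, 1] <- 4.0
  expect_equal(contact_map(toy_energy_traj(list(m3), rep(0, 5)))["1", "4"], 0)
  # probability is monotone non-decreasing in the cutoff
  withr::with_seed(51, {
    mr <- matrix(stats::rnorm(15, sd = 4), 5, 3)
    trr <- toy_energy_traj(list(mr), rep(0, 5))
    cuts <- c(2, 4, 6, 8, 12)
    probs <- vapply(cuts, function(cc)
      contact_map(trr, contact_criterion(cc))["1", "4"], 0)
    expect_true(all(diff(probs) >= 0))
  })
})

test_that("pair energies hit the LJ minimum and Coulomb arithmetic exactly", {
  sig <- 3; r <- 2^(1/6) * sig
  m <- rbind(c(0, 0, 0), c(0, 0, 40), c(0, 0, 80), c(r, 0, 0))
  traj <- toy_energy_traj(list(m), charges = c(0, 0, 0, 0),
                          sigmas = sig, epsilons = 0.25)
  E <- pair_energy_matrices(traj)
  expect_equal(E$lj["1", "4"], -0.25, tolerance = 1e-12)
  expect_equal(E$coulomb["1", "4"], 0)
  # +1/-1 at k_e/100 Å: exactly -100 kcal/mol
  m2 <- rbind(c(0, 0, 0), c(0, 0, 40), c(0, 0, 80), c(3.320636, 0, 0))
  t2 <- toy_energy_traj(list(m2), charges = c(1, 0, 0, -1),
                        sigmas = 1e-3, epsilons = 0)
  expect_equal(pair_energy_matrices(t2)$coulomb["1", "4"], -100,
               tolerance = 1e-9)
})

test_that("energy matrices equal an independent all-pairs re-summation", {
  withr::with_seed(52, {
    frames <- list(matrix(stats::rnorm(12, sd = 4), 4, 3),
                   matrix(stats::rnorm(12, sd = 4), 4, 3))
    q <- c(0.5, -0.3, 0.2, -0.4)
    eps <- c(0.1, 0.2, 0.15, 0.12); sig <- c(3, 3.4, 2.9, 3.1)
    top <- topology(paste0("A", 1:4), 1:4, "GLY", "peptide", radius = 1.7,
                    charge = q, lj_epsilon = eps, lj_sigma = sig, mass = 12)
    traj <- trajectory(top, array(unlist(frames), dim = c(4, 3, 2)))
    E <- pair_energy_matrices(traj)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      lj <- 0; co <- 0
      for (f in 1:2) {
        r <- sqrt(sum((frames[[f]][i, ] - frames[[f]][j, ])^2))
        s <- (sig[i] + sig[j]) / 2
        e <- sqrt(eps[i] * eps[j])
        lj <- lj + 4 * e * ((s / r)^12 - (s / r)^6)
        co <- co + 332.0636 * q[i] * q[j] / r
      }
      expect_equal(E$lj[i, j], lj / 2, tolerance = 1e-10)
      expect_equal(E$coulomb[i, j], co / 2, tolerance = 1e-10)
    }
  })
})

test_that("hydrogen bonds require both distance and angle", {
  # donor at origin with H pointing at the acceptor: angle 0
  mk <- function(acc, h = c(1, 0, 0)) {
    m <- rbind(c(0, 0, 0), h, acc, c(0, 0, 60))
    top <- topology(c("N", "H", "O", "C"), c(1L, 1L, 2L, 3L), "GLY",
                    "peptide", radius = c(1.55, 1.2, 1.52, 1.7),
                    mass = c(14, 1, 16, 12))
    trajectory(top, array(m, dim = c(4, 3, 1)))
  }
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  occ <- hbond_occupancy(mk(c(2.9, 0, 0)), donors = donors, acceptors = 3L)
  expect_equal(occ["1", "2"], 100)
  # same distance, angle ~40 degrees: rejected
  acc40 <- 2.9 * c(cos(40 * pi / 180), sin(40 * pi / 180), 0)
  expect_equal(hbond_occupancy(mk(acc40), donors = donors,
                               acceptors = 3L)["1", "2"], 0)
  # too far: rejected
  expect_equal(hbond_occupancy(mk(c(3.8, 0, 0)), donors = donors,
                               acceptors = 3L)["1", "2"], 0)
  expect_error(hbond_occupancy(mk(c(2.9, 0, 0)),
                               donors = data.frame(donor = 1L,
                                                   hydrogen = NA_integer_),
                               acceptors = 3L), "hydrogen")
})

test_that("peptide-ligand profile partitions the total interaction energy", {
  withr::with_seed(53, {
    # 6-residue chain + 2-atom ligand with charges
    coords <- lapply(1:3, function(f) matrix(stats::rnorm(24, sd = 5), 8, 3))
    q <- c(0.3, -0.2, 0.1, 0.4, -0.3, 0.2, 0.5, -0.5)
    top <- topology(c(paste0("A", 1:6), "L1", "L2"),
                    c(1:6, 7L, 7L), "GLY",
                    c(rep("peptide", 6), "ligand", "ligand"),
                    radius = 1.7, charge = q, lj_epsilon = 0.15,
                    lj_sigma = 3.2, mass = 12)
    traj <- trajectory(top, array(unlist(coords), dim = c(8, 3, 3)))
    prof <- peptide_ligand_profile(traj)
    # independent total: double loop over all peptide x ligand atom pairs
    tot_lj <- 0; tot_co <- 0
    for (f in 1:3) for (i in 1:6) for (j in 7:8) {
      r <- sqrt(sum((coords[[f]][i, ] - coords[[f]][j, ])^2))
      tot_lj <- tot_lj + 4 * 0.15 * ((3.2 / r)^12 - (3.2 / r)^6)
      tot_co <- tot_co + 332.0636 * q[i] * q[j] / r
    }
    expect_equal(sum(prof$lj), tot_lj / 3, tolerance = 1e-9)
    expect_equal(sum(prof$coulomb), tot_co / 3, tolerance = 1e-9)
    # energies are invariant under rigid motion of whole frames
    moved <- transform_trajectory(traj, random_rotation(5), c(7, -3, 1))
    expect_equal(peptide_ligand_profile(moved)$lj, prof$lj,
                 tolerance = 1e-8)
  })
  # distant neutral ligand: all three series vanish
  far <- rbind(line_template(4), c(1000, 0, 0))
  topf <- topology(c(paste0("A", 1:4), "L1"), c(1:4, 5L), "GLY",
                   c(rep("peptide", 4), "ligand"), radius = 1.7,
                   charge = 0, lj_epsilon = 0.15, lj_sigma = 3.2, mass = 12)
  trf <- trajectory(topf, array(far, dim = c(5, 3, 1)))
  pf <- peptide_ligand_profile(trf)
  expect_lt(max(abs(pf$lj)), 1e-6)
  expect_equal(pf$coulomb, rep(0, 4))
  expect_equal(pf$hbond_pct, rep(0, 4))
})

test_that("opposite charges attract in the mean Coulomb matrix", {
  eps <- rep(0.3, 10)
  ch <- chain_spec(10, stickiness = eps)
  tr <- simulate_cg(ch, NULL, simulation_params(n_steps = 2e4,
                                                save_interval = 200,
                                                seed = 19))
  tr$topology$charge <- c(1, 0, 0, 0, -1, 0, 0, 0, 1, 0)
  E <- pair_energy_matrices(tr)
  expect_lt(E$coulomb["1", "5"], 0)
  expect_lt(E$coulomb["5", "9"], 0)
  expect_gt(E$coulomb["1", "9"], 0)
})
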