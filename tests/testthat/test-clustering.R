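test_that("kabsch superposition inverts rigid motions and stays proper", {
  withr::with_seed(41, {
    A <- matrix(stats::rnorm(30, sd = 4), 10, 3)
    R <- random_rotation(2)
    B <- A %*% t(R) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
    sp <- kabsch_superpose(A, B)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    # mirror image: rotation stays proper, rmsd > 0
    M <- A; M[, 1] <- -M[, 1]
    spm <- kabsch_superpose(M, A)
    expect_equal(det(spm$rotation), 1, tolerance = 1e-9)
    expect_gt(spm$rmsd, 0.1)
    # collinear subset is rejected
    line <- cbind(1:5, 0, 0)
    expect_error(kabsch_superpose(line, line), "degenerate|collinear")
  })
})

test_that("superposed RMSD matches the quaternion oracle", {
  withr::with_seed(43, {
    for (k in 1:10) {
      A <- matrix(stats::rnorm(30, sd = 3), 10, 3)
      B <- matrix(stats::rnorm(30, sd = 3), 10, 3)
      expect_equal(kabsch_superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                   tolerance = 1e-8)
    }
  })
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and exact", {
  withr::with_seed(44, {
    n <- 5; na <- 8
    coords <- array(stats::rnorm(na * 3 * n, sd = 3), dim = c(na, 3, n))
    top <- topology(paste0("A", 1:na), 1:na, "GLY", "peptide", radius = 1.9)
    traj <- trajectory(top, coords)
    M <- pairwise_rmsd_matrix(traj, subset = 1:na)
    expect_equal(M, t(M), tolerance = 1e-9)
    expect_equal(diag(M), rep(0, n))
    for (i in 1:n) for (j in 1:n) if (i < j)
      expect_equal(M[i, j],
                   kabsch_superpose(frame_coords(traj, i),
                                    frame_coords(traj, j))$rmsd,
                   tolerance = 1e-8)
    # identical frames give an all-zero matrix
    same <- trajectory(top, array(rep(coords[, , 1], 4), dim = c(na, 3, 4)))
    expect_lt(max(pairwise_rmsd_matrix(same, 1:na)), 1e-8)
  })
})

test_that("pairwise RMSD is invariant under rigid motion of whole frames", {
  withr::with_seed(45, {
    na <- 10
    coords <- array(stats::rnorm(na * 3 * 4, sd = 3), dim = c(na, 3, 4))
    top <- topology(paste0("A", 1:na), 1:na, "GLY", "peptide", radius = 1.9)
    traj <- trajectory(top, coords)
    moved <- transform_trajectory(traj, random_rotation(9), c(10, -4, 2))
    expect_equal(pairwise_rmsd_matrix(traj, 1:na),
                 pairwise_rmsd_matrix(moved, 1:na), tolerance = 1e-8)
  })
})

test_that("daura clustering matches the exhaustive greedy oracle", {
  expect_error(daura_cluster(matrix(0, 0, 0)), "empty")
  # degenerate: all identical frames form one full cluster
  z <- matrix(0, 6, 6)
  cs <- daura_cluster(z, 2)
  expect_equal(length(cs$sizes), 1)
  expect_equal(cs$populations, 1)
  expect_equal(cs$representatives, 1L)  # lowest-index tie break
  # property: identical to the oracle on random instances up to 25 frames
  withr::with_seed(46, {
    for (k in 1:40) {
      n <- sample(2:25, 1)
      m <- random_rmsd_matrix(n)
      cut <- stats::runif(1, 0.5, 2.5)
      got <- daura_cluster(m, cut)
      ora <- daura_oracle(m, cut)
      expect_identical(got$assignment, ora$assignment)
      expect_identical(got$representatives, ora$representatives)
      expect_true(all(diff(got$sizes) <= 0))
      expect_equal(sum(got$populations), 1, tolerance = 1e-9)
    }
  })
})

test_that("cluster populations recover mixture weights", {
  tmpl <- list(line_template(12), ring_template(12))
  spec <- conformer_mixture_spec(tmpl, weights = c(0.6, 0.4),
                                 noise_sigma = 0.5, seed = 9)
  traj <- sample_conformer_mixture(spec, 1000)
  M <- pairwise_rmsd_matrix(traj, 1:12)
  cs <- daura_cluster(M, cutoff = 2.0)
  expect_equal(length(cs$sizes), 2)
  expect_lt(max(abs(cs$populations - c(0.6, 0.4))), 0.03)
  # with pairwise template RMSD far above cutoff, clustering recovers the
  # true component labels exactly
  comp <- attr(traj, "components")
  expect_true(all(tapply(comp, cs$assignment,
                         function(x) length(unique(x))) == 1))
})

test_that("ligand clouds carry one centre of mass per member frame", {
  # peptide + 2-bead ligand, equal masses, already aligned frames
  top <- rbind(
    topology(paste0("A", 1:4), 1:4, "GLY", "peptide", radius = 1.9,
             mass = 110),
    topology(c("L1", "L2"), c(5L, 5L), "LIG", "ligand", radius = 2.5,
             mass = 50)
  )
  base <- rbind(ring_template(4), c(0, 0, 0), c(2, 0, 0))
  coords <- array(rep(base, 3), dim = c(6, 3, 3))
  traj <- trajectory(top, coords)
  cs <- daura_cluster(pairwise_rmsd_matrix(traj, 1:4), 2.0)
  cloud <- ligand_cloud(traj, cs, subset = 1:4)
  expect_equal(length(cloud), length(cs$sizes))
  expect_equal(nrow(cloud[[1]]), cs$sizes[1])
  expect_equal(cloud[[1]][1, ], c(1, 0, 0))  # two equal-mass beads
  # rigidly moved member frames land on the same cloud point
  traj2 <- traj
  R <- random_rotation(3)
  traj2$coords[, , 2] <- base %*% t(R) + matrix(c(5, 5, 5), 6, 3, byrow = TRUE)
  cs2 <- daura_cluster(pairwise_rmsd_matrix(traj2, 1:4), 2.0)
  cloud2 <- ligand_cloud(traj2, cs2, subset = 1:4)
  expect_equal(cloud2[[1]][2, ], cloud2[[1]][1, ], tolerance = 1e-8)
  # no ligand -> configuration error
  expect_error(ligand_cloud(trajectory(top[1:4, ],
                                       coords[1:4, , , drop = FALSE]), cs),
               "ligand")
})

test_that("population reports reproduce the published cumulative occupancies", {
  holo <- c(14.3, 13.9, 13.7, 10.4, 7.5, 6.9, 5.4, 5.2) / 100
  apo <- c(10.5, 8.6, 7.8, 6.4, 6.1, 4.5, 3.5, 3.0) / 100
  expect_equal(cluster_population_report(holo, 8)$cumulative_pct, 77L)
  expect_equal(cluster_population_report(apo, 8)$cumulative_pct, 50L)
  expect_equal(cluster_population_report(c(1), 1)$cumulative_pct, 100L)
  # top_k beyond cluster count reports all clusters
  expect_equal(nrow(cluster_population_report(holo, 20)$table), 8)
})

test_that("bound ensembles cluster tighter than unbound ones", {
  # ligand-stabilised ensemble: mass concentrated on few templates
  tmpl <- lapply(1:10, function(k) {
    withr::with_seed(100 + k, line_template(12) +
                       matrix(stats::rnorm(36, sd = 6), 12, 3))
  })
  w_holo <- c(0.30, 0.22, 0.16, 0.10, 0.07, 0.05, 0.04, 0.03, 0.02, 0.01)
  w_apo <- rep(0.1, 10)
  top8 <- function(w, seed) {
    tr <- sample_conformer_mixture(
      conformer_mixture_spec(tmpl, w, noise_sigma = 0.5, seed = seed), 400)
    cs <- daura_cluster(pairwise_rmsd_matrix(tr, 1:12), 2.0)
    cluster_population_report(cs, 8)$cumulative_pct
  }
  expect_gt(top8(w_holo, 11), top8(w_apo, 11))
})
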