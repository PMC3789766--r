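# Independent oracles and fixture builders used across the suite.

# Monte-Carlo SASA oracle: random points on each probe-expanded sphere,
# buried iff strictly inside another subset atom's expanded sphere.
mc_sasa_oracle <- function(coords, radii, subset = seq_len(nrow(coords)),
                           probe = 1.4, n_points = 1e6, seed = 42) {
  withr::with_seed(seed, {
    er <- radii + probe
    vapply(subset, function(i) {
      u <- matrix(stats::rnorm(3 * n_points), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pts <- sweep(u * er[i], 2, coords[i, ], "+")
      exposed <- rep(TRUE, n_points)
      for (j in setdiff(subset, i)) {
        d2 <- (pts[, 1] - coords[j, 1])^2 + (pts[, 2] - coords[j, 2])^2 +
          (pts[, 3] - coords[j, 3])^2
        exposed <- exposed & d2 >= er[j]^2
      }
      4 * pi * er[i]^2 * mean(exposed)
    }, 0)
  })
}

# Quaternion (Kearsley) superposition oracle: minimal RMSD over proper
# rotations from the largest eigenvalue of the 4x4 key matrix.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(A0, B0)  # sum over atoms of a_i b_i^T
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  ga <- sum(A0^2); gb <- sum(B0^2)
  sqrt(max(0, (ga + gb - 2 * lambda) / nrow(A)))
}

# Exhaustive greedy clustering oracle: neighbour counts recomputed from
# scratch at every iteration, lowest-index tie break.
daura_oracle <- function(rmsd, cutoff) {
  n <- nrow(rmsd)
  remaining <- seq_len(n)
  assignment <- integer(n)
  reps <- integer(0)
  cl <- 0L
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(rmsd[i, remaining] <= cutoff) - 1L, 0L)
    center <- remaining[which.max(counts)]
    members <- remaining[rmsd[center, remaining] <= cutoff]
    cl <- cl + 1L
    assignment[members] <- cl
    reps[cl] <- center
    remaining <- setdiff(remaining, members)
  }
  list(assignment = assignment, representatives = reps)
}

# random symmetric "rmsd-like" matrix (zero diagonal, non-negative)
random_rmsd_matrix <- function(n, scale = 3) {
  m <- matrix(stats::runif(n * n, 0, scale), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# rigid bead templates with large mutual RMSD: straight line vs ring
line_template <- function(n, spacing = 3.8)
  cbind(spacing * seq_len(n), 0, 0)

ring_template <- function(n, spacing = 3.8) {
  r <- spacing / (2 * sin(pi / n))
  th <- 2 * pi * seq_len(n) / n
  cbind(r * cos(th), r * sin(th), 0)
}

# minimal delta_sasa_series built directly from a value matrix
make_series <- function(values, time_spacing = 20) {
  structure(list(values = values,
                 residues = as.integer(rownames(values)),
                 times = seq_len(ncol(values)) * time_spacing,
                 time_spacing = time_spacing),
            class = "delta_sasa_series")
}

# tiny two-residue + ligand trajectory with explicit parameters
toy_energy_traj <- function(coords_list, charges, sigmas = 3, epsilons = 0.2,
                            roles = NULL) {
  n <- nrow(coords_list[[1]])
  if (is.null(roles)) roles <- rep("peptide", n)
  top <- topology(paste0("A", seq_len(n)), seq_len(n), "GLY", roles,
                  radius = 1.7, charge = charges,
                  lj_epsilon = rep(epsilons, length.out = n),
                  lj_sigma = rep(sigmas, length.out = n), mass = 12)
  trajectory(top, array(unlist(coords_list),
                        dim = c(n, 3, length(coords_list))),
             time_spacing = 1)
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}
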