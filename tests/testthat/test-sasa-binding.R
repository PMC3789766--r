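test_that("isolated and distant spheres recover the closed-form area", {
  top <- topology(c("A", "B"), 1:2, "GLY", "peptide", radius = 1.9)
  far <- matrix(c(0, 0, 0, 100, 0, 0), 2, 3, byrow = TRUE)
  a <- shrake_rupley_sasa(far, top)
  expect_equal(unname(a), rep(4 * pi * 3.3^2, 2), tolerance = 1e-9)
  a1 <- shrake_rupley_sasa(far, top, subset = 1)
  expect_equal(unname(a1), 4 * pi * 3.3^2, tolerance = 1e-9)
  expect_error(shrake_rupley_sasa(far, top, subset = integer(0)),
               "non-empty")
  expect_error(sasa_params(n_sphere_points = 8), "12")
})

test_that("clustered atoms agree with the Monte-Carlo surface oracle", {
  coords <- matrix(c(0, 0, 0,
                     2.5, 0.4, -0.3,
                     1.2, 2.1, 0.8), 3, 3, byrow = TRUE)
  radii <- c(1.9, 1.7, 1.5)
  top <- topology(paste0("A", 1:3), 1:3, "GLY", "peptide", radius = radii)
  got <- shrake_rupley_sasa(coords, top, params = sasa_params(1.4, 1024))
  ora <- mc_sasa_oracle(coords, radii, n_points = 2e5)
  expect_lt(max(abs(got - ora) / ora), 0.01)
})

test_that("SASA is occlusion-monotone and converges in sphere points", {
  withr::with_seed(21, {
    coords <- matrix(stats::rnorm(30, sd = 2.5), 10, 3)
    top <- topology(paste0("A", 1:10), 1:10, "GLY", "peptide",
                    radius = stats::runif(10, 1.4, 2.0))
    # adding an occluder never increases any area
    a9 <- shrake_rupley_sasa(coords, top, subset = 1:9)
    a10 <- shrake_rupley_sasa(coords, top, subset = 1:10)
    expect_true(all(a10[1:9] <= a9 + 1e-12))
    # doubling the point count changes per-atom areas by < 2% of each
    # atom's isolated-sphere area (the well-conditioned scale for nearly
    # buried atoms)
    lo <- shrake_rupley_sasa(coords, top, params = sasa_params(1.4, 512))
    hi <- shrake_rupley_sasa(coords, top, params = sasa_params(1.4, 1024))
    iso <- 4 * pi * (top$radius + 1.4)^2
    expect_lt(max(abs(hi - lo) / iso), 0.02)
  })
})

test_that("delta-SASA localises ligand occlusion and is non-negative", {
  # 3 well-separated residues + ligand bead 3 Å from residue 2 only
  top <- topology(c("CA", "CA", "CA", "L1"), c(1:3, 4L), "GLY",
                  c(rep("peptide", 3), "ligand"),
                  radius = c(1.9, 1.9, 1.9, 2.5))
  m <- matrix(c(0, 0, 0,
                30, 0, 0,
                60, 0, 0,
                33, 0, 0), 4, 3, byrow = TRUE)
  traj <- trajectory(top, array(m, dim = c(4, 3, 1)), time_spacing = 20)
  ds <- delta_sasa(traj, sasa_params(1.4, 1024))
  expect_gt(ds$values["2", 1], 0)
  expect_equal(unname(ds$values[c("1", "3"), 1]), c(0, 0))
  # cross-check the occluded residue against the Monte-Carlo oracle
  apo <- mc_sasa_oracle(m[1:3, ], top$radius[1:3], subset = 1:3,
                        n_points = 2e5)
  holo <- mc_sasa_oracle(m, top$radius, n_points = 2e5)
  expect_equal(unname(ds$values["2", 1]), apo[2] - holo[2], tolerance = 0.05)

  # far ligand: exactly zero everywhere
  m2 <- m; m2[4, ] <- c(0, 100, 0)
  t2 <- trajectory(top, array(m2, dim = c(4, 3, 1)), time_spacing = 20)
  expect_equal(max(delta_sasa(t2)$values), 0)

  # no ligand at all: configuration error
  t3 <- trajectory(top[1:3, ], array(m[1:3, ], dim = c(3, 3, 1)))
  expect_error(delta_sasa(t3), "ligand")
})

test_that("event segmentation applies threshold, continuity and duration rules", {
  # 1000 frames at 20 ps all above threshold: one 20 ns event retained
  v <- matrix(20, 1, 1000, dimnames = list("1", NULL))
  ev <- segment_events(make_series(v), threshold = 10, min_duration = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 20)
  expect_equal(ev$n_frames, 1000)
  expect_equal(ev$end_time - ev$start_time, 20000)

  # a single 400-frame (8 ns) run is discarded by the 10 ns filter
  v2 <- matrix(0, 1, 1000, dimnames = list("1", NULL))
  v2[1, 101:500] <- 30
  expect_equal(nrow(segment_events(make_series(v2), 10, 10)), 0)

  # alternating above/below every frame: single-frame runs never survive
  # the duration filter
  v3 <- matrix(rep(c(30, 0), 500), 1, 1000, dimnames = list("1", NULL))
  expect_equal(nrow(segment_events(make_series(v3), 10, 10)), 0)

  # strict inequality: values equal to the threshold are unbound
  v4 <- matrix(10, 1, 1000, dimnames = list("1", NULL))
  expect_equal(nrow(segment_events(make_series(v4), 10, 1)), 0)

  expect_warning(segment_events(make_series(v), 10, min_duration = 0.001),
                 "frame spacing")
})

test_that("binding percentages match a brute-force mask oracle", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      nres <- 6; nf <- 400; spacing <- 20
      v <- matrix(stats::rexp(nres * nf, rate = 1 / 8), nres, nf,
                  dimnames = list(seq_len(nres), NULL))
      series <- make_series(v, spacing)
      min_dur_ns <- 0.1  # 5 frames
      ev <- segment_events(series, 10, min_dur_ns)
      pct <- binding_percentage(ev, nf, series$residues)
      # oracle: run-length filter the boolean mask directly
      oracle <- vapply(seq_len(nres), function(k) {
        r <- rle(v[k, ] > 10)
        keep <- r$values & (r$lengths * spacing / 1000 >= min_dur_ns)
        100 * sum(r$lengths[keep]) / nf
      }, 0)
      expect_equal(unname(pct), oracle)
    }
  })
  # degenerate cases
  expect_error(binding_percentage(data.frame(), 0, 1), "positive")
  v <- matrix(c(rep(30, 100), rep(0, 100)), 1, 200,
              dimnames = list("1", NULL))
  s <- make_series(v, 20)
  expect_equal(unname(binding_percentage(segment_events(s, 10, 1), 200, 1)),
               50)
  # only event discarded by the duration filter -> 0%
  expect_equal(unname(binding_percentage(segment_events(s, 10, 10), 200, 1)),
               0)
})

test_that("site calling merges, bridges and ranks ranges", {
  pct <- setNames(rep(0, 15), 1:15)
  expect_equal(nrow(call_sites(pct, 15, 1)), 0)
  pct[c(5, 6, 7, 12)] <- c(40, 35, 50, 20)
  s <- call_sites(pct, min_pct = 15, max_gap = 1)
  expect_equal(nrow(s), 2)
  expect_equal(s$start, c(5, 12))
  expect_equal(s$end, c(7, 12))
  expect_equal(s$rank, c(1, 2))
  # max_gap 0 splits a range broken by one sub-threshold residue
  pct2 <- setNames(rep(0, 10), 1:10)
  pct2[c(3, 4, 6, 7)] <- 30
  expect_equal(nrow(call_sites(pct2, 15, 1)), 1)
  expect_equal(nrow(call_sites(pct2, 15, 0)), 2)
})

test_that("delta-SASA of a simulated complex is non-negative everywhere", {
  eps <- rep(0.3, 12); eps[4:8] <- 3
  tr <- simulate_cg(chain_spec(12, stickiness = eps), ligand_spec(1),
                    simulation_params(n_steps = 3e4, save_interval = 200,
                                      seed = 17))
  ds <- delta_sasa(tr, sasa_params(1.4, 128))
  expect_gte(min(ds$values), 0)
})
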