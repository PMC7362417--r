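make_point_traj <- function(frames, kind = "histone") {
  n <- nrow(frames[[1]])
  df <- data.frame(chain = "A", resid = seq_len(n), name = "CA",
                   elem = "C", x = frames[[1]][, 1], y = frames[[1]][, 2],
                   z = frames[[1]][, 3])
  topo <- toy_assembly(df, chain_row("A", kind, "H3", 1L))
  new_trajectory(topo, frames)
}

test_that("RMSD is zero against itself and under rigid motion", {
  set.seed(4)
  ref <- random_cloud(25)
  tr <- make_point_traj(list(ref, ref, rigid_motion(ref)))
  s <- rmsd_series(tr, ref = 1L)
  expect_equal(s$values[1], 0)
  expect_equal(s$values[2], 0)
  expect_lt(s$values[3], 1e-6)
  # explicit 90-degree rotation plus translation
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- sweep(ref %*% t(R90), 2, c(10, 0, 0), "+")
  tr2 <- make_point_traj(list(ref, moved))
  expect_lt(rmsd_series(tr2, ref = 1L)$values[2], 1e-6)
})

test_that("unfitted RMSD reproduces the hand-computed displacement", {
  set.seed(5)
  ref <- random_cloud(10)
  moved <- ref
  moved[4, ] <- moved[4, ] + c(5, 0, 0)   # one of 10 atoms moved 5 A
  tr <- make_point_traj(list(ref, moved))
  s <- rmsd_series(tr, ref = 1L, fit = FALSE)
  expect_equal(s$values[2], sqrt(25 / 10), tolerance = 1e-12)
})

test_that("underdetermined fits and mismatched selections error", {
  set.seed(6)
  ref <- random_cloud(5)
  tr <- make_point_traj(list(ref, ref))
  expect_error(rmsd_series(tr, sel = 1:5, fit_sel = 1:2), "3 atoms")
  expect_error(rmsd_series(tr, sel = integer(0)), "zero atoms")
})

test_that("end-to-end distance is the entry-exit P separation", {
  a <- toy_unwrap_assembly(c(10, 10, 10))
  # place terminal P atoms at known positions
  i <- nucleowrap:::terminal_p_atom(a, "entry")
  j <- nucleowrap:::terminal_p_atom(a, "exit")
  a$xyz[i, ] <- c(0, 0, 0)
  a$xyz[j, ] <- c(72, 0, 0)
  tr <- new_trajectory(a, list(a$xyz, a$xyz))
  expect_equal(end_to_end_series(tr)$values, c(72, 72))
  a$xyz[j, ] <- a$xyz[i, ]
  expect_equal(end_to_end_series(new_trajectory(a, list(a$xyz)))$values, 0)
})

test_that("the wrapped-particle end-to-end distance equals the helix chord", {
  spec <- small_spec(n_bp = 80L)
  ncp <- make_wrapped_ncp(spec)
  tr <- new_trajectory(ncp, list(ncp$xyz))
  expect_equal(end_to_end_series(tr)$values, helix_chord(spec),
               tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms", {
  # ring of N points: Rg equals the ring radius
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  ring <- cbind(7.5 * cos(th), 7.5 * sin(th), 0)
  expect_equal(radius_of_gyration(ring), 7.5, tolerance = 1e-12)
  # single point: 0; two points 2d apart: d
  expect_equal(radius_of_gyration(matrix(c(3, 4, 5), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(8, 0, 0))), 4)
  # mass weighting shifts the centroid accordingly
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(3, 0, 0)),
                                  weights = c(2, 1)),
               sqrt((2 * 1^2 + 1 * 2^2) / 3))
})

test_that("RMSF is zero for static trajectories and exact for oscillation", {
  set.seed(7)
  ref <- random_cloud(12)
  tr <- make_point_traj(list(ref, ref, ref))
  expect_lt(max(rmsf_per_residue(tr)$rmsf), 1e-10)
  # one atom oscillating +/- a along x, fit disabled: RMSF = a
  up <- ref; up[3, 1] <- up[3, 1] + 2.5
  dn <- ref; dn[3, 1] <- dn[3, 1] - 2.5
  tr2 <- make_point_traj(list(up, dn))
  r <- rmsf_per_residue(tr2, fit = FALSE)
  expect_equal(r$rmsf[3], 2.5, tolerance = 1e-12)
  expect_true(all(r$rmsf[-3] == 0))
  expect_error(rmsf_per_residue(make_point_traj(list(ref))), "2 frames")
})

test_that("breathing ends fluctuate more than the wrap interior", {
  tr <- make_breathing_trajectory(small_spec(),
                                  breathing_spec(0.3, 0.3, 8L, 60L,
                                                 seed = 14))
  r <- rmsf_per_residue(tr, sel = list(chain = "I"), fit = FALSE)
  expect_gt(r$rmsf[1], r$rmsf[20])           # terminal vs mid base pair
  expect_gt(r$rmsf[nrow(r)], r$rmsf[20])
})

test_that("three-point angles reproduce hand-derived values", {
  o <- c(0, 0, 0)
  expect_equal(angle_deg(c(1, 0, 0), o, c(0, 1, 0)), 90, tolerance = 1e-12)
  expect_equal(angle_deg(c(1, 0, 0), o, c(1, 1, 0)), 45, tolerance = 1e-12)
  expect_equal(angle_deg(c(1, 0, 0), o, c(2, 0, 0)), 0, tolerance = 1e-12)
  expect_equal(angle_deg(c(1, 0, 0), o, c(-3, 0, 0)), 180, tolerance = 1e-12)
  expect_error(angle_deg(o, o, c(1, 0, 0)), "zero-length")
})

test_that("geometric observables are invariant under global rigid motion", {
  set.seed(8)
  ncp <- make_wrapped_ncp(small_spec())
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 30)
    moved <- ncp
    moved$xyz <- rigid_motion(ncp$xyz, R, t)
    expect_equal(radius_of_gyration(moved), radius_of_gyration(ncp),
                 tolerance = 1e-9)
    e1 <- end_to_end_series(new_trajectory(ncp, list(ncp$xyz)))$values
    e2 <- end_to_end_series(new_trajectory(moved, list(moved$xyz)))$values
    expect_equal(e2, e1, tolerance = 1e-9)
    p <- ncp$xyz[1:3, ]; q <- rigid_motion(p, R, t)
    expect_equal(angle_deg(q[1, ], q[2, ], q[3, ]),
                 angle_deg(p[1, ], p[2, ], p[3, ]), tolerance = 1e-9)
    tr <- new_trajectory(ncp, list(ncp$xyz, moved$xyz))
    expect_lt(rmsd_series(tr, ref = 1L)$values[2], 1e-6)
  }
})

test_that("cross-replica aggregation uses the population SD", {
  agg <- aggregate_replicas(list(rep(10, 4), rep(20, 4)))
  expect_equal(agg$values, rep(15, 4))
  expect_equal(agg$sd_values, rep(5, 4))
  expect_equal(agg$n_replicas, 2L)
  # three scripted replicas against the hand-computed population SD
  r <- list(c(1, 2), c(4, 8), c(7, 2))
  agg3 <- aggregate_replicas(r)
  expect_equal(agg3$values, c(4, 4))
  expect_equal(agg3$sd_values, c(sqrt(6), sqrt(8)))
  expect_error(aggregate_replicas(list(1:3, 1:4)), "length")
})
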