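test_that("the wrapped particle is wrapped by construction and deterministic", {
  a <- make_wrapped_ncp(small_spec())
  b <- make_wrapped_ncp(small_spec())
  expect_identical(a$xyz, b$xyz)
  rec <- count_unwrapped(a)
  expect_equal(rec$n_total, 0L)
  dists <- count_unwrapped(a, diagnostics = TRUE)$bp_min_dist
  expect_true(all(dists <= 6.0))
  validate_assembly(a)
})

test_that("spec validation rejects degenerate geometries", {
  expect_error(superhelix_spec(n_bp = 1), "n_bp")
  expect_error(superhelix_spec(radius = -1))
  expect_error(superhelix_spec(turns = 0))
  expect_error(superhelix_spec(core_radius = 50), "core_radius")
})

test_that("the 2-bp helix end-to-end distance equals the analytic chord", {
  spec <- superhelix_spec(n_bp = 2L, atoms_per_bp = 1L)
  ncp <- make_wrapped_ncp(spec)
  tr <- new_trajectory(ncp, list(ncp$xyz))
  expect_equal(end_to_end_series(tr)$values, helix_chord(spec),
               tolerance = 1e-9)
})

test_that("extra per-bp atoms stay within 2 A of their phosphate", {
  ncp <- make_wrapped_ncp(small_spec(atoms_per_bp = 3L))
  at <- ncp$atoms
  for (ch in c("I", "J")) {
    rows <- which(at$chain == ch)
    for (r in unique(at$resid[rows])) {
      res <- rows[at$resid[rows] == r]
      p <- res[at$name[res] == "P"]
      d <- sqrt(rowSums((ncp$xyz[res, , drop = FALSE] -
                         matrix(ncp$xyz[p, ], length(res), 3,
                                byrow = TRUE))^2))
      expect_lte(max(d), 2)
    }
  }
})

test_that("peeled base pairs clear the core and plant exact ground truth", {
  ncp <- make_wrapped_ncp()
  p <- peel_ends(ncp, 15L, 0L, lift = 4)
  rec <- count_unwrapped(p)
  expect_equal(c(rec$n_entry, rec$n_exit, rec$n_total), c(15L, 0L, 15L))
  expect_equal(p$labels$peel$n_entry, 15L)
  d <- count_unwrapped(p, diagnostics = TRUE)$bp_min_dist
  expect_true(all(d[1:15] > 6 + 4))       # clearance exceeds cutoff + lift
  expect_true(all(d[16:146] <= 6))
  # symmetric peel; asymmetry is visible in the per-site counts
  rec2 <- count_unwrapped(peel_ends(ncp, 10L, 10L, lift = 4))
  expect_equal(rec2$n_total, 20L)
  expect_equal(rec2$n_entry, rec2$n_exit)
  # zero peel is the identity on coordinates
  expect_identical(peel_ends(ncp, 0L, 0L, lift = 4)$xyz, ncp$xyz)
  expect_error(peel_ends(ncp, 100L, 50L, lift = 4), "overlap")
  expect_error(peel_ends(ncp, 1L, 0L, lift = 0), "lift")
})

test_that("reported unwrap counts are monotone in the planted peel", {
  ncp <- make_wrapped_ncp(small_spec())
  prev <- -1L
  for (ne in c(0L, 3L, 7L, 12L)) {
    n <- count_unwrapped(peel_ends(ncp, ne, 0L, lift = 2))$n_entry
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("breathing trajectories are seed-reproducible with exact state labels", {
  spec <- small_spec()
  br <- breathing_spec(0.2, 0.4, 6L, 50L, seed = 11)
  t1 <- make_breathing_trajectory(spec, br)
  t2 <- make_breathing_trajectory(spec, br)
  expect_identical(t1$coords, t2$coords)
  expect_identical(t1$labels$entry_states, t2$labels$entry_states)
  t3 <- make_breathing_trajectory(spec, breathing_spec(0.2, 0.4, 6L, 50L,
                                                       seed = 12))
  expect_false(identical(t1$coords, t3$coords))
  # planted truth: series equals n_unwrap_open x open indicator, exactly
  us <- unwrap_series(t1)
  truth <- 6L * (t1$labels$entry_states + t1$labels$exit_states)
  expect_identical(us$records$n_total, as.integer(truth))
  expect_identical(us$records$n_entry, 6L * t1$labels$entry_states)
})

test_that("k_open = 0 keeps every frame closed", {
  tr <- make_breathing_trajectory(small_spec(),
                                  breathing_spec(0, 0.5, 6L, 30L, seed = 3))
  expect_true(all(unwrap_series(tr)$records$n_total == 0L))
})

test_that("breathing occupancy matches the two-state stationary law", {
  # k_open = k_close = 0.5: rho = 0, occupancy 1/2
  br <- breathing_spec(0.5, 0.5, 6L, 4000L, seed = 21)
  tr <- make_breathing_trajectory(small_spec(), br)
  th <- breathing_occupancy_theory(0.5, 0.5, 4000L)
  occ <- mean(unwrap_series(tr)$records$n_entry > 0L)
  expect_lt(abs(occ - th$p), 3 * th$se)
  # asymmetric rates: occupancy k_open / (k_open + k_close) = 0.25
  br2 <- breathing_spec(0.1, 0.3, 6L, 4000L, seed = 22)
  tr2 <- make_breathing_trajectory(small_spec(), br2)
  th2 <- breathing_occupancy_theory(0.1, 0.3, 4000L)
  occ2 <- mean(unwrap_series(tr2)$records$n_entry > 0L)
  expect_lt(abs(occ2 - 0.25), 3 * th2$se)
})

test_that("chromatosome arms hit feasible angle targets to machine precision", {
  for (tg in list(c(90, 90), c(120, 60), c(45, 45))) {
    ch <- make_chromatosome(chromatosome_spec(core = small_spec(n_bp = 60L),
                                              angles = tg))
    m <- linker_angle_series(ch)
    expect_equal(c(m$angle_P1_P2_P4, m$angle_P3_P4_P2), tg,
                 tolerance = 1e-6)
  }
})

test_that("infeasible arm targets raise a geometry error", {
  expect_error(
    make_chromatosome(chromatosome_spec(core = small_spec(n_bp = 60L),
                                        angles = c(10, 10))),
    "infeasible")
})

test_that("chromatosome assembles valid topology with anchors and H1", {
  ch <- make_chromatosome(chromatosome_spec(core = small_spec(n_bp = 60L)))
  validate_assembly(ch)
  expect_named(ch$selections, c("P1", "P2", "P3", "P4"))
  expect_true("linker_histone" %in% ch$chains$kind)
  expect_equal(sum(ch$atoms$chain == "X"), 20L)
  # arms do not sit inside the bead core
  core <- ch$xyz[atom_indices(ch, kind = "histone"), ]
  arm <- ch$xyz[ch$atoms$chain %in% c("X", "Y"), ]
  zr <- range(core[, 3])
  inside <- sqrt(arm[, 1]^2 + arm[, 2]^2) < 41.8 - 3 &
    arm[, 3] > zr[1] & arm[, 3] < zr[2]
  expect_false(any(inside))
})

test_that("angle noise propagates with the specified spread", {
  meas <- vapply(1:200, function(s)
    make_chromatosome(chromatosome_spec(core = small_spec(),
                                        angles = c(90, 90), noise_sd = 5,
                                        seed = s))$labels$chromatosome$measured_angles[1],
    numeric(1))
  expect_lt(abs(sd(meas) - 5) / 5, 0.2)
  expect_lt(abs(mean(meas) - 90), 1.5)
})

test_that("fixtures write a PDB plus a JSON ground-truth sidecar", {
  dir <- withr::local_tempdir()
  p <- peel_ends(make_wrapped_ncp(small_spec()), 5L, 2L)
  paths <- write_fixture(p, file.path(dir, "peeled"))
  expect_true(all(file.exists(paths)))
  side <- jsonlite::read_json(paths[["json"]])
  expect_equal(side$peel$n_entry, 5L)
  expect_equal(side$peel$n_exit, 2L)
})
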