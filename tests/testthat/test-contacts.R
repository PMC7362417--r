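test_that("the contact rule uses a strict inequality at the cutoff", {
  xyz <- rbind(c(0, 0, 0), c(5.99, 0, 0))
  expect_equal(count_contacts(xyz, 1L, 2L, cutoff = 6), 1L)
  xyz[2, 1] <- 6.00
  expect_equal(count_contacts(xyz, 1L, 2L, cutoff = 6), 0L)
  xyz[2, 1] <- 6.01
  expect_equal(count_contacts(xyz, 1L, 2L, cutoff = 6), 0L)
})

test_that("complete bipartite proximity counts every pair once", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  B <- rbind(c(0, 0, 1), c(1, 1, 0))
  xyz <- rbind(A, B)
  expect_equal(count_contacts(xyz, 1:3, 4:5, cutoff = 6), 6L)
})

test_that("overlapping selections are rejected", {
  a <- toy_copy_assembly()
  expect_error(count_contacts(a, 1:2, 2:3), "overlap")
  expect_error(residue_profile(new_trajectory(a, list(a$xyz)),
                               a = list(histone_class = "H3"),
                               b = list(kind = "histone")), "overlap")
})

test_that("the cell-list search equals the exhaustive count and is symmetric", {
  set.seed(41)
  for (i in 1:20) {
    A <- random_cloud(300); B <- random_cloud(400)
    xyz <- rbind(A, B)
    got <- count_contacts(xyz, seq_len(300), 300 + seq_len(400), cutoff = 6)
    expect_identical(got, brute_count_within(A, B, 6))
    expect_identical(got,
                     count_contacts(xyz, 300 + seq_len(400), seq_len(300),
                                    cutoff = 6))
  }
})

test_that("copy averaging pools the two histone copies", {
  a <- toy_copy_assembly()
  tr <- new_trajectory(a, list(a$xyz))
  # copy 1 of H3 sees 2 contacts, copy 2 sees 1: profile mean 1.5
  pr <- residue_profile(tr, a = list(histone_class = "H3"),
                        b = list(histone_class = "H2A"))
  expect_equal(nrow(pr$axis), 1L)
  expect_equal(pr$mean, 1.5)
  expect_equal(pr$total_mean, 1.5)
  # identical copies: the average equals either copy
  b <- a
  b$xyz[6, ] <- c(1002, 0, 0)   # give copy 2 a second in-range atom
  pr2 <- residue_profile(new_trajectory(b, list(b$xyz)),
                         a = list(histone_class = "H3"),
                         b = list(histone_class = "H2A"))
  expect_equal(pr2$mean, 2)
})

test_that("frame averaging precedes copy and replica averaging", {
  a <- toy_copy_assembly()
  far <- a$xyz
  far[c(2, 3, 5, 6), 1] <- far[c(2, 3, 5, 6), 1] + 5000  # frame 2: H2A moved away
  tr <- new_trajectory(a, list(a$xyz, far))
  pr <- residue_profile(tr, a = list(histone_class = "H3"),
                        b = list(histone_class = "H2A"))
  expect_equal(pr$mean, 0.75)   # mean over frames (2,0)/2 and (1,0)/2, copies
})

test_that("replica profiles reproduce hand-computed means and population SDs", {
  a <- toy_q_assembly()      # residue i of A contacts its partner once
  x1 <- a$xyz
  x2 <- a$xyz
  x2[10 + 1:5, 2] <- 100     # replica 2: residues 1..5 lose their contact
  tr1 <- new_trajectory(a, list(x1))
  tr2 <- new_trajectory(a, list(x2))
  pr <- residue_profile(list(tr1, tr2), a = list(histone_class = "H3"),
                        b = list(kind = "dna"))
  expect_equal(unname(pr$per_replica[, 1]), rep(1, 10))
  expect_equal(unname(pr$per_replica[, 2]), c(rep(0, 5), rep(1, 5)))
  expect_equal(pr$mean, c(rep(0.5, 5), rep(1, 5)))
  expect_equal(pr$sd, c(rep(0.5, 5), rep(0, 5)))   # population SD
  expect_equal(pr$total, c(10, 5))
  expect_equal(pr$total_mean, 7.5)
  expect_equal(pr$total_sd, 2.5)
})

test_that("region totals sum per replica and are additive over partitions", {
  a <- toy_region_assembly()  # residue i has exactly i contacts
  tr <- new_trajectory(a, list(a$xyz))
  pr <- residue_profile(tr, a = list(histone_class = "H3"),
                        b = list(kind = "dna"))
  expect_equal(pr$mean, as.numeric(1:10))
  mid <- region_total(pr, region_annotation("mid", 4, 6,
                                            histone_class = "H3"))
  expect_equal(mid$mean, 15)
  expect_equal(mid$n_residues, 3L)
  parts <- list(c(1, 3), c(4, 6), c(7, 10))
  total <- sum(vapply(parts, function(p)
    region_total(pr, list(start = p[1], end = p[2]))$mean, numeric(1)))
  expect_equal(total, region_total(pr, list(start = 1, end = 10))$mean)
  expect_equal(total, 55)
  expect_error(region_total(pr, list(start = 11, end = 12)), "no residues")
})

test_that("shipped region presets carry the expected ranges", {
  rg <- preset_regions()
  l2a <- rg[rg$name == "L2" & rg$histone_class == "H2A", ]
  expect_equal(c(l2a$start, l2a$end), c(74, 79))       # 74-KKTRII
  l2b <- rg[rg$name == "L2" & rg$histone_class == "H2A.B", ]
  expect_equal(c(l2b$start, l2b$end), c(78, 83))       # 78-GERNII
  expect_false("Ct" %in% rg$name[rg$histone_class == "H2A.B"])
})

test_that("native-contact sets match brute-force enumeration", {
  set.seed(43)
  a <- toy_q_assembly()
  ns <- build_native_contacts(a, granularity = "atom", cutoff = 6)
  expect_equal(ns$n, 10L)
  expect_equal(as.data.frame(ns$pairs), brute_native_atom_pairs(a, 6))
  # a pair at exactly the cutoff is excluded
  b <- a
  b$xyz[11, 2] <- 6       # first pair distance 6.0 exactly
  expect_equal(build_native_contacts(b, cutoff = 6)$n, 9L)
  # random toy complex against the exhaustive loop
  df <- data.frame(chain = rep(c("A", "I"), each = 30),
                   resid = rep(1:10, 6), name = "CA", elem = "C")
  set.seed(44)
  df$x <- runif(60, 0, 15); df$y <- runif(60, 0, 15); df$z <- runif(60, 0, 15)
  r <- toy_assembly(df, rbind(chain_row("A", "histone", "H3", 1L),
                              chain_row("I", "dna")))
  ns2 <- build_native_contacts(r, granularity = "atom", cutoff = 6)
  expect_equal(as.data.frame(ns2$pairs), brute_native_atom_pairs(r, 6))
})

test_that("residue-granularity native sets exclude sequence neighbours", {
  # 5 consecutive residues on one chain, 3 A apart in a line
  df <- data.frame(chain = "A", resid = 1:5, name = "CA", elem = "C",
                   x = 3 * (1:5), y = 0, z = 0)
  a <- toy_assembly(df, chain_row("A", "histone", "H3", 1L))
  ns <- build_native_contacts(a, granularity = "residue", cutoff = 7)
  # pairs within 7 A: (i, i+1) at 3 A and (i, i+2) at 6 A, all |i-j| < 3
  expect_equal(ns$n, 0L)
  ns2 <- build_native_contacts(a, granularity = "residue", cutoff = 10)
  # (i, i+3) at 9 A survive the exclusion
  expect_equal(ns2$n, 2L)
})

test_that("the q factor satisfies its contract", {
  a <- toy_q_assembly()
  ns <- build_native_contacts(a, granularity = "atom", cutoff = 6)
  expect_equal(q_factor(a, ns), 1)
  # separating the components by 100 A breaks every native contact
  apart <- a$xyz
  apart[11:20, ] <- apart[11:20, ] + 100
  expect_equal(q_factor(apart, ns), 0)
  # stretching exactly half the native pairs gives q = 0.5
  half <- a$xyz
  half[11:15, 2] <- half[11:15, 2] + 50
  expect_equal(q_factor(half, ns), 0.5)
  # tolerance factor 1: a pair just over the native cutoff is broken
  j1 <- a$xyz
  j1[11, 2] <- 6.5
  expect_equal(q_factor(j1, ns, tolerance_factor = 1), 0.9)
  expect_equal(q_factor(j1, ns, tolerance_factor = 1.2), 1)
  expect_error(q_factor(a, ns, tolerance_factor = 1.2), NA)
})

test_that("q decreases monotonically as components are pulled apart", {
  a <- toy_q_assembly()
  ns <- build_native_contacts(a, granularity = "atom", cutoff = 6)
  qs <- vapply(c(0, 2, 4, 6, 10, 50), function(d) {
    x <- a$xyz
    x[11:20, 2] <- x[11:20, 2] + d
    q_factor(x, ns)
  }, numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_equal(qs[1], 1)
  expect_equal(qs[length(qs)], 0)
  # residue granularity agrees on this one-pair-per-residue toy
  nr <- build_native_contacts(a, granularity = "residue", cutoff = 6)
  expect_equal(q_factor(a, nr), 1)
  sep <- a$xyz; sep[11:20, 2] <- sep[11:20, 2] + 100
  expect_equal(q_factor(sep, nr), 0)
})

test_that("q-factor series track assembly along a trajectory", {
  a <- toy_q_assembly()
  ns <- build_native_contacts(a, cutoff = 6)
  x2 <- a$xyz; x2[11:20, 2] <- x2[11:20, 2] + 50
  tr <- new_trajectory(a, list(a$xyz, x2))
  qs <- q_series(tr, ns)
  expect_equal(qs$values, c(1, 0))
})
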