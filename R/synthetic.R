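#' Superhelix specification for a synthetic wrapped nucleosome
#'
#' Geometric parameters of an idealized nucleosome core particle: DNA
#' phosphate positions on a left-handed-style superhelical path around a
#' cylindrical bead core.  Defaults follow the canonical core-particle
#' geometry (about 1.65 superhelical turns of radius ~42 A and pitch
#' ~26 A for ~146 bp).
#'
#' @param n_bp number of base pairs (default 146).
#' @param radius superhelix radius in Angstrom (default 41.8).
#' @param pitch superhelix pitch in Angstrom per turn (default 25.9).
#' @param turns number of superhelical turns (default 1.65).
#' @param rise_per_bp spacing of linker-arm phosphates along a straight arm
#'   (Angstrom per bp); default: the superhelical path length per bp.
#' @param core_radius radius of the bead-core cylinder (default
#'   `radius - 3`).
#' @param core_bead_spacing bead spacing on the core surface lattice
#'   (default 3.0 A).
#' @param atoms_per_bp atoms per strand residue (>= 1); the first atom of
#'   each residue is the phosphate `P`, extras are placed within 2 A of it.
#' @return list of class `SuperhelixSpec`.
#' @export
superhelix_spec <- function(n_bp = 146L, radius = 41.8, pitch = 25.9,
                            turns = 1.65, rise_per_bp = NULL,
                            core_radius = radius - 3, core_bead_spacing = 3.0,
                            atoms_per_bp = 1L) {
  stopifnot(n_bp >= 2L, radius > 0, pitch > 0, turns > 0, core_radius > 0,
            core_bead_spacing > 0, atoms_per_bp >= 1L)
  if (core_radius >= radius)
    stop("core_radius must be smaller than the superhelix radius")
  theta_tot <- 2 * pi * turns
  path_len <- sqrt((radius * theta_tot)^2 + (pitch * turns)^2)
  if (is.null(rise_per_bp)) rise_per_bp <- path_len / (n_bp - 1)
  structure(list(n_bp = as.integer(n_bp), radius = radius, pitch = pitch,
                 turns = turns, rise_per_bp = rise_per_bp,
                 core_radius = core_radius,
                 core_bead_spacing = core_bead_spacing,
                 atoms_per_bp = as.integer(atoms_per_bp)),
            class = "SuperhelixSpec")
}

# phosphate positions on the superhelix, one per bp, z-centred at 0
helix_points <- function(spec) {
  theta <- (seq_len(spec$n_bp) - 1) * 2 * pi * spec$turns / (spec$n_bp - 1)
  z <- spec$pitch * theta / (2 * pi)
  cbind(spec$radius * cos(theta), spec$radius * sin(theta),
        z - max(z) / 2)
}

#' Analytic chord length of the superhelix
#'
#' Straight-line distance between the first and last phosphate of the
#' helical path; the closed form against which the measured end-to-end
#' distance of a wrapped synthetic particle is checked.
#'
#' @param spec a [superhelix_spec()].
#' @return chord length in Angstrom.
#' @export
helix_chord <- function(spec) {
  dth <- 2 * pi * spec$turns
  dz <- spec$pitch * spec$turns
  sqrt(2 * spec$radius^2 * (1 - cos(dth)) + dz^2)
}

#' Build an idealized fully wrapped nucleosome core particle
#'
#' Two DNA strands with their phosphates on (or within 2 A of) the
#' superhelical path, wrapped around a histone core modelled as a bead
#' lattice on a cylinder.  The core lattice is dense enough that every base
#' pair's minimum bead distance is below the 6 A contact cutoff (asserted
#' at build time), so the construction is wrapped by definition.  Bead
#' residues are divided over eight histone chains (two copies each of H3,
#' H4, H2A, H2B) so that copy-resolved contact analyses apply.  The build
#' is deterministic: no randomness is used.
#'
#' @param spec a [superhelix_spec()].
#' @param h2a_class histone class label for the H2A positions (use
#'   `"H2A.B"` to label a variant particle).
#' @return a `NucleoAssembly`; `labels$spec` echoes the spec.
#' @export
make_wrapped_ncp <- function(spec = superhelix_spec(), h2a_class = "H2A") {
  stopifnot(inherits(spec, "SuperhelixSpec"))
  hp <- helix_points(spec)
  n <- spec$n_bp
  k <- spec$atoms_per_bp
  # deterministic sub-2 A offsets for extra atoms and the partner strand
  extra_dirs <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                      c(0, 0, -1), c(-1, 0, 0), c(0, -1, 0))
  strand_atoms <- function(points) {
    xyz <- matrix(0, nrow(points) * k, 3)
    name <- character(nrow(points) * k)
    for (i in seq_len(nrow(points))) {
      rows <- (i - 1) * k + seq_len(k)
      xyz[rows[1], ] <- points[i, ]
      name[rows[1]] <- "P"
      if (k > 1) for (m in 2:k) {
        d <- extra_dirs[(m - 2) %% nrow(extra_dirs) + 1, ]
        xyz[rows[m], ] <- points[i, ] + 1.4 * d
        name[rows[m]] <- paste0("C", m - 1)
      }
    }
    list(xyz = xyz, name = name)
  }
  s1 <- strand_atoms(hp)
  # strand 2: residue j pairs bp n+1-j; atoms offset 1.2 A axially
  hp2 <- hp[n:1, , drop = FALSE]
  hp2[, 3] <- hp2[, 3] + 1.2
  s2 <- strand_atoms(hp2)

  # core bead lattice on the cylinder surface spanning the DNA's z range
  zr <- range(hp[, 3])
  zs <- seq(zr[1] - 1, zr[2] + 1, by = spec$core_bead_spacing)
  nang <- max(8L, ceiling(2 * pi * spec$core_radius / spec$core_bead_spacing))
  ang <- (seq_len(nang) - 1) * 2 * pi / nang
  core <- cbind(rep(spec$core_radius * cos(ang), length(zs)),
                rep(spec$core_radius * sin(ang), length(zs)),
                rep(zs, each = nang))
  ncore <- nrow(core)
  hist_chains <- c("A", "B", "C", "D", "E", "F", "G", "H")
  split_sizes <- rep(ncore %/% 8L, 8L)
  if (ncore %% 8L) split_sizes[seq_len(ncore %% 8L)] <-
    split_sizes[seq_len(ncore %% 8L)] + 1L
  core_chain <- rep(hist_chains, times = split_sizes)
  core_resid <- unlist(lapply(split_sizes, seq_len), use.names = FALSE)

  atoms <- data.frame(
    chain = c(rep("I", n * k), rep("J", n * k), core_chain),
    resid = c(rep(seq_len(n), each = k), rep(seq_len(n), each = k),
              core_resid),
    resname = c(rep("DA", n * k), rep("DT", n * k),
                rep("ALA", ncore)),
    name = c(s1$name, s2$name, rep("CA", ncore)),
    elem = c(ifelse(s1$name == "P", "P", "C"),
             ifelse(s2$name == "P", "P", "C"), rep("C", ncore)),
    stringsAsFactors = FALSE)
  atoms$heavy <- TRUE
  xyz <- rbind(s1$xyz, s2$xyz, core)
  classes <- c("H3", "H4", h2a_class, "H2B")
  chains <- data.frame(
    chain_id = c(hist_chains, "I", "J"),
    kind = c(rep("histone", 8), "dna", "dna"),
    histone_class = c(classes, classes, NA, NA),
    copy_index = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, NA, NA),
    stringsAsFactors = FALSE)
  pairing <- data.frame(bp = seq_len(n), chain1 = "I", resid1 = seq_len(n),
                        chain2 = "J", resid2 = n + 1L - seq_len(n),
                        stringsAsFactors = FALSE)
  ncp <- new_assembly(atoms, xyz, chains, pairing,
                      labels = list(spec = unclass(spec),
                                    h2a_class = h2a_class))
  # construction guarantee: wrapped under the 6 A rule
  rec <- count_unwrapped(ncp, cutoff = 6.0)
  if (rec$n_total != 0L)
    stop("superhelix spec does not produce a wrapped particle; ",
         "tighten core_bead_spacing or core_radius")
  ncp
}

#' Peel terminal base pairs off a wrapped particle
#'
#' Displaces the first `n_entry` and last `n_exit` base pairs radially
#' outward from the superhelix axis by `cutoff + lift`, which guarantees
#' that each peeled base pair's minimum distance to every core bead exceeds
#' `cutoff + lift` (the core lies at least the radial gap further in).  All
#' other base pairs are untouched, and the planted counts are attached as
#' ground-truth labels.
#'
#' @param ncp a wrapped `NucleoAssembly` from [make_wrapped_ncp()].
#' @param n_entry,n_exit number of base pairs peeled at the entry and exit
#'   termini; their sum must be less than `n_bp`.
#' @param lift clearance margin above the cutoff, Angstrom (> 0).
#' @param cutoff the contact cutoff the clearance is measured against
#'   (default 6.0).
#' @return the modified `NucleoAssembly` with `labels$peel` set.
#' @export
peel_ends <- function(ncp, n_entry, n_exit, lift = 4, cutoff = 6.0) {
  stopifnot(inherits(ncp, "NucleoAssembly"))
  n <- n_bp(ncp)
  if (n_entry < 0L || n_exit < 0L) stop("peel counts must be >= 0")
  if (n_entry + n_exit >= n) stop("peel ranges overlap: n_entry + n_exit must be < n_bp")
  if (lift <= 0) stop("lift must be > 0")
  d <- cutoff + lift
  peel_bp <- c(seq_len(n_entry), if (n_exit > 0) (n - n_exit + 1L):n)
  bp_all <- bp_atom_list(ncp, heavy_only = FALSE)
  for (i in peel_bp) {
    idx <- bp_all[[i]]
    ctr <- colMeans(ncp$xyz[idx, , drop = FALSE])
    u <- c(ctr[1], ctr[2], 0)
    u <- u / sqrt(sum(u^2))
    ncp$xyz[idx, ] <- ncp$xyz[idx, , drop = FALSE] +
      rep(d, length(idx)) %o% u
  }
  ncp$labels$peel <- list(n_entry = as.integer(n_entry),
                          n_exit = as.integer(n_exit),
                          lift = lift, cutoff = cutoff)
  ncp
}

#' Two-state DNA-breathing specification
#'
#' Per-end two-state (closed/open) Markov model for spontaneous terminal
#' DNA detachment: per-frame opening and closing probabilities, the number
#' of base pairs peeled while open, the trajectory length, and the RNG
#' seed.  The stationary open-state occupancy is
#' `k_open / (k_open + k_close)`.
#'
#' @param k_open,k_close per-frame transition probabilities, in `[0, 1]`
#'   (not both 0).
#' @param n_unwrap_open base pairs peeled per open end (<`n_bp/2`).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list of class `BreathingSpec`.
#' @export
breathing_spec <- function(k_open = 0.1, k_close = 0.3,
                           n_unwrap_open = 15L, n_frames = 1000L,
                           seed = 1L) {
  stopifnot(k_open >= 0, k_open <= 1, k_close >= 0, k_close <= 1,
            n_unwrap_open >= 1L, n_frames >= 1L)
  structure(list(k_open = k_open, k_close = k_close,
                 n_unwrap_open = as.integer(n_unwrap_open),
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "BreathingSpec")
}

simulate_two_state <- function(k_open, k_close, n) {
  s <- integer(n)  # 0 = closed, 1 = open; start closed
  u <- runif(n)
  state <- 0L
  for (t in seq_len(n)) {
    state <- if (state == 0L) {
      if (u[t] < k_open) 1L else 0L
    } else {
      if (u[t] < k_close) 0L else 1L
    }
    s[t] <- state
  }
  s
}

#' Generate a stochastic DNA-breathing trajectory
#'
#' Each DNA end follows an independent two-state Markov chain (closed /
#' open) with the given per-frame transition probabilities; open frames
#' have that end's terminal `n_unwrap_open` base pairs peeled.  The
#' ground-truth state sequences are attached, and a fixed seed makes the
#' trajectory bit-identical across runs.
#'
#' @param spec a [superhelix_spec()].
#' @param breath a [breathing_spec()].
#' @param lift peel clearance margin, Angstrom (default 4).
#' @return a `Trajectory`; `labels` holds `entry_states`, `exit_states`
#'   (0/1 per frame), the specs and the seed.
#' @export
make_breathing_trajectory <- function(spec = superhelix_spec(),
                                      breath = breathing_spec(),
                                      lift = 4) {
  stopifnot(inherits(breath, "BreathingSpec"))
  if (breath$n_unwrap_open >= spec$n_bp / 2)
    stop("n_unwrap_open must be below n_bp / 2")
  wrapped <- make_wrapped_ncp(spec)
  states <- with_seed(breath$seed, {
    entry <- simulate_two_state(breath$k_open, breath$k_close,
                                breath$n_frames)
    exit <- simulate_two_state(breath$k_open, breath$k_close,
                               breath$n_frames)
    list(entry = entry, exit = exit)
  })
  # the four attainable conformations, indexed by (entry, exit) state
  variants <- list(
    `00` = wrapped$xyz,
    `10` = peel_ends(wrapped, breath$n_unwrap_open, 0L, lift)$xyz,
    `01` = peel_ends(wrapped, 0L, breath$n_unwrap_open, lift)$xyz,
    `11` = peel_ends(wrapped, breath$n_unwrap_open,
                     breath$n_unwrap_open, lift)$xyz)
  nf <- breath$n_frames
  coords <- array(0, dim = c(nrow(wrapped$atoms), 3L, nf))
  keys <- paste0(states$entry, states$exit)
  for (f in seq_len(nf)) coords[, , f] <- variants[[keys[f]]]
  new_trajectory(wrapped, coords,
                 labels = list(spec = unclass(spec),
                               breathing = unclass(breath),
                               entry_states = states$entry,
                               exit_states = states$exit,
                               lift = lift))
}

#' Stationary occupancy and autocorrelation-corrected standard error
#'
#' For a two-state chain with per-frame probabilities `k_open`/`k_close`,
#' the stationary open occupancy is `p = k_open / (k_open + k_close)` and
#' the standard error of its n-frame occupancy estimate is
#' `sqrt(p (1 - p) / n) * sqrt((1 + rho) / (1 - rho))` with lag-1
#' autocorrelation `rho = 1 - k_open - k_close`.
#'
#' @param k_open,k_close transition probabilities.
#' @param n_frames sample size.
#' @return list with `p` and `se`.
#' @export
breathing_occupancy_theory <- function(k_open, k_close, n_frames) {
  p <- k_open / (k_open + k_close)
  rho <- 1 - k_open - k_close
  list(p = p,
       se = sqrt(p * (1 - p) / n_frames) * sqrt((1 + rho) / (1 - rho)))
}

#' Chromatosome specification
#'
#' A wrapped core particle plus two straight linker-DNA arms appended at
#' the entry and exit termini, oriented so that the two arm angles
#' P1-P2-P4 and P3-P4-P2 (terminal/proximal phosphates of arm 1 and arm 2)
#' hit the given targets, and an optional linker-histone bead cluster.
#'
#' @param core a [superhelix_spec()].
#' @param linker_length_bp phosphates per arm (default 20, >= 2).
#' @param angles length-2 numeric: target P1-P2-P4 and P3-P4-P2 angles in
#'   degrees, each in (0, 180).
#' @param noise_sd SD of Gaussian perturbation added to each target angle
#'   (degrees; 0 = exact construction).
#' @param include_h1 add a small linker-histone bead chain (default TRUE).
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list of class `ChromatosomeSpec`.
#' @export
chromatosome_spec <- function(core = superhelix_spec(),
                              linker_length_bp = 20L,
                              angles = c(90, 90), noise_sd = 0,
                              include_h1 = TRUE, seed = 1L) {
  stopifnot(inherits(core, "SuperhelixSpec"), linker_length_bp >= 2L,
            length(angles) == 2L, all(angles > 0), all(angles < 180),
            noise_sd >= 0)
  structure(list(core = core,
                 linker_length_bp = as.integer(linker_length_bp),
                 angles = as.numeric(angles), noise_sd = noise_sd,
                 include_h1 = include_h1, seed = as.integer(seed)),
            class = "ChromatosomeSpec")
}

unit <- function(v) v / sqrt(sum(v^2))

# direction perpendicular to d, as close as possible to the hint direction
perp_toward <- function(d, hint) {
  w <- hint - sum(hint * d) * d
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) {  # hint parallel to d: fall back to the helix axis
    w <- c(0, 0, 1) - sum(c(0, 0, 1) * d) * d
    nw <- sqrt(sum(w^2))
  }
  w / nw
}

#' Build a chromatosome with articulated linker arms
#'
#' Appends two straight linker arms at the entry and exit phosphates of a
#' wrapped particle.  Arm directions are solved by fixed-point iteration so
#' that the measured angles P1-P2-P4 and P3-P4-P2 equal the (optionally
#' noise-perturbed) targets to machine precision; arms that would collide
#' with the bead core (closer than 6 A) are rejected as infeasible.  The
#' anchor atoms P1..P4 are recorded as named selections on the returned
#' assembly.
#'
#' @param spec a [chromatosome_spec()].
#' @return a `NucleoAssembly` with linker chains `X`, `Y` (and `K` for H1),
#'   `selections` P1..P4, and ground-truth labels (targets, realized
#'   angles, seed).
#' @export
make_chromatosome <- function(spec = chromatosome_spec()) {
  stopifnot(inherits(spec, "ChromatosomeSpec"))
  ncp <- make_wrapped_ncp(spec$core)
  targets <- spec$angles
  if (spec$noise_sd > 0)
    targets <- targets + with_seed(spec$seed, rnorm(2, 0, spec$noise_sd))
  targets <- pmin(pmax(targets, 1e-6), 180 - 1e-6)
  a <- ncp$xyz[terminal_p_atom(ncp, "entry"), ]
  b <- ncp$xyz[terminal_p_atom(ncp, "exit"), ]
  r <- spec$core$rise_per_bp
  alpha <- targets[1] * pi / 180
  beta <- targets[2] * pi / 180
  L <- spec$linker_length_bp
  core_idx <- atom_indices(ncp, kind = "histone")
  core_xyz <- ncp$xyz[core_idx, , drop = FALSE]
  # candidate in-plane orientations for each arm, tried in a deterministic
  # order: away from the core centre, radially outward, axially, then a
  # sweep of azimuths in between
  hints <- function(p) {
    base <- list(unit(p), unit(c(p[1], p[2], 0)),
                 c(0, 0, 1), c(0, 0, -1))
    e1 <- unit(c(p[1], p[2], 0))
    e2 <- c(0, 0, 1)
    sweep_dirs <- lapply(seq(0, 330, by = 30) * pi / 180, function(ps)
      cos(ps) * e1 + sin(ps) * e2)
    c(base, sweep_dirs)
  }
  solve_arms <- function(h1, h2) {
    u1 <- h1; u2 <- h2
    for (it in 1:500) {
      p2 <- a + r * u1; p4 <- b + r * u2
      d1 <- unit(p4 - p2)           # ray P2 -> P4
      d2 <- -d1                     # ray P4 -> P2
      u1n <- cos(alpha) * d1 + sin(alpha) * perp_toward(d1, h1)
      u2n <- cos(beta) * d2 + sin(beta) * perp_toward(d2, h2)
      delta <- max(sum((u1n - u1)^2), sum((u2n - u2)^2))
      u1 <- u1n; u2 <- u2n
      if (delta < 1e-24) break
    }
    list(u1 = u1, u2 = u2, converged = delta < 1e-12)
  }
  arm_xyz <- function(origin, u)
    sweep((seq_len(L) * r) %o% u, 2, origin, "+")
  # infeasible if an arm pierces the bead-core cylinder or overlaps a bead;
  # mere contact-range proximity near the attachment point is physical
  zr <- range(core_xyz[, 3])
  collides <- function(xyz) {
    cpp_min_dist(xyz, core_xyz) < 2.5 ||
      any(sqrt(xyz[, 1]^2 + xyz[, 2]^2) < spec$core$core_radius &
            xyz[, 3] > zr[1] & xyz[, 3] < zr[2])
  }
  sol <- NULL
  for (h1 in hints(a)) {
    for (h2 in hints(b)) {
      cand <- solve_arms(h1, h2)
      if (!cand$converged) next
      if (!collides(arm_xyz(a, cand$u1)) && !collides(arm_xyz(b, cand$u2))) {
        sol <- cand
        break
      }
    }
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("infeasible linker angle targets: arms collide with the core")
  arm1 <- arm_xyz(a, sol$u1)   # row 1 = P2 (proximal), row L = P1
  arm2 <- arm_xyz(b, sol$u2)   # row 1 = P4 (proximal), row L = P3

  add <- function(x, chain, kind, class, xyz, name, resname, elem,
                  linker = FALSE) {
    nr <- nrow(xyz)
    x$atoms <- rbind(x$atoms, data.frame(
      chain = chain, resid = seq_len(nr), resname = resname, name = name,
      elem = elem, heavy = TRUE, stringsAsFactors = FALSE))
    x$xyz <- rbind(x$xyz, xyz)
    x$chains <- rbind(x$chains, data.frame(
      chain_id = chain, kind = kind, histone_class = class,
      copy_index = NA, linker = linker, stringsAsFactors = FALSE))
    x
  }
  ncp <- add(ncp, "X", "dna", NA, arm1, "P", "DA", "P", linker = TRUE)
  ncp <- add(ncp, "Y", "dna", NA, arm2, "P", "DA", "P", linker = TRUE)
  if (spec$include_h1) {
    m <- (arm1[1, ] + arm2[1, ]) / 2
    dirm <- unit(c(m[1], m[2], 0))
    h1 <- sweep((0:4) %o% (2 * dirm), 2, m + 4 * dirm, "+")
    ncp <- add(ncp, "K", "linker_histone", "H1", h1, "CA", "ALA", "C")
  }
  i1 <- which(ncp$atoms$chain == "X")
  i2 <- which(ncp$atoms$chain == "Y")
  ncp$selections <- list(P1 = i1[L], P2 = i1[1], P3 = i2[L], P4 = i2[1])
  meas <- linker_angle_series(ncp)
  ncp$labels$chromatosome <- list(
    target_angles = spec$angles, realized_targets = targets,
    measured_angles = c(meas$angle_P1_P2_P4, meas$angle_P3_P4_P2),
    noise_sd = spec$noise_sd, seed = spec$seed,
    linker_length_bp = L)
  validate_assembly(ncp)
  ncp
}

#' Write a synthetic fixture with its ground-truth sidecar
#'
#' Writes the structure (or multi-model trajectory) as PDB next to a JSON
#' sidecar holding the generator specs, seeds, and ground-truth labels.
#'
#' @param x a `NucleoAssembly` or `Trajectory` built by the generators.
#' @param prefix output path prefix; writes `<prefix>.pdb` and
#'   `<prefix>.json`.
#' @return named character vector of the two paths, invisibly.
#' @export
write_fixture <- function(x, prefix) {
  pdb <- paste0(prefix, ".pdb")
  json <- paste0(prefix, ".json")
  write_structure(x, pdb)
  labels <- if (inherits(x, "Trajectory")) x$labels else x$labels
  jsonlite::write_json(labels, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(pdb = pdb, json = json))
}
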