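#' Region annotation
#'
#' A named residue range on a chain or histone class (1-based, inclusive),
#' used for region contact totals and core-selection exclusions.
#'
#' @param name region name (e.g. `"Nt"`, `"L2"`, `"docking"`, `"Ct"`,
#'   `"alphaN"`).
#' @param start,end first and last residue index of the range.
#' @param chain chain id the range lives on, or `NA` to address by class.
#' @param histone_class histone class the range applies to (both copies).
#' @return one-row data.frame with columns `name`, `chain`,
#'   `histone_class`, `start`, `end`.
#' @export
region_annotation <- function(name, start, end, chain = NA,
                              histone_class = NA) {
  stopifnot(start >= 1L, end >= start)
  data.frame(name = name, chain = chain, histone_class = histone_class,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Shipped region presets
#'
#' Editable default residue ranges for the regions commonly analysed on
#' H2A-family histones and H3.  The L2 ranges follow the sequences
#' 74-KKTRII (H2A) and 78-GERNII (H2A.B); the H2A C-terminal tail is
#' 107-129 and its docking domain 80-106, with the H2A.B docking domain
#' incomplete (84-114, no Ct).  The remaining ranges (tails, H3 alphaN) are
#' reconstructions by sequence convention and should be adjusted to the
#' numbering of the structures actually analysed.
#'
#' @return data.frame of [region_annotation()] rows.
#' @export
preset_regions <- function() {
  rbind(
    region_annotation("Nt", 1, 13, histone_class = "H2A"),
    region_annotation("L2", 74, 79, histone_class = "H2A"),
    region_annotation("docking", 80, 106, histone_class = "H2A"),
    region_annotation("Ct", 107, 129, histone_class = "H2A"),
    region_annotation("Nt", 1, 8, histone_class = "H2A.B"),
    region_annotation("L2", 78, 83, histone_class = "H2A.B"),
    region_annotation("docking", 84, 114, histone_class = "H2A.B"),
    region_annotation("alphaN", 45, 57, histone_class = "H3"))
}

# atoms addressed by one region-annotation row
region_atoms <- function(x, region, heavy_only = TRUE) {
  args <- list(x, resid = seq.int(region$start, region$end),
               heavy_only = heavy_only)
  if (!is.na(region$chain)) args$chain <- region$chain
  if (!is.na(region$histone_class)) args$histone_class <- region$histone_class
  do.call(atom_indices, args)
}

#' Count heavy-atom contacts between two selections
#'
#' A contact is a pair of atoms, one from each selection, strictly closer
#' than the cutoff.  The two selections must be disjoint.
#'
#' @param x a `NucleoAssembly`, or an `n x 3` coordinate matrix (then
#'   `sel_a`/`sel_b` index its rows).
#' @param sel_a,sel_b atom selections (index vectors or [atom_indices()]
#'   argument lists).
#' @param cutoff contact cutoff in Angstrom (default 6.0; strict `<`).
#' @return integer contact count.
#' @export
count_contacts <- function(x, sel_a, sel_b, cutoff = 6.0) {
  if (is.matrix(x)) {
    ia <- as.integer(sel_a); ib <- as.integer(sel_b); xyz <- x
  } else {
    ia <- resolve_selection(x, sel_a, what = "selection A")
    ib <- resolve_selection(x, sel_b, what = "selection B")
    xyz <- x$xyz
  }
  if (length(intersect(ia, ib)))
    stop("contact selections overlap")
  cpp_count_within(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE], cutoff)
}

# per-residue contact counts of component atoms `ia` against `ib`, on the
# residue axis `axis_resid` (resid values within the component chain)
profile_one_frame <- function(xyz, ia, ib, resid_a, axis_resid, cutoff) {
  pr <- cpp_pairs_within(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                         cutoff)
  pos <- match(resid_a[pr$i], axis_resid)
  tabulate(pos, nbins = length(axis_resid))
}

#' Per-residue contact profile with copy and replica averaging
#'
#' For every residue of component A, counts its heavy-atom contacts with
#' component B per frame, averages over frames, then over the two histone
#' copies, and finally reports the cross-replica mean and population SD.
#'
#' @param trajs a `Trajectory` or a list of replica `Trajectory` objects
#'   sharing one topology.
#' @param a component A: an [atom_indices()] argument list, typically
#'   `list(histone_class = "H3")`; its residue axis is the profile axis.
#' @param b component B: an argument list, e.g. `list(kind = "dna")` or
#'   another histone class.
#' @param cutoff contact cutoff in Angstrom (default 6.0).
#' @param pair_copies `"auto"` (default), `"paired"`, or `"all"`.  When
#'   paired, copy k of A is counted against copy `copy_map[k]` of B;
#'   `"all"` counts each copy of A against all of B.  `"auto"` pairs
#'   whenever both components are histone classes with the same number of
#'   copies.
#' @param copy_map integer vector mapping A copy index to B copy index
#'   (default identity, i.e. copies pair by chain-id order).
#' @return object of class `ContactProfile`: list with `axis` (data.frame
#'   `resid`, `resname`), `per_replica` (matrix residues x replicas of
#'   frame- and copy-averaged counts), `mean`, `sd` (population, across
#'   replicas), `total` (per-replica totals with `total_mean`/`total_sd`),
#'   and `meta`.
#' @export
residue_profile <- function(trajs, a, b, cutoff = 6.0,
                            pair_copies = c("auto", "paired", "all"),
                            copy_map = NULL) {
  pair_copies <- match.arg(pair_copies)
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  topo <- trajs[[1]]$topology
  ch <- topo$chains
  class_a <- if (is.list(a)) a$histone_class else NULL
  class_b <- if (is.list(b)) b$histone_class else NULL
  copies_a <- if (!is.null(class_a))
    sort(ch$copy_index[!is.na(ch$histone_class) &
                       ch$histone_class == class_a]) else integer(0)
  copies_b <- if (!is.null(class_b))
    sort(ch$copy_index[!is.na(ch$histone_class) &
                       ch$histone_class == class_b]) else integer(0)
  paired <- switch(pair_copies,
    auto = length(copies_a) > 1L && length(copies_a) == length(copies_b),
    paired = TRUE, all = FALSE)
  if (pair_copies == "paired" &&
      (length(copies_a) == 0L || length(copies_a) != length(copies_b)))
    stop("copy pairing requested but copies cannot be matched")
  if (length(copies_a) == 0L) copies_a <- NA  # single-component A
  if (is.null(copy_map)) copy_map <- seq_along(copies_a)

  # per-copy atom sets of A; a shared residue axis is required across copies
  sets_a <- lapply(copies_a, function(cp) {
    args <- a
    if (!is.na(cp)[1]) args$copy_index <- cp
    resolve_selection(topo, args, what = "component A")
  })
  axis_resid <- sort(unique(topo$atoms$resid[sets_a[[1]]]))
  for (s in sets_a)
    if (!identical(sort(unique(topo$atoms$resid[s])), axis_resid))
      stop("A copies do not share one residue axis")
  sets_b <- lapply(seq_along(copies_a), function(k) {
    args <- b
    if (paired) args$copy_index <- copies_b[copy_map[k]]
    resolve_selection(topo, args, what = "component B")
  })
  for (k in seq_along(sets_a))
    if (length(intersect(sets_a[[k]], sets_b[[k]])))
      stop("components overlap; contacts are defined between two components")

  nres <- length(axis_resid)
  per_replica <- matrix(vapply(trajs, function(tr) {
    nf <- n_frames(tr)
    copy_profiles <- matrix(vapply(seq_along(sets_a), function(k) {
      ia <- sets_a[[k]]; ib <- sets_b[[k]]
      resid_a <- topo$atoms$resid[ia]
      acc <- numeric(nres)
      for (f in seq_len(nf))
        acc <- acc + profile_one_frame(frame_xyz(tr, f), ia, ib, resid_a,
                                       axis_resid, cutoff)
      acc / nf
    }, numeric(nres)), nrow = nres)
    rowMeans(copy_profiles)
  }, numeric(nres)), nrow = nres)

  mu <- rowMeans(per_replica)
  sdv <- sqrt(rowMeans((per_replica - mu)^2))
  first_atoms <- sets_a[[1]][!duplicated(topo$atoms$resid[sets_a[[1]]])]
  resname <- topo$atoms$resname[first_atoms][
    match(axis_resid, topo$atoms$resid[first_atoms])]
  totals <- colSums(per_replica)
  structure(list(
    axis = data.frame(resid = axis_resid, resname = resname,
                      stringsAsFactors = FALSE),
    per_replica = per_replica, mean = mu, sd = sdv,
    total = totals, total_mean = mean(totals),
    total_sd = sqrt(mean((totals - mean(totals))^2)),
    meta = list(cutoff = cutoff, paired_copies = paired,
                n_replicas = ncol(per_replica),
                component_a = a, component_b = b,
                sd_convention = "population")),
    class = "ContactProfile")
}

#' @export
print.ContactProfile <- function(x, ...) {
  cat(sprintf(
    "ContactProfile: %d residues, %d replica(s); total %.1f +/- %.1f contacts\n",
    nrow(x$axis), x$meta$n_replicas, x$total_mean, x$total_sd))
  invisible(x)
}

#' ContactProfile as a writable table
#' @param x a `ContactProfile`.
#' @param ... unused.
#' @return data.frame with columns `resid`, `resname`, `mean_contacts`,
#'   `sd_contacts`.
#' @export
as.data.frame.ContactProfile <- function(x, ...) {
  data.frame(resid = x$axis$resid, resname = x$axis$resname,
             mean_contacts = x$mean, sd_contacts = x$sd,
             stringsAsFactors = FALSE)
}

#' Regional contact total
#'
#' Sums the per-residue contact counts of a profile over a region's residue
#' range per replica, then reports the cross-replica mean and population
#' SD.  A region with no residue on the profile axis is an error, not a
#' zero.
#'
#' @param profile a `ContactProfile`.
#' @param region a [region_annotation()] row, or any list with `start` and
#'   `end`.
#' @return list with `mean`, `sd`, `per_replica`, `n_residues`.
#' @export
region_total <- function(profile, region) {
  stopifnot(inherits(profile, "ContactProfile"))
  rows <- which(profile$axis$resid >= region$start &
                profile$axis$resid <= region$end)
  if (length(rows) == 0L)
    stop("region [", region$start, ", ", region$end,
         "] has no residues on the profile axis")
  per_rep <- colSums(profile$per_replica[rows, , drop = FALSE])
  list(mean = mean(per_rep),
       sd = sqrt(mean((per_rep - mean(per_rep))^2)),
       per_replica = per_rep, n_residues = length(rows))
}

#' Build the native-contact set of a reference structure
#'
#' Enumerates all contacts present in the reference under the strict
#' distance rule, excluding pairs within one residue and, at residue
#' granularity, sequence neighbours (|i - j| < `neighbor_exclusion` on the
#' same chain).
#'
#' @param ref a `NucleoAssembly` (the native/reference conformation).
#' @param granularity `"atom"` (atom pairs) or `"residue"` (residue pairs,
#'   formed when any heavy-atom pair is within the cutoff).
#' @param cutoff contact cutoff in Angstrom (default 6.0; strict `<`).
#' @param sel atom selection defining the universe (default all heavy
#'   atoms).
#' @param neighbor_exclusion minimum sequence separation on the same chain
#'   for residue-granularity pairs (default 3).
#' @return object of class `NativeContactSet` with the canonically sorted,
#'   duplicate-free pair list and `n` the total count.
#' @export
build_native_contacts <- function(ref, granularity = c("atom", "residue"),
                                  cutoff = 6.0, sel = NULL,
                                  neighbor_exclusion = 3L) {
  granularity <- match.arg(granularity)
  idx <- resolve_selection(ref, sel, what = "native-contact selection")
  xyz <- ref$xyz[idx, , drop = FALSE]
  pr <- cpp_pairs_within(xyz, xyz, cutoff)
  keep <- pr$i < pr$j
  i <- idx[pr$i[keep]]; j <- idx[pr$j[keep]]
  at <- ref$atoms
  same_res <- at$chain[i] == at$chain[j] & at$resid[i] == at$resid[j]
  i <- i[!same_res]; j <- j[!same_res]
  if (granularity == "atom") {
    ord <- order(i, j)
    pairs <- data.frame(i = i[ord], j = j[ord])
  } else {
    key <- data.frame(chain1 = at$chain[i], resid1 = at$resid[i],
                      chain2 = at$chain[j], resid2 = at$resid[j],
                      stringsAsFactors = FALSE)
    # canonical residue-pair order: by chain then residue index
    flip <- key$chain1 > key$chain2 |
      (key$chain1 == key$chain2 & key$resid1 > key$resid2)
    key[flip, c("chain1", "resid1", "chain2", "resid2")] <-
      key[flip, c("chain2", "resid2", "chain1", "resid1")]
    near <- key$chain1 == key$chain2 &
      abs(key$resid1 - key$resid2) < neighbor_exclusion
    key <- key[!near, , drop = FALSE]
    pairs <- unique(key)
    pairs <- pairs[order(pairs$chain1, pairs$resid1, pairs$chain2,
                         pairs$resid2), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  res_atoms <- if (granularity == "residue")
    split(idx, paste(at$chain[idx], at$resid[idx], sep = "\r")) else NULL
  structure(list(granularity = granularity, cutoff = cutoff,
                 pairs = pairs, n = nrow(pairs), sel = idx,
                 res_atoms = res_atoms),
            class = "NativeContactSet")
}

#' @export
print.NativeContactSet <- function(x, ...) {
  cat(sprintf("NativeContactSet: %d %s pairs (cutoff %.2f A)\n",
              x$n, x$granularity, x$cutoff))
  invisible(x)
}

#' Native-contact fraction (q factor)
#'
#' Fraction of the reference's native contacts formed in a conformation.  A
#' native pair is formed when its distance is below `tolerance_factor x
#' cutoff`; factor 1 recovers the strict native rule, the default 1.2
#' tolerates thermal stretching.  q is 1 at the reference (for any
#' tolerance >= 1) and decreases toward 0 as the assembly comes apart.
#'
#' @param x a `NucleoAssembly` or an `n x 3` coordinate matrix congruent
#'   with the reference topology.
#' @param native a [build_native_contacts()] set.
#' @param tolerance_factor multiplier on the native cutoff defining
#'   "formed" (default 1.2).
#' @return fraction in `[0, 1]`.
#' @export
q_factor <- function(x, native, tolerance_factor = 1.2) {
  stopifnot(inherits(native, "NativeContactSet"))
  if (native$n == 0L) stop("native-contact set is empty")
  xyz <- if (is.matrix(x)) x else x$xyz
  thr <- tolerance_factor * native$cutoff
  if (native$granularity == "atom") {
    d <- sqrt(rowSums((xyz[native$pairs$i, , drop = FALSE] -
                       xyz[native$pairs$j, , drop = FALSE])^2))
    return(mean(d < thr))
  }
  formed <- vapply(seq_len(native$n), function(r) {
    p <- native$pairs[r, ]
    a1 <- native$res_atoms[[paste(p$chain1, p$resid1, sep = "\r")]]
    a2 <- native$res_atoms[[paste(p$chain2, p$resid2, sep = "\r")]]
    cpp_min_dist(xyz[a1, , drop = FALSE], xyz[a2, , drop = FALSE]) < thr
  }, logical(1))
  mean(formed)
}

#' q-factor time series
#' @param traj a `Trajectory`.
#' @param native a [build_native_contacts()] set.
#' @param tolerance_factor see [q_factor()].
#' @return a `SeriesStat` of per-frame q values.
#' @export
q_series <- function(traj, native, tolerance_factor = 1.2) {
  stopifnot(inherits(traj, "Trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    q_factor(frame_xyz(traj, f), native, tolerance_factor), numeric(1))
  series_stat(vals, meta = list(metric = "q_factor",
                                tolerance_factor = tolerance_factor))
}
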