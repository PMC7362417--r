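#' Default histone-core selection
#'
#' The histone core defaults to all heavy atoms of histone chains.  Flexible
#' tail regions materially change minimum distances, so annotated regions
#' (e.g. N-/C-terminal tails) can be excluded via `exclude_regions`.
#'
#' @param x a `NucleoAssembly`.
#' @param exclude_regions optional data.frame of region annotations (see
#'   [region_annotation()]) whose residues are dropped from the core.
#' @return integer vector of core atom indices.
#' @export
core_selection <- function(x, exclude_regions = NULL) {
  idx <- atom_indices(x, kind = "histone")
  if (length(idx) == 0L) stop("assembly has no histone chains")
  if (!is.null(exclude_regions)) {
    drop <- unlist(lapply(seq_len(nrow(exclude_regions)), function(r)
      region_atoms(x, exclude_regions[r, ])), use.names = FALSE)
    idx <- setdiff(idx, drop)
    if (length(idx) == 0L) stop("core selection empty after exclusions")
  }
  idx
}

# heavy-atom index list per base pair, resolved in one pass per topology
bp_atom_list <- function(x, heavy_only = TRUE) {
  at <- x$atoms
  rows <- if (heavy_only) which(at$heavy) else seq_len(nrow(at))
  by_res <- split(rows, paste(at$chain[rows], at$resid[rows], sep = "\r"))
  p <- x$pairing
  lapply(seq_len(nrow(p)), function(i)
    c(by_res[[paste(p$chain1[i], p$resid1[i], sep = "\r")]],
      by_res[[paste(p$chain2[i], p$resid2[i], sep = "\r")]]))
}

# two-sided terminal scan on raw coordinates
scan_unwrap <- function(xyz, bp_list, core_xyz, cutoff,
                        diagnostics = FALSE) {
  nbp <- length(bp_list)
  dists <- if (diagnostics)
    vapply(bp_list, function(idx)
      cpp_min_dist(xyz[idx, , drop = FALSE], core_xyz), numeric(1))
  else NULL
  get_d <- if (diagnostics) function(i) dists[i] else function(i)
    cpp_min_dist(xyz[bp_list[[i]], , drop = FALSE], core_xyz)
  n_entry <- 0L
  while (n_entry < nbp && get_d(n_entry + 1L) > cutoff)
    n_entry <- n_entry + 1L
  n_exit <- 0L
  while (n_exit < nbp - n_entry && get_d(nbp - n_exit) > cutoff)
    n_exit <- n_exit + 1L
  rec <- list(n_entry = n_entry, n_exit = n_exit,
              n_total = n_entry + n_exit,
              fully_detached = n_entry + n_exit >= nbp,
              cutoff = cutoff)
  if (diagnostics) rec$bp_min_dist <- dists
  structure(rec, class = "UnwrapRecord")
}

#' Minimum heavy-atom distance of one base pair to the core
#'
#' Minimum Euclidean distance between any heavy atom of the two residues of
#' base pair `bp_index` and any atom of the core selection.
#'
#' @param x a `NucleoAssembly`.
#' @param bp_index base-pair index (1 = entry terminus).
#' @param core_sel core atom selection; default [core_selection()].
#' @return distance in Angstrom.
#' @export
bp_min_distance <- function(x, bp_index, core_sel = NULL) {
  core <- resolve_selection(x, core_sel, default = core_selection(x),
                            what = "core selection")
  bp <- bp_atoms(x, bp_index)
  cpp_min_dist(x$xyz[bp, , drop = FALSE], x$xyz[core, , drop = FALSE])
}

#' Count terminally unwrapped base pairs
#'
#' At each terminus the count N is the length of the maximal run of
#' consecutive terminal base pairs whose minimum heavy-atom distance to the
#' histone core exceeds the cutoff: the entry scan walks base pairs 1, 2,
#' ... and the exit scan n_bp, n_bp - 1, ..., each stopping at the first
#' base pair at or below the cutoff.  A base pair farther inward that
#' exceeds the cutoff (a bulge) is never counted.  A base pair at exactly
#' the cutoff stops the scan (counted as wrapped).  If the two scans meet,
#' the DNA is fully detached: `n_total = n_bp` and `fully_detached = TRUE`.
#'
#' @param x a `NucleoAssembly` with a base-pairing table.
#' @param core_sel core atom selection; default [core_selection()].
#' @param cutoff contact cutoff in Angstrom (default 6.0).
#' @param diagnostics if `TRUE`, also return every base pair's minimum core
#'   distance (forces a full scan).
#' @return list of class `UnwrapRecord` with `n_entry`, `n_exit`,
#'   `n_total`, `fully_detached`, and optionally `bp_min_dist`.
#' @export
count_unwrapped <- function(x, core_sel = NULL, cutoff = 6.0,
                            diagnostics = FALSE) {
  stopifnot(cutoff > 0)
  if (is.null(x$pairing)) stop("assembly has no base-pairing table")
  core <- resolve_selection(x, core_sel, default = core_selection(x),
                            what = "core selection")
  scan_unwrap(x$xyz, bp_atom_list(x), x$xyz[core, , drop = FALSE],
              cutoff, diagnostics)
}

#' @export
print.UnwrapRecord <- function(x, ...) {
  cat(sprintf("UnwrapRecord: entry %d + exit %d = %d unwrapped bp%s\n",
              x$n_entry, x$n_exit, x$n_total,
              if (x$fully_detached) " (fully detached)" else ""))
  invisible(x)
}

#' Unwrapped base-pair time series
#'
#' Applies the terminal unwrapping counter to every frame of a trajectory.
#' Base-pair and core atom selections are resolved once on the shared
#' topology.
#'
#' @param traj a `Trajectory`.
#' @param core_sel core atom selection; default [core_selection()] of the
#'   topology.
#' @param cutoff contact cutoff in Angstrom (default 6.0).
#' @return list with `records` (data.frame: `frame`, `n_entry`, `n_exit`,
#'   `n_total`, `fully_detached`) and `stat` (a `SeriesStat` of `n_total`).
#' @export
unwrap_series <- function(traj, core_sel = NULL, cutoff = 6.0) {
  stopifnot(inherits(traj, "Trajectory"))
  topo <- traj$topology
  core <- resolve_selection(topo, core_sel, default = core_selection(topo),
                            what = "core selection")
  bps <- bp_atom_list(topo)
  recs <- lapply(seq_len(n_frames(traj)), function(f) {
    xyz <- frame_xyz(traj, f)
    scan_unwrap(xyz, bps, xyz[core, , drop = FALSE], cutoff)
  })
  records <- data.frame(
    frame = seq_along(recs),
    n_entry = vapply(recs, `[[`, integer(1), "n_entry"),
    n_exit = vapply(recs, `[[`, integer(1), "n_exit"),
    n_total = vapply(recs, `[[`, integer(1), "n_total"),
    fully_detached = vapply(recs, `[[`, logical(1), "fully_detached"))
  list(records = records,
       stat = series_stat(records$n_total,
                          meta = list(metric = "unwrapped_bp",
                                      cutoff = cutoff)))
}
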