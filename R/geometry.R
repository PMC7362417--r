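#' Per-frame series with summary statistics
#'
#' Container for a per-frame observable: the values, their mean and SD over
#' frames, and (after [aggregate_replicas()]) the per-replica series with
#' cross-replica mean and SD.
#'
#' @param values numeric per-frame values.
#' @param sd_values optional per-frame SD across replicas.
#' @param replicas optional matrix `n_frames x n_replicas` of the underlying
#'   per-replica series.
#' @param meta named list of metadata (selection, units, conventions).
#' @return object of class `SeriesStat` with elements `values`, `mean`,
#'   `sd`, `n`, and optionally `sd_values`, `replicas`, `n_replicas`.
#' @export
series_stat <- function(values, sd_values = NULL, replicas = NULL,
                        meta = list()) {
  values <- as.numeric(values)
  structure(list(values = values, mean = mean(values),
                 sd = stats::sd(values), n = length(values),
                 sd_values = sd_values, replicas = replicas,
                 n_replicas = if (is.null(replicas)) NULL else ncol(replicas),
                 meta = meta),
            class = "SeriesStat")
}

#' @export
print.SeriesStat <- function(x, ...) {
  cat(sprintf("SeriesStat: %d frames, mean %.4g, sd %.4g", x$n,
              x$mean, x$sd))
  if (!is.null(x$n_replicas)) cat(",", x$n_replicas, "replicas")
  cat("\n")
  invisible(x)
}

#' Cross-replica aggregation of per-frame series
#'
#' Combines series from independent replicas into one series of per-frame
#' means with per-frame population SDs (divisor n, the convention used when
#' quoting mean +/- SD over a small fixed set of replicate simulations).
#'
#' @param series list of `SeriesStat` objects or numeric vectors of equal
#'   length, one per replica.
#' @return a `SeriesStat` whose `values` are per-frame cross-replica means,
#'   with `sd_values` the per-frame population SDs and `replicas` the input
#'   series as columns.
#' @export
aggregate_replicas <- function(series) {
  vals <- lapply(series, function(s)
    if (inherits(s, "SeriesStat")) s$values else as.numeric(s))
  n <- unique(vapply(vals, length, integer(1)))
  if (length(n) != 1L) stop("replica series differ in length")
  m <- do.call(cbind, vals)
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))  # population SD across replicas
  series_stat(mu, sd_values = sdv, replicas = m,
              meta = list(sd_convention = "population"))
}

#' Optimal rigid-body superposition (least squares)
#'
#' Kabsch/SVD rotation fitting `mobile` onto `ref`; reflections are
#' disallowed (determinant forced to +1).
#'
#' @param mobile,ref `n x 3` matrices of paired coordinates (n >= 3).
#' @return list with `R` (3x3 rotation), `center_mobile`, `center_ref`;
#'   apply as `sweep(x, 2, center_mobile) %*% R + center_ref`.
#' @export
kabsch_fit <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref), ncol(mobile) == 3L)
  if (nrow(mobile) < 3L) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  s <- svd(crossprod(P, Q))          # H = P^T Q = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, center_mobile = cm, center_ref = cr)
}

apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$center_mobile) %*% fit$R, 2, fit$center_ref, "+")
}

rmsd_pair <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series after least-squares superposition
#'
#' For each frame, the atoms in `fit_sel` are superposed onto the reference
#' by the optimal rigid-body fit, and the RMSD is evaluated over `sel`.
#' By default the fit uses the same selection that is measured (e.g. all
#' DNA P atoms); pass a different `fit_sel` to fit on the histone core
#' instead, or `fit = FALSE` to compare coordinates as stored.
#'
#' @param traj a `Trajectory`.
#' @param sel atom selection measured: an index vector or a list of
#'   [atom_indices()] arguments; default all heavy atoms.
#' @param ref reference: a frame index (default 1) or an `n x 3` matrix of
#'   full-topology coordinates.
#' @param fit_sel selection used for the superposition; default `sel`.
#' @param fit logical; `FALSE` skips superposition.
#' @return a `SeriesStat` of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, sel = NULL, ref = 1L, fit_sel = sel,
                        fit = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  idx <- resolve_selection(traj$topology, sel, what = "rmsd selection")
  fidx <- resolve_selection(traj$topology, fit_sel, default = idx,
                            what = "fit selection")
  refxyz <- if (is.matrix(ref)) ref else frame_xyz(traj, ref)
  if (nrow(refxyz) != nrow(traj$topology$atoms))
    stop("reference coordinates do not match the topology")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_xyz(traj, f)
    if (fit) {
      tr <- kabsch_fit(x[fidx, , drop = FALSE], refxyz[fidx, , drop = FALSE])
      x <- apply_fit(x, tr)
    }
    rmsd_pair(x[idx, , drop = FALSE], refxyz[idx, , drop = FALSE])
  }, numeric(1))
  series_stat(vals, meta = list(metric = "rmsd", units = "Angstrom",
                                fitted = fit))
}

# index of the first P atom of a terminal base pair (entry-strand residue
# first, matching the pairing order)
terminal_p_atom <- function(assembly, which = c("entry", "exit")) {
  which <- match.arg(which)
  if (is.null(assembly$pairing)) stop("assembly has no base-pairing table")
  bp <- if (which == "entry") 1L else n_bp(assembly)
  idx <- bp_atoms(assembly, bp, heavy_only = TRUE)
  p <- idx[assembly$atoms$name[idx] == "P"]
  if (length(p) == 0L)
    stop("no P atom in the ", which, " base pair")
  p[1]
}

#' DNA end-to-end distance series
#'
#' Per frame, the Euclidean distance between the first P atom of the entry
#' base pair and the first P atom of the exit base pair.
#'
#' @param traj a `Trajectory` whose topology has a base-pairing table.
#' @return a `SeriesStat` of distances (Angstrom).
#' @export
end_to_end_series <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  i <- terminal_p_atom(traj$topology, "entry")
  j <- terminal_p_atom(traj$topology, "exit")
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_xyz(traj, f)
    sqrt(sum((x[i, ] - x[j, ])^2))
  }, numeric(1))
  series_stat(vals, meta = list(metric = "end_to_end", units = "Angstrom",
                                atoms = c(i, j)))
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` over the selected atoms, with
#' `rbar` the (weighted) centroid.  Unweighted by default (`w_i = 1`).
#'
#' @param x a `NucleoAssembly` or an `n x 3` coordinate matrix.
#' @param sel atom selection (ignored when `x` is a bare matrix).
#' @param weights optional per-atom weights (e.g. masses).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(x, sel = NULL, weights = NULL) {
  xyz <- if (is.matrix(x)) x else {
    idx <- resolve_selection(x, sel, what = "rg selection")
    x$xyz[idx, , drop = FALSE]
  }
  w <- if (is.null(weights)) rep(1, nrow(xyz)) else as.numeric(weights)
  if (length(w) != nrow(xyz)) stop("weights length differs from selection")
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Radius-of-gyration time series
#' @param traj a `Trajectory`.
#' @param sel atom selection; default all heavy atoms.
#' @param weights optional per-atom weights over the selection.
#' @return a `SeriesStat` (Angstrom).
#' @export
rg_series <- function(traj, sel = NULL, weights = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  idx <- resolve_selection(traj$topology, sel, what = "rg selection")
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(frame_xyz(traj, f)[idx, , drop = FALSE],
                       weights = weights), numeric(1))
  series_stat(vals, meta = list(metric = "rg", units = "Angstrom"))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed (on `fit_sel`) onto the trajectory mean structure,
#' computed after one initial superposition pass onto the first frame; the
#' RMSF of each selected atom about its mean position is then averaged over
#' each residue's selected atoms.
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param sel atoms whose fluctuation is measured; default all heavy atoms.
#' @param fit_sel selection used for superposition; default `sel`.
#' @param fit logical; `FALSE` uses coordinates as stored.
#' @return data.frame with columns `chain`, `resid`, `resname`, `rmsf`
#'   (Angstrom), one row per residue in selection order.
#' @export
rmsf_per_residue <- function(traj, sel = NULL, fit_sel = sel, fit = TRUE) {
  stopifnot(inherits(traj, "Trajectory"))
  if (n_frames(traj) < 2L)
    stop("RMSF needs at least 2 frames")
  topo <- traj$topology
  idx <- resolve_selection(topo, sel, what = "rmsf selection")
  fidx <- resolve_selection(topo, fit_sel, default = idx,
                            what = "fit selection")
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) frame_xyz(traj, f))
  if (fit) {
    ref1 <- frames[[1]][fidx, , drop = FALSE]
    frames <- lapply(frames, function(x)
      apply_fit(x, kabsch_fit(x[fidx, , drop = FALSE], ref1)))
    mean1 <- Reduce(`+`, frames) / nf
    refm <- mean1[fidx, , drop = FALSE]
    frames <- lapply(frames, function(x)
      apply_fit(x, kabsch_fit(x[fidx, , drop = FALSE], refm)))
  }
  sel_frames <- lapply(frames, function(x) x[idx, , drop = FALSE])
  mu <- Reduce(`+`, sel_frames) / nf
  msd <- Reduce(`+`, lapply(sel_frames,
                            function(x) rowSums((x - mu)^2))) / nf
  atom_rmsf <- sqrt(msd)
  key <- paste(topo$atoms$chain[idx], topo$atoms$resid[idx], sep = "\r")
  first <- !duplicated(key)
  data.frame(chain = topo$atoms$chain[idx][first],
             resid = topo$atoms$resid[idx][first],
             resname = topo$atoms$resname[idx][first],
             rmsf = as.numeric(tapply(atom_rmsf, factor(key, levels = key[first]),
                                      mean)),
             stringsAsFactors = FALSE)
}

#' Three-point angle
#'
#' Angle at vertex `b` between rays `b -> a` and `b -> c`, in degrees,
#' computed with `atan2` of the cross and dot products for numerical
#' stability near 0 and 180 degrees.
#'
#' @param a,b,c numeric length-3 coordinates (Angstrom).
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_deg <- function(a, b, c) {
  u <- as.numeric(a) - as.numeric(b)
  v <- as.numeric(c) - as.numeric(b)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length ray at the angle vertex")
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

#' Linker-DNA arm angle series of a chromatosome
#'
#' Measures the two linker-arm angles P1-P2-P4 and P3-P4-P2 per frame, where
#' P1/P2 are the terminal/proximal P atoms of the first linker arm and P3/P4
#' those of the second arm (named selections recorded by the chromatosome
#' generator, or supplied explicitly).
#'
#' @param traj a `Trajectory` (or a `NucleoAssembly` for one conformation).
#' @param anchors named integer vector/list with atom indices `P1`..`P4`;
#'   default: the topology's `selections`, or, failing that, the terminal
#'   and proximal P atoms of the two linker-flagged DNA chains.
#' @return data.frame with columns `frame`, `angle_P1_P2_P4`,
#'   `angle_P3_P4_P2` (degrees).
#' @export
linker_angle_series <- function(traj, anchors = NULL) {
  single <- inherits(traj, "NucleoAssembly")
  topo <- if (single) traj else traj$topology
  if (is.null(anchors) &&
      all(c("P1", "P2", "P3", "P4") %in% names(topo$selections)))
    anchors <- topo$selections[c("P1", "P2", "P3", "P4")]
  if (is.null(anchors)) {
    lk <- !is.null(topo$chains$linker) & topo$chains$linker %in% TRUE &
      topo$chains$kind == "dna"
    arms <- sort(topo$chains$chain_id[lk])
    if (length(arms) == 2L) {
      i1 <- atom_indices(topo, chain = arms[1], name = "P")
      i2 <- atom_indices(topo, chain = arms[2], name = "P")
      anchors <- list(P1 = i1[length(i1)], P2 = i1[1],
                      P3 = i2[length(i2)], P4 = i2[1])
    }
  }
  if (is.null(anchors) ||
      any(vapply(anchors, is.null, logical(1))) || length(anchors) < 4L)
    stop("linker anchors P1..P4 are not defined for this topology")
  a <- vapply(anchors, function(i) as.integer(i[1]), integer(1))
  nf <- if (single) 1L else n_frames(traj)
  res <- data.frame(frame = seq_len(nf), angle_P1_P2_P4 = NA_real_,
                    angle_P3_P4_P2 = NA_real_)
  for (f in seq_len(nf)) {
    x <- if (single) traj$xyz else frame_xyz(traj, f)
    res$angle_P1_P2_P4[f] <- angle_deg(x[a[["P1"]], ], x[a[["P2"]], ],
                                       x[a[["P4"]], ])
    res$angle_P3_P4_P2[f] <- angle_deg(x[a[["P3"]], ], x[a[["P4"]], ],
                                       x[a[["P2"]], ])
  }
  res
}
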