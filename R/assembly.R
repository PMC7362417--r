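#' Nucleosome-like assembly container
#'
#' A `NucleoAssembly` holds one conformation of a nucleosome-like complex:
#' an atom table, coordinates, a chain table assigning each chain a molecular
#' role (histone, DNA, or linker histone), and a DNA base-pairing table
#' ordered from the designated entry terminus (base pair 1) to the exit
#' terminus (base pair `n_bp`).  All coordinates are in Angstrom.
#'
#' @param atoms data.frame with one row per atom and columns `chain`,
#'   `resid` (1-based residue index within its chain), `resname`, `name`
#'   (atom name), `elem` (element symbol), `heavy` (logical; element != H).
#' @param xyz numeric matrix `n_atoms x 3` of coordinates (Angstrom).
#' @param chains data.frame with columns `chain_id`, `kind` (one of
#'   `"histone"`, `"dna"`, `"linker_histone"`), `histone_class` (e.g. `"H3"`,
#'   `"H2A"`, `"H2A.B"`, `"H1"`, or `NA`), `copy_index` (1, 2, or `NA`),
#'   and optionally `linker` (logical; linker-DNA strands excluded from
#'   base pairing, default `FALSE`).
#' @param pairing data.frame with columns `bp`, `chain1`, `resid1`,
#'   `chain2`, `resid2`; row `bp = 1` is the entry base pair, the last row
#'   the exit base pair.  May be `NULL` for assemblies without paired DNA.
#' @param labels list of ground-truth labels / provenance metadata (used by
#'   the synthetic generators).
#' @param selections named list of pre-resolved atom index vectors (e.g. the
#'   linker-DNA anchor atoms `P1`..`P4` of a chromatosome).
#' @return An object of class `NucleoAssembly`.
#' @export
new_assembly <- function(atoms, xyz, chains, pairing = NULL,
                         labels = list(), selections = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  chains <- as.data.frame(chains)
  if (is.null(chains$linker)) chains$linker <- FALSE
  x <- structure(
    list(atoms = atoms, xyz = xyz, chains = chains,
         pairing = if (is.null(pairing)) NULL else as.data.frame(pairing),
         labels = labels, selections = selections),
    class = "NucleoAssembly")
  validate_assembly(x)
  x
}

#' Validate a NucleoAssembly
#'
#' Checks the container invariants: finite coordinates, congruent atom table,
#' known chain roles, and a base-pairing table that is a total order in which
#' no residue appears twice.
#'
#' @param x a `NucleoAssembly`.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_assembly <- function(x) {
  stopifnot(inherits(x, "NucleoAssembly"))
  if (nrow(x$atoms) != nrow(x$xyz))
    stop("atom table and coordinate matrix disagree in length")
  if (ncol(x$xyz) != 3L) stop("coordinates must be n x 3")
  if (!all(is.finite(x$xyz))) stop("non-finite coordinates")
  need <- c("chain", "resid", "resname", "name", "elem", "heavy")
  if (!all(need %in% names(x$atoms)))
    stop("atom table missing columns: ",
         paste(setdiff(need, names(x$atoms)), collapse = ", "))
  if (!all(x$chains$kind %in% c("histone", "dna", "linker_histone")))
    stop("unknown chain kind; expected histone/dna/linker_histone")
  if (!all(x$atoms$chain %in% x$chains$chain_id))
    stop("atoms reference chains absent from the chain table")
  if (!is.null(x$pairing)) {
    p <- x$pairing
    if (!identical(p$bp, seq_len(nrow(p))))
      stop("base pairs must be indexed 1..n_bp from the entry terminus")
    keys <- c(paste(p$chain1, p$resid1), paste(p$chain2, p$resid2))
    if (anyDuplicated(keys))
      stop("a residue appears in more than one base pair")
  }
  invisible(x)
}

#' @export
print.NucleoAssembly <- function(x, ...) {
  cat("NucleoAssembly:", nrow(x$atoms), "atoms,",
      nrow(x$chains), "chains,",
      if (is.null(x$pairing)) 0L else nrow(x$pairing), "base pairs\n")
  ck <- table(x$chains$kind)
  cat("  chains:", paste(names(ck), ck, sep = "=", collapse = ", "), "\n")
  if (length(x$labels)) cat("  labels:", paste(names(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of base pairs in an assembly
#' @param x a `NucleoAssembly`.
#' @return integer count of base pairs (0 if no pairing table).
#' @export
n_bp <- function(x) if (is.null(x$pairing)) 0L else nrow(x$pairing)

#' Resolve an atom selection to ordered atom indices
#'
#' Selections are predicates over chain, role, residue, atom name and
#' element.  Resolution is deterministic: indices are returned in atom-table
#' order.  Hydrogens are excluded by default, matching the heavy-atom
#' convention used by all distance-based analyses.
#'
#' @param x a `NucleoAssembly`.
#' @param chain character vector of chain ids, or `NULL` for all.
#' @param kind chain role filter (`"histone"`, `"dna"`, `"linker_histone"`).
#' @param histone_class histone class filter (e.g. `"H3"`, `"H2A.B"`).
#' @param copy_index histone copy filter (1 or 2).
#' @param resid integer vector of residue indices (1-based within chain).
#' @param name atom-name filter (e.g. `"P"`).
#' @param elem element filter.
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return integer vector of atom indices (rows of the atom table).
#' @export
atom_indices <- function(x, chain = NULL, kind = NULL, histone_class = NULL,
                         copy_index = NULL, resid = NULL, name = NULL,
                         elem = NULL, heavy_only = TRUE) {
  stopifnot(inherits(x, "NucleoAssembly"))
  ch <- x$chains
  keep_ch <- rep(TRUE, nrow(ch))
  if (!is.null(chain)) keep_ch <- keep_ch & ch$chain_id %in% chain
  if (!is.null(kind)) keep_ch <- keep_ch & ch$kind %in% kind
  if (!is.null(histone_class))
    keep_ch <- keep_ch & !is.na(ch$histone_class) & ch$histone_class %in% histone_class
  if (!is.null(copy_index))
    keep_ch <- keep_ch & !is.na(ch$copy_index) & ch$copy_index %in% copy_index
  sel_chains <- ch$chain_id[keep_ch]
  a <- x$atoms
  keep <- a$chain %in% sel_chains
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(elem)) keep <- keep & a$elem %in% elem
  if (heavy_only) keep <- keep & a$heavy
  which(keep)
}

# Accept either a ready index vector or a list of atom_indices() arguments.
resolve_selection <- function(x, sel, default = NULL, what = "selection") {
  idx <- if (is.null(sel)) {
    if (is.null(default)) atom_indices(x) else default
  } else if (is.numeric(sel)) {
    as.integer(sel)
  } else if (is.list(sel)) {
    do.call(atom_indices, c(list(x), sel))
  } else stop("cannot interpret ", what)
  if (length(idx) == 0L) stop(what, " resolves to zero atoms")
  if (any(idx < 1L | idx > nrow(x$atoms))) stop(what, " indices out of range")
  idx
}

#' Heavy atoms of one base pair
#'
#' Returns the atom indices belonging to the two residues of base pair
#' `bp_index`, residue 1 (the entry-strand residue) first.
#'
#' @param x a `NucleoAssembly` with a pairing table.
#' @param bp_index base-pair index, 1 = entry.
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return integer vector of atom indices.
#' @export
bp_atoms <- function(x, bp_index, heavy_only = TRUE) {
  if (is.null(x$pairing)) stop("assembly has no base-pairing table")
  if (bp_index < 1L || bp_index > n_bp(x)) stop("bp_index out of range")
  p <- x$pairing[bp_index, ]
  idx <- c(atom_indices(x, chain = p$chain1, resid = p$resid1,
                        heavy_only = heavy_only),
           atom_indices(x, chain = p$chain2, resid = p$resid2,
                        heavy_only = heavy_only))
  if (length(idx) == 0L) stop("base pair ", bp_index, " has no heavy atoms")
  idx
}

#' Trajectory container
#'
#' An ordered sequence of conformations sharing one topology.  Coordinates
#' are stored as an `n_atoms x 3 x n_frames` array.
#'
#' @param topology a `NucleoAssembly` describing every frame.
#' @param coords numeric array `n_atoms x 3 x n_frames`, or a list of
#'   `n_atoms x 3` matrices.
#' @param times optional numeric frame times (arbitrary units).
#' @param labels list of ground-truth labels (synthetic trajectories).
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, coords, times = NULL, labels = list()) {
  stopifnot(inherits(topology, "NucleoAssembly"))
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("frame atom count differs from topology atom count")
  if (!is.null(times) && length(times) != dim(coords)[3])
    stop("times length differs from frame count")
  structure(list(topology = topology, coords = coords, times = times,
                 labels = labels),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3], "frames x",
      dim(x$coords)[1], "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param x a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(x) dim(x$coords)[3]

#' Coordinates of one frame
#' @param x a `Trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_xyz <- function(x, i) {
  stopifnot(i >= 1L, i <= n_frames(x))
  x$coords[, , i, drop = TRUE]
}

#' Assembly snapshot of one trajectory frame
#' @param x a `Trajectory`.
#' @param i frame index.
#' @return a `NucleoAssembly` with that frame's coordinates.
#' @export
frame_assembly <- function(x, i) {
  a <- x$topology
  a$xyz <- frame_xyz(x, i)
  a
}
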