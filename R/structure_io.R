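#' Default chain-role map
#'
#' Convention for mapping PDB chain ids to molecular roles, following the
#' common nucleosome crystal-structure layout: chains A-H are the eight
#' histone chains (H3, H4, H2A, H2B in two copies), chains I and J the two
#' DNA strands, and chain K (if present) a linker histone H1.
#'
#' @param h2a_class histone class recorded for the H2A positions; use
#'   `"H2A.B"` when reading a variant nucleosome.
#' @return named list mapping chain id to `list(kind, histone_class,
#'   copy_index)`, suitable for `read_structure()`.
#' @export
default_chain_map <- function(h2a_class = "H2A") {
  hist <- function(cls, cp) list(kind = "histone", histone_class = cls,
                                 copy_index = cp)
  list(A = hist("H3", 1L), B = hist("H4", 1L),
       C = hist(h2a_class, 1L), D = hist("H2B", 1L),
       E = hist("H3", 2L), F = hist("H4", 2L),
       G = hist(h2a_class, 2L), H = hist("H2B", 2L),
       I = list(kind = "dna", histone_class = NA, copy_index = NA),
       J = list(kind = "dna", histone_class = NA, copy_index = NA),
       K = list(kind = "linker_histone", histone_class = "H1",
                copy_index = NA),
       X = list(kind = "dna", histone_class = NA, copy_index = NA,
                linker = TRUE),
       Y = list(kind = "dna", histone_class = NA, copy_index = NA,
                linker = TRUE))
}

# element from the PDB element column when present, else from the atom name
infer_element <- function(elety, elesy) {
  e <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- e == ""
  if (any(miss)) {
    nm <- toupper(gsub("^[0-9']+", "", trimws(elety[miss])))
    e[miss] <- ifelse(substr(nm, 1, 1) == "H", "H", substr(nm, 1, 1))
  }
  e
}

build_pairing <- function(atoms, chains, pairing_table, entry_strand) {
  lk <- if (is.null(chains$linker)) rep(FALSE, nrow(chains)) else chains$linker
  dna <- chains$chain_id[chains$kind == "dna" & !lk]
  if (length(dna) == 0L) return(NULL)
  if (is.null(entry_strand)) entry_strand <- dna[1]
  if (!is.null(pairing_table)) {
    p <- as.data.frame(pairing_table)
    stopifnot(all(c("chain1", "resid1", "chain2", "resid2") %in% names(p)))
    # canonicalize: the entry strand's residue always listed first
    if (!is.null(entry_strand)) {
      flip <- p$chain2 == entry_strand
      if (any(flip)) {
        tmp <- p[flip, c("chain1", "resid1")]
        p[flip, c("chain1", "resid1")] <- p[flip, c("chain2", "resid2")]
        p[flip, c("chain2", "resid2")] <- tmp
      }
    }
    return(data.frame(bp = seq_len(nrow(p)), chain1 = p$chain1,
                      resid1 = p$resid1, chain2 = p$chain2,
                      resid2 = p$resid2, stringsAsFactors = FALSE))
  }
  if (length(dna) != 2L)
    stop("positional pairing needs exactly 2 DNA strands; ",
         "supply an explicit pairing table")
  s1 <- entry_strand
  s2 <- setdiff(dna, s1)
  n1 <- max(atoms$resid[atoms$chain == s1])
  n2 <- max(atoms$resid[atoms$chain == s2])
  if (n1 != n2)
    stop("DNA strands of unequal length (", n1, " vs ", n2,
         "); supply an explicit pairing table")
  data.frame(bp = seq_len(n1), chain1 = s1, resid1 = seq_len(n1),
             chain2 = s2, resid2 = n1 + 1L - seq_len(n1),
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses a (single-model) PDB file and binds its chains to the assembly
#' topology model.  Hydrogens are kept in the atom records but flagged so
#' that every distance-based analysis uses heavy atoms only.  DNA base
#' pairing is built positionally (residue i of the entry strand with residue
#' n+1-i of the other strand) unless an explicit pairing table is given.
#'
#' @param path PDB file path.
#' @param chain_map named list mapping each chain id to
#'   `list(kind, histone_class, copy_index)`; defaults to
#'   [default_chain_map()].  Every chain in the file must be mapped.
#' @param pairing optional explicit base-pair table with columns `chain1`,
#'   `resid1`, `chain2`, `resid2` ordered entry to exit.
#' @param entry_strand chain id of the strand whose residue 1 is the entry
#'   terminus; default: the first DNA strand in the file.
#' @return a [new_assembly()] object.
#' @export
read_structure <- function(path, chain_map = default_chain_map(),
                           pairing = NULL, entry_strand = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file ", path,
                                           ": ", conditionMessage(e)))
  assembly_from_pdb(pdb, chain_map, pairing, entry_strand)
}

assembly_from_pdb <- function(pdb, chain_map, pairing, entry_strand) {
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stop("cannot parse PDB input: no atom records found")
  chain_ids <- unique(at$chain)
  unknown <- setdiff(chain_ids, names(chain_map))
  if (length(unknown))
    stop("no role configured for chain(s): ",
         paste(unknown, collapse = ", "))
  # residue index: 1-based order of appearance within each chain
  resid <- integer(nrow(at))
  for (cid in chain_ids) {
    rows <- which(at$chain == cid)
    resid[rows] <- match(at$resno[rows], unique(at$resno[rows]))
  }
  elem <- infer_element(at$elety, at$elesy)
  atoms <- data.frame(chain = at$chain, resid = resid, resname = at$resid,
                      name = trimws(at$elety), elem = elem,
                      heavy = elem != "H", orig_resno = at$resno,
                      stringsAsFactors = FALSE)
  chains <- do.call(rbind, lapply(chain_ids, function(cid) {
    m <- chain_map[[cid]]
    data.frame(chain_id = cid, kind = m$kind,
               histone_class = if (is.null(m$histone_class)) NA else m$histone_class,
               copy_index = if (is.null(m$copy_index)) NA else m$copy_index,
               linker = isTRUE(m$linker),
               stringsAsFactors = FALSE)
  }))
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  new_assembly(atoms, xyz, chains,
               build_pairing(atoms, chains, pairing, entry_strand))
}

#' Read a trajectory
#'
#' Multi-model PDB files carry their own topology; the per-frame xyz-series
#' dialect (plain text: atom count, comment line, then `name x y z` rows per
#' frame) needs a `topology` assembly describing the atoms.
#'
#' @param path file path.
#' @param format `"pdb"` (multi-model) or `"xyz"` (per-frame series).
#' @param chain_map,pairing,entry_strand passed to the PDB topology builder.
#' @param topology a `NucleoAssembly`, required for `format = "xyz"`.
#' @return a [new_trajectory()] object; model numbers become frame indices
#'   in file order.
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz"),
                            chain_map = default_chain_map(), pairing = NULL,
                            entry_strand = NULL, topology = NULL) {
  format <- match.arg(format)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- assembly_from_pdb(pdb, chain_map, pairing, entry_strand)
    nf <- nrow(pdb$xyz)
    coords <- array(0, dim = c(nrow(topo$atoms), 3L, nf))
    for (f in seq_len(nf))
      coords[, , f] <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
    return(new_trajectory(topo, coords))
  }
  if (is.null(topology)) stop("xyz-series input requires a topology")
  lines <- readLines(path)
  n <- nrow(topology$atoms)
  block <- n + 2L
  if (length(lines) %% block != 0L)
    stop("xyz-series file length inconsistent with topology atom count")
  nf <- length(lines) %/% block
  coords <- array(0, dim = c(n, 3L, nf))
  for (f in seq_len(nf)) {
    off <- (f - 1L) * block
    if (as.integer(trimws(lines[off + 1L])) != n)
      stop("frame ", f, " atom count differs from topology")
    fields <- strsplit(trimws(lines[off + 2L + seq_len(n)]), "[[:space:]]+")
    coords[, , f] <- t(vapply(fields,
                              function(v) as.numeric(v[2:4]), numeric(3)))
  }
  new_trajectory(topology, coords)
}

#' Write a structure or trajectory to a PDB file
#'
#' Chain ids and residue numbering are preserved (original PDB residue
#' numbers when the assembly was read from a file, 1-based indices
#' otherwise).  A `Trajectory` is written as a multi-model PDB.
#'
#' @param x a `NucleoAssembly` or `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "Trajectory")) {
    topo <- x$topology
    nf <- n_frames(x)
    xyz <- t(vapply(seq_len(nf),
                    function(f) as.numeric(t(frame_xyz(x, f))),
                    numeric(3L * nrow(topo$atoms))))
  } else {
    stopifnot(inherits(x, "NucleoAssembly"))
    topo <- x
    xyz <- matrix(as.numeric(t(x$xyz)), nrow = 1)
  }
  a <- topo$atoms
  resno <- if ("orig_resno" %in% names(a)) a$orig_resno else a$resid
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno,
                   resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$name, chain = a$chain, elesy = a$elem)
  invisible(path)
}

#' Write a trajectory as a per-frame xyz series
#'
#' @param x a `Trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(x, path) {
  stopifnot(inherits(x, "Trajectory"))
  a <- x$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(x))) {
    xyz <- frame_xyz(x, f)
    writeLines(c(as.character(nrow(a)), paste("frame", f),
                 sprintf("%s %.6f %.6f %.6f", a$name,
                         xyz[, 1], xyz[, 2], xyz[, 3])), con)
  }
  invisible(path)
}

#' Write a tabular result as delimited text
#'
#' Writes tab-separated values with a commented metadata block (`# key:
#' value` lines, including column units when given) followed by a header
#' line naming each column.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named list of metadata scalars echoed as comment lines.
#' @param units optional named character vector of column units.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, meta = list(), units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = " ")), con)
  if (!is.null(units))
    writeLines(sprintf("# units: %s",
                       paste(names(units), units, sep = "=", collapse = " ")),
               con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_table()]
#' @param path file path.
#' @return data.frame (metadata comment lines are skipped).
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}
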