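# Small hand-built assemblies with exactly known geometry.

# generic builder: df needs chain, resid, name, elem, x, y, z (+resname opt)
toy_assembly <- function(df, chains, pairing = NULL) {
  atoms <- data.frame(chain = df$chain, resid = as.integer(df$resid),
                      resname = if (is.null(df$resname)) "GLY" else df$resname,
                      name = df$name, elem = df$elem,
                      heavy = df$elem != "H", stringsAsFactors = FALSE)
  new_assembly(atoms, cbind(df$x, df$y, df$z), chains, pairing)
}

chain_row <- function(id, kind, class = NA, copy = NA) {
  data.frame(chain_id = id, kind = kind, histone_class = class,
             copy_index = copy, stringsAsFactors = FALSE)
}

# one histone "core" atom at the origin plus a 6-bp duplex whose base pairs
# sit at exactly the given distances from it (entry side first)
toy_unwrap_assembly <- function(dists) {
  n <- length(dists)
  phi <- seq(0, pi, length.out = n + 2)[seq_len(n)]
  pos <- function(i) c(dists[i] * cos(phi[i]), dists[i] * sin(phi[i]), 0)
  rows <- list(data.frame(chain = "A", resid = 1L, name = "CA", elem = "C",
                          x = 0, y = 0, z = 0))
  for (i in seq_len(n)) {
    p <- pos(i)
    rows[[length(rows) + 1L]] <- data.frame(chain = "I", resid = i,
                                            name = "P", elem = "P",
                                            x = p[1], y = p[2], z = p[3])
    rows[[length(rows) + 1L]] <- data.frame(chain = "J", resid = n + 1L - i,
                                            name = "P", elem = "P",
                                            x = p[1], y = p[2], z = p[3])
  }
  df <- do.call(rbind, rows)
  chains <- rbind(chain_row("A", "histone", "H3", 1L),
                  chain_row("I", "dna"), chain_row("J", "dna"))
  pairing <- data.frame(bp = seq_len(n), chain1 = "I", resid1 = seq_len(n),
                        chain2 = "J", resid2 = n + 1L - seq_len(n),
                        stringsAsFactors = FALSE)
  toy_assembly(df, chains, pairing)
}

# two-copy toy for copy averaging: H3 copy 1 sees 2 H2A atoms in contact,
# H3 copy 2 sees 1; clusters are 1000 A apart
toy_copy_assembly <- function() {
  df <- rbind(
    data.frame(chain = "A", resid = 1L, name = "CA", elem = "C",
               x = 0, y = 0, z = 0),
    data.frame(chain = "C", resid = 1L, name = "CA", elem = "C",
               x = 1, y = 0, z = 0),
    data.frame(chain = "C", resid = 2L, name = "CA", elem = "C",
               x = 2, y = 0, z = 0),
    data.frame(chain = "E", resid = 1L, name = "CA", elem = "C",
               x = 1000, y = 0, z = 0),
    data.frame(chain = "G", resid = 1L, name = "CA", elem = "C",
               x = 1001, y = 0, z = 0),
    data.frame(chain = "G", resid = 2L, name = "CA", elem = "C",
               x = 1020, y = 0, z = 0))
  chains <- rbind(chain_row("A", "histone", "H3", 1L),
                  chain_row("C", "histone", "H2A", 1L),
                  chain_row("E", "histone", "H3", 2L),
                  chain_row("G", "histone", "H2A", 2L))
  toy_assembly(df, chains)
}

# chain A: 10 single-atom residues at x = 100 i; dna chain I: cluster i has
# exactly i atoms within 6 A of residue i (so residue i counts i contacts)
toy_region_assembly <- function() {
  rows <- list()
  for (i in 1:10) {
    rows[[length(rows) + 1L]] <- data.frame(chain = "A", resid = i,
                                            name = "CA", elem = "C",
                                            x = 100 * i, y = 0, z = 0)
    for (k in seq_len(i))
      rows[[length(rows) + 1L]] <- data.frame(chain = "I", resid = i,
                                              name = "P", elem = "P",
                                              x = 100 * i, y = 1 + 0.1 * k,
                                              z = 0)
  }
  df <- do.call(rbind, rows)
  chains <- rbind(chain_row("A", "histone", "H3", 1L),
                  chain_row("I", "dna"))
  toy_assembly(df, chains)
}

# 10 well-separated A-I atom pairs 3 A apart: the native set has exactly one
# atom pair per residue pair
toy_q_assembly <- function() {
  i <- 1:10
  df <- rbind(
    data.frame(chain = "A", resid = i, name = "CA", elem = "C",
               x = 100 * i, y = 0, z = 0),
    data.frame(chain = "I", resid = i, name = "P", elem = "P",
               x = 100 * i, y = 3, z = 0))
  chains <- rbind(chain_row("A", "histone", "H3", 1L),
                  chain_row("I", "dna"))
  toy_assembly(df, chains)
}

# hand-written 3-bp duplex PDB file (chains I and J, one P + one C1 atom per
# residue, plus one hydrogen on the first residue)
write_toy_duplex_pdb <- function(path, j_residues = 3L) {
  fmt <- "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- character(0)
  eleno <- 0
  emit <- function(name, resname, chain, resno, x, y, z, elem) {
    eleno <<- eleno + 1
    lines <<- c(lines, sprintf(fmt, eleno, name, resname, chain, resno,
                               x, y, z, elem))
  }
  for (i in 1:3) {
    emit("P", "DA", "I", i, i * 7, 0, 0, "P")
    emit("C1", "DA", "I", i, i * 7 + 1, 0, 0, "C")
    if (i == 1) emit("H5", "DA", "I", i, i * 7 + 1.5, 0, 0, "H")
  }
  for (j in seq_len(j_residues)) {
    emit("P", "DT", "J", j, (4 - j) * 7, 2, 0, "P")
    emit("C1", "DT", "J", j, (4 - j) * 7 + 1, 2, 0, "C")
  }
  writeLines(c(lines, "END"), path)
  path
}

small_spec <- function(n_bp = 40L, ...) superhelix_spec(n_bp = n_bp, ...)
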