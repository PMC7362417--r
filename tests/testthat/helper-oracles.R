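# Independent brute-force oracles: exhaustive O(n^2) pair computations kept
# deliberately separate from the package's cell-list search.

brute_min_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

brute_count_within <- function(A, B, cutoff) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sum(d2 < cutoff^2)
}

# exhaustive native-contact enumeration at atom granularity
brute_native_atom_pairs <- function(assembly, cutoff) {
  at <- assembly$atoms
  idx <- which(at$heavy)
  out <- list()
  for (ii in seq_along(idx)) for (jj in seq_along(idx)) {
    if (jj <= ii) next
    i <- idx[ii]; j <- idx[jj]
    if (at$chain[i] == at$chain[j] && at$resid[i] == at$resid[j]) next
    if (sqrt(sum((assembly$xyz[i, ] - assembly$xyz[j, ])^2)) < cutoff)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L) return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2])
}

random_cloud <- function(n, box = 40) {
  matrix(runif(n * 3, 0, box), ncol = 3)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

rigid_motion <- function(xyz, R = random_rotation(), t = rnorm(3, sd = 20)) {
  sweep(xyz %*% t(R), 2, t, "+")
}
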