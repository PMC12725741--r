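# Shared builders for small test systems.

make_free_particles <- function(n, box = c(1e4, 1e4, 1e4), seed = 1) {
  set.seed(seed)
  structure(list(
    positions = matrix(stats::runif(3 * n) * 100, n),
    velocities = matrix(stats::rnorm(3 * n), n),
    kind = rep(-1L, n), eps_mp = 0, eps_pp = 0,
    bonds = matrix(integer(0), 0, 2), angles = matrix(integer(0), 0, 3),
    tethered = integer(0), box = box,
    n_monomers = 0L, n_proteins = n, time = 0), class = "bd_system")
}

make_dimer <- function(kb = 100, seed = 1) {
  set.seed(seed)
  structure(list(
    positions = rbind(c(10, 10, 10), c(11, 10, 10)),
    velocities = matrix(stats::rnorm(6), 2),
    kind = c(0L, 1L), eps_mp = c(0, 0), eps_pp = 0,
    bonds = matrix(c(0L, 1L), 1), angles = matrix(integer(0), 0, 3),
    tethered = integer(0), box = c(50, 50, 50),
    n_monomers = 2L, n_proteins = 0L, time = 0), class = "bd_system")
}

# brute-force DBSCAN oracle: connected components of the eps-graph over
# core points, border points attached to the nearest-first cluster
dbscan_oracle <- function(points, eps, min_pts) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nbrs <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl. self
  core <- vapply(nbrs, length, 1L) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    while (length(queue)) {
      j <- queue[[1L]]; queue <- queue[-1L]
      for (m in nbrs[[j]]) {
        if (labels[m] == 0L) {
          labels[m] <- cid
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels
}

# label-permutation-invariant comparison of two clusterings
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (any((a == 0L) != (b == 0L))) return(FALSE)
  in_a <- a[a != 0L]
  in_b <- b[b != 0L]
  length(unique(paste(in_a, in_b))) == length(unique(in_a)) &&
    length(unique(paste(in_a, in_b))) == length(unique(in_b))
}
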