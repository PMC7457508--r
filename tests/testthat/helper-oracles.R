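# Independent oracles, deliberately kept apart from the implementation
# paths they check: Kabsch SVD superposition, exhaustive permutation
# enumeration for graph matching and assignment, and small fixture helpers.

# Minimum RMSD over rigid motions via the Kabsch algorithm (SVD route,
# independent of the quartic/key-matrix route in the package).
kabsch_rmsd <- function(p, q) {
  p <- sweep(p, 2, colMeans(p))
  q <- sweep(q, 2, colMeans(q))
  h <- crossprod(p, q)
  s <- svd(h)
  d <- sign(det(s$u) * det(s$v))
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((p %*% r - q)^2)))
}

# All permutations of a vector (recursive; used only for n <= 8).
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) {
    return(list(v))
  }
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_perms(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# All label-preserving permutations m with m[i] the probe atom mapped to
# reference atom i: cartesian product of within-element permutations.
label_preserving_perms <- function(z_ref, z_probe) {
  stopifnot(identical(sort(z_ref), sort(z_probe)))
  n <- length(z_ref)
  maps <- list(integer(n))
  for (e in unique(z_ref)) {
    ir <- which(z_ref == e)
    ip <- which(z_probe == e)
    expanded <- list()
    for (m in maps) {
      for (pp in all_perms(ip)) {
        m2 <- m
        m2[ir] <- pp
        expanded[[length(expanded) + 1L]] <- m2
      }
    }
    maps <- expanded
  }
  maps
}

# Exhaustive set of label- and edge-preserving bijections.
brute_force_isomorphisms <- function(z_ref, adj_ref, z_probe, adj_probe) {
  Filter(
    function(m) identical(adj_ref != 0, adj_probe[m, m, drop = FALSE] != 0),
    label_preserving_perms(z_ref, z_probe)
  )
}

# Brute-force symmetry-corrected RMSD: minimum of the chosen score over all
# label/edge-preserving permutations.
brute_force_symm_rmsd <- function(ref, probe, minimize = FALSE) {
  maps <- brute_force_isomorphisms(
    ref$atomic_numbers, ref$adjacency,
    probe$atomic_numbers, probe$adjacency
  )
  stopifnot(length(maps) > 0L)
  score <- if (minimize) rmsd_qcp else rmsd_standard
  min(vapply(
    maps,
    function(m) score(ref$coords, probe$coords[m, , drop = FALSE]),
    numeric(1)
  ))
}

# Exhaustive linear-sum-assignment minimum.
brute_force_assignment_cost <- function(d) {
  n <- nrow(d)
  min(vapply(
    all_perms(seq_len(n)),
    function(p) sum(d[cbind(seq_len(n), p)]),
    numeric(1)
  ))
}

adjacency_from_edges_test <- function(n, edges) {
  adj <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- 1
    adj[edges[k, 2], edges[k, 1]] <- 1
  }
  adj
}

random_coords <- function(n, seed, spread = 3) {
  set.seed(seed)
  matrix(stats::runif(3 * n, -spread, spread), n, 3)
}

# A seeded pool of small (<= 8 atom) molecule pairs sharing one molecular
# graph: reference plus a permuted, rigidly moved, jittered probe.
small_fixture_pair <- function(seed) {
  set.seed(seed)
  pick <- sample(c("chain", "disconnected-pair", "oxo-chain"), 1,
    prob = c(0.6, 0.2, 0.2)
  )
  if (pick == "chain") {
    k <- sample(3:7, 1)
    elements <- sample(c(6L, 6L, 8L, 7L), k, replace = TRUE)
    template <- "linear-chain"
  } else {
    k <- 4L
    elements <- c(6L, 6L)
    template <- pick
  }
  perm <- sample(c("automorphism", "same-element", "none"), 1)
  tr <- random_rigid_transform(seed + 1000L)
  ref <- make_molecule(template,
    k = k, elements = elements,
    jitter_sigma = 0.3, seed = seed + 1L
  )
  probe <- make_molecule(template,
    k = k, elements = elements,
    permutation = if (perm == "none") NULL else perm,
    jitter_sigma = 0.25, seed = seed + 2L
  )
  probe$coords <- apply_transform(probe$coords, tr)
  list(ref = ref, probe = probe)
}
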