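# Deterministic synthetic-molecule generator: ideal template geometries plus
# seeded rigid transforms, permutations and Gaussian jitter, so every RMSD
# operation is testable with no external data.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]
    j <- edges[k, 2L]
    adj[i, j] <- 1
    adj[j, i] <- 1
  }
  adj
}

# Ideal template geometries. Bond-length constants (C-C 1.39 A aromatic,
# C-H 1.09 A, generic heavy-atom spacing 1.5 A) are fixture conventions.
fixture_template <- function(template, k = 4L, elements = c(6L, 6L)) {
  switch(template,
    "benzene" = {
      ang <- (0:5) * pi / 3
      cc <- 1.39 # regular hexagon: side length equals circumradius
      ch <- 1.09
      coords <- rbind(
        cbind(cc * cos(ang), cc * sin(ang), 0),
        cbind((cc + ch) * cos(ang), (cc + ch) * sin(ang), 0)
      )
      edges <- rbind(
        cbind(1:6, c(2:6, 1L)), # ring
        cbind(1:6, 7:12) # radial hydrogens
      )
      list(coords = coords, z = c(rep(6L, 6), rep(1L, 6)), edges = edges)
    },
    "ethanol" = {
      # CH3-CH2-OH, staggered-ish geometry
      coords <- rbind(
        c(0.997, 0.066, -0.076), # C1
        c(2.511, 0.073, -0.074), # C2
        c(2.993, 0.953, 0.930), # O3
        c(0.612, -0.617, -0.840), # H on C1
        c(0.605, 1.069, -0.271),
        c(0.611, -0.243, 0.901),
        c(2.910, 0.345, -1.061), # H on C2
        c(2.895, -0.931, 0.122),
        c(2.679, 1.841, 0.737) # H on O
      )
      edges <- rbind(
        c(1L, 2L), c(1L, 4L), c(1L, 5L), c(1L, 6L),
        c(2L, 3L), c(2L, 7L), c(2L, 8L), c(3L, 9L)
      )
      list(
        coords = coords,
        z = c(6L, 6L, 8L, 1L, 1L, 1L, 1L, 1L, 1L), edges = edges
      )
    },
    "linear-chain" = {
      k <- as.integer(k)
      if (k < 1L) abort_contract("linear-chain needs k >= 1 atoms")
      z <- rep_len(as.integer(elements), k)
      coords <- cbind(1.5 * (seq_len(k) - 1), 0, 0)
      edges <- if (k > 1L) cbind(seq_len(k - 1L), 2:k) else
        matrix(integer(0), 0, 2)
      list(coords = coords, z = z, edges = edges)
    },
    "disconnected-pair" = {
      # two identical C-O fragments 10 A apart; a two-fragment graph whose
      # automorphisms include the fragment swap
      coords <- rbind(
        c(0, 0, 0), c(1.4, 0, 0),
        c(10, 0, 0), c(11.4, 0, 0)
      )
      list(
        coords = coords, z = c(6L, 8L, 6L, 8L),
        edges = rbind(c(1L, 2L), c(3L, 4L))
      )
    },
    "oxo-chain" = {
      # O-C(-N)-C-O: the pendant nitrogen makes the two oxygens graph-
      # inequivalent, so a mirrored pose exposes the Hungarian pathology:
      # the element-wise assignment swaps the oxygens (breaking the graph)
      # while the isomorphism method cannot.
      coords <- rbind(
        c(-2.1, 0, 0), # O1
        c(-0.7, 0, 0), # C1 (bears N)
        c(0.7, 0, 0), # C2
        c(2.1, 0, 0), # O2
        c(-0.7, 1.4, 0) # N
      )
      edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(2L, 5L))
      list(coords = coords, z = c(8L, 6L, 6L, 8L, 7L), edges = edges)
    },
    abort_contract(sprintf("unknown template '%s'", template))
  )
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ca <- cos(angle)
  sa <- sin(angle)
  ux <- rbind(
    c(0, -u[3], u[2]),
    c(u[3], 0, -u[1]),
    c(-u[2], u[1], 0)
  )
  ca * diag(3) + sa * ux + (1 - ca) * tcrossprod(u)
}

mirror_matrix <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  diag(3) - 2 * tcrossprod(n)
}

# Resolve a symbolic permutation request against a template graph.
resolve_permutation <- function(permutation, tpl) {
  n <- nrow(tpl$coords)
  if (is.numeric(permutation)) {
    p <- as.integer(permutation)
    if (!identical(sort(p), seq_len(n))) {
      abort_contract("permutation must be a permutation of 1..N")
    }
    return(p)
  }
  swap_first_pair <- function(same_element) {
    p <- seq_len(n)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if ((tpl$z[i] == tpl$z[j]) == same_element) {
          p[c(i, j)] <- c(j, i)
          return(p)
        }
      }
    }
    abort_contract("template has no atom pair of the requested kind")
  }
  switch(permutation,
    "automorphism" = {
      g <- build_graph(tpl$z, adjacency_from_edges(n, tpl$edges))
      auts <- enumerate_isomorphisms(g, g)
      auts <- auts[order(vapply(
        auts, function(m) paste(m, collapse = ","), character(1)
      ))]
      nontrivial <- Filter(function(m) !identical(m, seq_len(n)), auts)
      if (length(nontrivial)) nontrivial[[1L]] else seq_len(n)
    },
    "same-element" = swap_first_pair(TRUE),
    "cross-element" = swap_first_pair(FALSE),
    abort_contract(sprintf("unknown permutation '%s'", permutation))
  )
}

#' Generate a synthetic molecule fixture
#'
#' Builds an ideal-geometry template (benzene as a regular hexagon with
#' radial hydrogens; ethanol; a linear chain; a two-fragment pair; an
#' asymmetric O-C(-N)-C-O chain), then applies, in order: an optional rigid
#' transform (rotation, mirror, translation), an optional atom permutation,
#' and optional i.i.d. Gaussian coordinate jitter drawn under `seed`. The
#' adjacency matrix is permuted consistently with the atoms, so a permuted
#' copy is the same molecule with its file order shuffled. Identical
#' arguments (including `seed`) give bit-identical output.
#'
#' @param template one of `"benzene"`, `"ethanol"`,
#'   `"linear-chain"`, `"disconnected-pair"`, `"oxo-chain"`.
#' @param k,elements chain length and atomic-number pattern, for
#'   `"linear-chain"` only.
#' @param rotation optional `list(axis =, angle =)` (radians).
#' @param mirror optional plane normal; reflection through the plane with
#'   that normal through the origin.
#' @param translation optional length-3 shift in Angstrom.
#' @param permutation optional: an explicit permutation of `1..N`, or one of
#'   `"automorphism"` (a deterministic non-identity graph automorphism),
#'   `"same-element"` (swap the first same-element pair; need not be an
#'   automorphism), `"cross-element"` (swap the first different-element
#'   pair).
#' @param jitter_sigma standard deviation of per-coordinate Gaussian noise,
#'   Angstrom.
#' @param seed integer seed for the jitter stream.
#' @return a [molecule()] with adjacency.
#' @examples
#' benz <- make_molecule("benzene")
#' nrow(benz$coords) # 12
#' sum(benz$adjacency) / 2 # 12 bonds
#' @export
make_molecule <- function(template, k = 4L, elements = c(6L, 6L),
                          rotation = NULL, mirror = NULL, translation = NULL,
                          permutation = NULL, jitter_sigma = 0, seed = 1L) {
  if (jitter_sigma < 0) abort_contract("jitter_sigma must be >= 0")
  tpl <- fixture_template(template, k = k, elements = elements)
  coords <- tpl$coords
  if (!is.null(rotation)) {
    coords <- coords %*% t(rotation_about_axis(rotation$axis, rotation$angle))
  }
  if (!is.null(mirror)) {
    coords <- coords %*% t(mirror_matrix(mirror))
  }
  if (!is.null(translation)) {
    coords <- sweep(coords, 2L, -as.numeric(translation))
  }
  n <- nrow(coords)
  adj <- adjacency_from_edges(n, tpl$edges)
  z <- tpl$z
  if (!is.null(permutation)) {
    p <- resolve_permutation(permutation, tpl)
    # row i of the new molecule is old atom p[i]
    coords <- coords[p, , drop = FALSE]
    z <- z[p]
    adj <- adj[p, p, drop = FALSE]
  }
  if (jitter_sigma > 0) {
    coords <- coords +
      with_seed(seed, matrix(stats::rnorm(3 * n, 0, jitter_sigma), n, 3))
  }
  molecule(coords, z, adj, name = template)
}

#' Seeded random rigid transform
#'
#' Samples a uniformly random proper rotation (via a normalised Gaussian
#' quaternion) and a translation with components uniform in \[-10, 10\]
#' Angstrom. The rotation determinant is +1 to machine precision.
#'
#' @param seed integer seed.
#' @return list with `rotation` (3 x 3) and `translation` (length 3).
#' @examples
#' tr <- random_rigid_transform(7)
#' det(tr$rotation) # 1
#' @export
random_rigid_transform <- function(seed) {
  with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]
    x <- q[2]
    y <- q[3]
    z <- q[4]
    rot <- rbind(
      c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
      c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
      c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
    )
    list(rotation = rot, translation = stats::runif(3, -10, 10))
  })
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param transform list with `rotation` and `translation`, as returned by
#'   [random_rigid_transform()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(
    as_coords(coords) %*% t(transform$rotation), 2L,
    -transform$translation
  )
}

#' Write molecules as a minimal V2000 SDF file
#'
#' Emits one MDL V2000 record per molecule (title line, counts line, atom
#' block, bond block, `M  END`, `$$$$`) so generated fixtures can exercise
#' the file readers and the command-line tool. Bond orders are written as 1;
#' only connectivity is meaningful here.
#'
#' @param molecules a [molecule()] or list of them (adjacency required).
#' @param path output file path.
#' @param names optional record titles; defaults to each molecule's `name`.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path, names = NULL) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (is.null(names)) {
    names <- vapply(seq_along(molecules), function(i) {
      nm <- molecules[[i]]$name
      if (is.null(nm) || !nzchar(nm)) sprintf("mol_%d", i) else nm
    }, character(1))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    stopifnot(inherits(m, "molecule"))
    if (is.null(m$adjacency)) {
      abort_contract("write_sdf requires molecules with adjacency matrices")
    }
    n <- nrow(m$coords)
    edges <- which(upper.tri(m$adjacency) & m$adjacency != 0, arr.ind = TRUE)
    writeLines(c(names[i], "  symrmsd", ""), con)
    writeLines(sprintf(
      "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(edges)
    ), con)
    sym <- z_to_symbol(m$atomic_numbers)
    for (a in seq_len(n)) {
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        m$coords[a, 1], m$coords[a, 2], m$coords[a, 3], sym[a]
      ), con)
    }
    if (nrow(edges)) {
      ord <- order(edges[, 1L], edges[, 2L])
      for (k in ord) {
        writeLines(sprintf(
          "%3d%3d  1  0  0  0  0", edges[k, 1L], edges[k, 2L]
        ), con)
      }
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
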