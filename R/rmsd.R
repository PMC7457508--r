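#' Standard (positional) RMSD
#'
#' `sqrt(mean of squared displacements)` under the file-order atom pairing:
#' atom i of `a` is paired with atom i of `b`. No superposition and no
#' symmetry correction; for symmetric molecules this can be artificially
#' inflated (see [rmsd_symmetry()]).
#'
#' @param a,b N x 3 coordinate matrices (Angstrom) of two conformers, atoms
#'   in the same order.
#' @return the RMSD in Angstrom.
#' @examples
#' a <- rbind(c(0, 0, 0), c(1, 0, 0))
#' rmsd_standard(a, a + rep(c(3, 4, 0), each = 2)) # 5: translation of norm 5
#' @export
rmsd_standard <- function(a, b) {
  a <- as_coords(a)
  b <- as_coords(b)
  if (nrow(a) != nrow(b)) {
    abort_contract(sprintf(
      "coordinate sets differ in atom count (%d vs %d)", nrow(a), nrow(b)
    ))
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Per-element Hungarian RMSD
#'
#' For each element separately, pairs the atoms of the two conformers by
#' solving the linear sum assignment problem on the matrix of squared
#' pairwise distances, then pools the minimised costs:
#' `sqrt((1/N) * sum_e min_X sum_ij D^e_ij X^e_ij)`. Solving per element
#' prevents cross-element pairings, but the assignment is still blind to
#' connectivity: it can break the molecular graph and report an artificially
#' low RMSD. It exists for comparison with other implementations; prefer
#' [rmsd_symmetry()].
#'
#' @param a,b `"molecule"` objects (see [molecule()]) with identical element
#'   multisets; adjacency is not used.
#' @return the Hungarian RMSD in Angstrom.
#' @export
rmsd_hungarian <- function(a, b) {
  stopifnot(inherits(a, "molecule"), inherits(b, "molecule"))
  n <- nrow(a$coords)
  if (n != nrow(b$coords)) {
    abort_contract(sprintf(
      "molecules differ in atom count (%d vs %d)", n, nrow(b$coords)
    ))
  }
  ta <- table(a$atomic_numbers)
  tb <- table(b$atomic_numbers)
  for (e in union(names(ta), names(tb))) {
    ca <- if (e %in% names(ta)) ta[[e]] else 0L
    cb <- if (e %in% names(tb)) tb[[e]] else 0L
    if (ca != cb) {
      abort_contract(sprintf(
        "element multisets differ: %s occurs %d time(s) in one molecule and %d in the other",
        z_to_symbol(as.integer(e)), ca, cb
      ))
    }
  }
  total <- 0
  for (z in unique(a$atomic_numbers)) {
    ia <- which(a$atomic_numbers == z)
    ib <- which(b$atomic_numbers == z)
    d <- squared_distances(
      a$coords[ia, , drop = FALSE],
      b$coords[ib, , drop = FALSE]
    )
    total <- total + hungarian_assign(d)$cost
  }
  sqrt(total / n)
}

# D[i, j] = |a_i - b_j|^2, clamped at 0 against floating-point cancellation
squared_distances <- function(a, b) {
  cross <- tcrossprod(a, b)
  pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * cross, 0)
}

#' Symmetry-corrected RMSD via graph isomorphisms
#'
#' For each probe, enumerates every atom-atom mapping between the reference
#' and probe molecular graphs that preserves atomic numbers and bonds (see
#' [enumerate_isomorphisms()]), evaluates the RMSD under each mapping, and
#' retains the lowest. With `minimize = TRUE` each candidate pairing is
#' scored with the rotation/translation-minimised RMSD ([rmsd_qcp()]) instead
#' of the positional one ([rmsd_standard()]).
#'
#' Because all probes of a docking run share one molecular graph, the
#' isomorphism list is computed once per distinct (reference graph, probe
#' graph) pair and cached; caching never changes a result.
#'
#' @param ref a `"molecule"` with an adjacency matrix.
#' @param probes a `"molecule"` or list of `"molecule"`s, each with an
#'   adjacency matrix and a graph isomorphic to the reference's.
#' @param minimize logical; minimise over rigid motions per mapping.
#' @param cache `TRUE` (default) to cache isomorphisms across probes, `FALSE`
#'   to disable, or an existing [new_iso_cache()] object to share across
#'   calls.
#' @return numeric vector, one RMSD (Angstrom) per probe, in probe order.
#' @examples
#' ref <- make_molecule("benzene")
#' flipped <- make_molecule("benzene", mirror = c(1, 0, 0))
#' rmsd_standard(ref$coords, flipped$coords) # inflated by the arbitrary order
#' rmsd_symmetry(ref, flipped)               # 0: the mirror is a symmetry
#' @export
rmsd_symmetry <- function(ref, probes, minimize = FALSE, cache = TRUE) {
  stopifnot(inherits(ref, "molecule"))
  single <- inherits(probes, "molecule")
  if (single) probes <- list(probes)
  if (is.null(ref$adjacency)) {
    abort_contract("reference molecule has no adjacency matrix")
  }
  cache_obj <- if (inherits(cache, "iso_cache")) {
    cache
  } else if (isTRUE(cache)) {
    new_iso_cache()
  } else {
    NULL
  }
  g_ref <- build_graph(ref$atomic_numbers, ref$adjacency)
  score <- if (minimize) rmsd_qcp else rmsd_standard
  vapply(probes, function(p) {
    stopifnot(inherits(p, "molecule"))
    if (is.null(p$adjacency)) {
      abort_contract("probe molecule has no adjacency matrix")
    }
    g_p <- build_graph(p$atomic_numbers, p$adjacency)
    maps <- cached_isomorphisms(cache_obj, g_ref, g_p)
    min(vapply(
      maps,
      function(m) score(ref$coords, p$coords[m, , drop = FALSE]),
      numeric(1)
    ))
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Array-level API: plain coordinates / atomic numbers / adjacency matrices,
# agnostic of how molecules are stored elsewhere.

#' Standard or minimised RMSD from plain arrays
#'
#' Array-level front end: pass coordinates (and optionally atomic numbers,
#' checked for consistency) without constructing [molecule()] objects.
#' `minimize = TRUE` returns the rigid-motion-minimised RMSD via the QCP
#' method.
#'
#' @param coords1,coords2 N x 3 coordinate matrices, atoms in the same order.
#' @param atomicn1,atomicn2 optional atomic-number vectors; if both given
#'   they must match element-wise.
#' @param minimize logical; superimpose before measuring.
#' @return RMSD in Angstrom.
#' @seealso [symmrmsd()] for symmetry correction, [hrmsd()] for the
#'   per-element assignment variant.
#' @export
rmsd <- function(coords1, coords2, atomicn1 = NULL, atomicn2 = NULL,
                 minimize = FALSE) {
  if (!is.null(atomicn1) && !is.null(atomicn2) &&
    !identical(as.integer(atomicn1), as.integer(atomicn2))) {
    abort_contract("atomic numbers of the two conformers differ")
  }
  if (minimize) rmsd_qcp(coords1, coords2) else rmsd_standard(coords1, coords2)
}

#' Hungarian RMSD from plain arrays
#'
#' @param coords1,coords2 N x 3 coordinate matrices.
#' @param atomicn1,atomicn2 atomic-number vectors (required: the assignment
#'   is solved per element).
#' @return RMSD in Angstrom.
#' @seealso [rmsd_hungarian()] for details and caveats.
#' @export
hrmsd <- function(coords1, coords2, atomicn1, atomicn2) {
  rmsd_hungarian(
    molecule(coords1, atomicn1),
    molecule(coords2, atomicn2)
  )
}

#' Symmetry-corrected RMSD from plain arrays
#'
#' @param coordsref reference N x 3 coordinate matrix.
#' @param coordsprobes probe coordinates: one N x 3 matrix or a list of them
#'   (e.g. docked poses).
#' @param atomicnref,atomicnprobes atomic-number vectors of reference and
#'   probes (probes share one vector: same molecule).
#' @param adjref,adjprobes N x N binary adjacency matrices of reference and
#'   probes.
#' @param minimize logical; minimise over rigid motions per mapping.
#' @param cache logical or [new_iso_cache()] object; see [rmsd_symmetry()].
#' @return numeric vector, one RMSD (Angstrom) per probe.
#' @export
symmrmsd <- function(coordsref, coordsprobes, atomicnref, atomicnprobes,
                     adjref, adjprobes, minimize = FALSE, cache = TRUE) {
  if (is.matrix(coordsprobes)) coordsprobes <- list(coordsprobes)
  ref <- molecule(coordsref, atomicnref, adjref)
  probes <- lapply(coordsprobes, molecule,
    atomic_numbers = atomicnprobes, adjacency = adjprobes
  )
  rmsd_symmetry(ref, probes, minimize = minimize, cache = cache)
}
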