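#' Build a molecular graph
#'
#' Turns atomic numbers plus a binary adjacency matrix into a labelled,
#' unweighted, undirected graph: one vertex per atom (labelled by atomic
#' number), one edge per bond. Bond orders, aromaticity and charges play no
#' role; two atoms either are bonded or they are not.
#'
#' @param atomic_numbers integer vector of length N (atomic numbers, >= 1).
#' @param adjacency N x N binary symmetric matrix with zero diagonal.
#' @return an object of class `"molgraph"`: a list with `num_vertices`,
#'   `vertex_labels` (atomic numbers) and `edges` (two-column matrix of
#'   vertex index pairs, i < j, ordered row-wise).
#' @examples
#' g <- build_graph(c(6, 6), rbind(c(0, 1), c(1, 0)))
#' g$num_vertices # 2
#' g$edges        # one C-C bond
#' @export
build_graph <- function(atomic_numbers, adjacency) {
  atomic_numbers <- as.integer(atomic_numbers)
  n <- length(atomic_numbers)
  if (n < 1L) abort_contract("graph must have at least one vertex")
  if (any(atomic_numbers < 1L)) {
    abort_contract("atomic numbers must be positive integers")
  }
  check_adjacency(as.matrix(adjacency), n)
  idx <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
  edges <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  structure(
    list(num_vertices = n, vertex_labels = atomic_numbers, edges = edges),
    class = "molgraph"
  )
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf(
    "<molgraph: %d vertices, %d edges>\n", x$num_vertices, nrow(x$edges)
  ))
  invisible(x)
}

# igraph view of a molgraph; vertex colours carry the atomic numbers so VF2
# only matches atoms of the same element.
as_igraph <- function(g) {
  igraph::make_graph(t(g$edges), n = g$num_vertices, directed = FALSE)
}

#' Enumerate element-respecting graph isomorphisms
#'
#' Computes every bijection from the vertices of `ref` to the vertices of
#' `probe` that preserves both vertex labels (atomic numbers) and the edge
#' structure, using the VF2 algorithm. For two conformers of one molecule,
#' each such bijection is a chemically valid atom-atom mapping; the
#' symmetry-corrected RMSD is the minimum of the standard RMSD over all of
#' them.
#'
#' Enumeration is exhaustive: graph isomorphism is an NP problem, so this is
#' only suited to small and medium sized molecules. The number of mappings
#' found is reported via a `message()` when `options(symrmsd.verbose = TRUE)`
#' is set. The order of the returned list is unspecified; consumers must
#' reduce with an order-independent minimum.
#'
#' @param ref,probe `"molgraph"` objects (see [build_graph()]).
#' @return a list of integer vectors; each vector `m` is one atom mapping with
#'   `m[i]` the probe vertex matched to reference vertex `i` (1-based).
#' @examples
#' adj <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' g <- build_graph(c(8, 6, 7), adj) # O-C-N path: labels break all symmetry
#' enumerate_isomorphisms(g, g)      # exactly the identity
#' @seealso [rmsd_symmetry()], [graph_digest()]
#' @export
enumerate_isomorphisms <- function(ref, probe) {
  stopifnot(inherits(ref, "molgraph"), inherits(probe, "molgraph"))
  if (ref$num_vertices != probe$num_vertices) {
    abort_not_isomorphic(sprintf(
      "graphs are not isomorphic: different vertex counts (%d vs %d)",
      ref$num_vertices, probe$num_vertices
    ))
  }
  if (!identical(sort(ref$vertex_labels), sort(probe$vertex_labels))) {
    abort_not_isomorphic(
      "graphs are not isomorphic: different element compositions"
    )
  }
  if (nrow(ref$edges) != nrow(probe$edges)) {
    abort_not_isomorphic(sprintf(
      "graphs are not isomorphic: different bond counts (%d vs %d)",
      nrow(ref$edges), nrow(probe$edges)
    ))
  }
  maps <- igraph::graph.get.isomorphisms.vf2(
    as_igraph(ref), as_igraph(probe),
    vertex.color1 = ref$vertex_labels,
    vertex.color2 = probe$vertex_labels
  )
  if (length(maps) == 0L) {
    abort_not_isomorphic(
      "graphs are not isomorphic: no label- and edge-preserving bijection exists"
    )
  }
  if (isTRUE(getOption("symrmsd.verbose"))) {
    message(sprintf("enumerate_isomorphisms: %d mapping(s)", length(maps)))
  }
  # igraph hands back the probe-to-reference direction; invert so that
  # m[i] is the probe vertex paired with reference vertex i
  lapply(maps, function(m) {
    m <- as.integer(m)
    inv <- integer(length(m))
    inv[m] <- seq_along(m)
    inv
  })
}

#' Digest of a molecular graph
#'
#' A deterministic text fingerprint of the concrete graph representation
#' (vertex count, labels, sorted edge list), used as an isomorphism-cache
#' key. Structurally identical graphs yield equal digests; the digest is of
#' the representation, not the isomorphism class, so relabelled copies of the
#' same molecule may hash differently.
#'
#' @param g a `"molgraph"` object.
#' @return a character scalar.
#' @export
graph_digest <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  e <- g$edges[order(g$edges[, 1L], g$edges[, 2L]), , drop = FALSE]
  paste0(
    "n", g$num_vertices,
    ";l", paste(g$vertex_labels, collapse = ","),
    ";e", paste(e[, 1L], e[, 2L], sep = "-", collapse = ",")
  )
}

#' Isomorphism cache
#'
#' Stores the full list of atom mappings per (reference graph, probe graph)
#' pair so repeated pose comparisons against one reference do not re-run the
#' VF2 enumeration. Caching never changes any RMSD value, only avoids
#' recomputation; [rmsd_symmetry()] creates one internally unless caching is
#' disabled.
#'
#' @return an empty cache object of class `"iso_cache"`.
#' @export
new_iso_cache <- function() {
  structure(list(store = new.env(parent = emptyenv())), class = "iso_cache")
}

# Look up or compute-and-store the mapping list for a (ref, probe) pair.
cached_isomorphisms <- function(cache, ref, probe) {
  if (is.null(cache)) {
    return(enumerate_isomorphisms(ref, probe))
  }
  stopifnot(inherits(cache, "iso_cache"))
  key <- paste(graph_digest(ref), graph_digest(probe), sep = "|")
  if (!is.null(hit <- cache$store[[key]])) {
    return(hit)
  }
  maps <- enumerate_isomorphisms(ref, probe)
  assign(key, maps, envir = cache$store)
  maps
}

#' @export
print.iso_cache <- function(x, ...) {
  cat(sprintf("<iso_cache: %d entry(ies)>\n", length(ls(x$store))))
  invisible(x)
}
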