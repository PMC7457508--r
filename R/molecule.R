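#' Molecule container
#'
#' Bundles the three plain structures every RMSD computation consumes: an
#' N x 3 coordinate matrix (Angstrom), a length-N vector of atomic numbers,
#' and optionally an N x N binary adjacency matrix (required only for
#' symmetry-corrected RMSD, where it defines the molecular graph).
#'
#' @param coords numeric N x 3 matrix of atomic coordinates in Angstrom.
#' @param atomic_numbers integer vector of length N, values >= 1.
#' @param adjacency optional N x N binary symmetric matrix with zero diagonal;
#'   entry (i, j) is 1 iff atoms i and j are bonded.
#' @param name optional identifier carried through readers and the CLI.
#' @return an object of class `"molecule"`: a list with elements `coords`,
#'   `atomic_numbers`, `adjacency` (possibly `NULL`) and `name`.
#' @examples
#' # water, no bonds needed for a standard RMSD
#' m <- molecule(
#'   coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
#'   atomic_numbers = c(8, 1, 1)
#' )
#' m
#' @export
molecule <- function(coords, atomic_numbers, adjacency = NULL, name = NULL) {
  coords <- as_coords(coords)
  n <- nrow(coords)
  atomic_numbers <- as.integer(atomic_numbers)
  if (length(atomic_numbers) != n) {
    abort_contract(sprintf(
      "length of atomic_numbers (%d) does not match number of atoms (%d)",
      length(atomic_numbers), n
    ))
  }
  if (any(atomic_numbers < 1L)) {
    abort_contract("atomic numbers must be positive integers")
  }
  if (!is.null(adjacency)) {
    check_adjacency(adjacency, n)
    adjacency <- matrix(as.numeric(adjacency != 0), n, n)
  }
  structure(
    list(
      coords = coords, atomic_numbers = atomic_numbers,
      adjacency = adjacency, name = name
    ),
    class = "molecule"
  )
}

# Coerce and validate an N x 3 coordinate matrix.
as_coords <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) {
    abort_contract("coordinates must be an N x 3 matrix")
  }
  if (nrow(coords) < 1L) {
    abort_contract("coordinate matrix must contain at least one atom")
  }
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) {
    abort_contract("coordinates must be finite")
  }
  dimnames(coords) <- NULL
  coords
}

check_adjacency <- function(adjacency, n) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    abort_contract("adjacency matrix must be square")
  }
  if (nrow(adjacency) != n) {
    abort_contract(sprintf(
      "adjacency matrix dimension (%d) does not match number of atoms (%d)",
      nrow(adjacency), n
    ))
  }
  if (!all(adjacency %in% c(0, 1))) {
    abort_contract("adjacency matrix entries must be 0 or 1")
  }
  if (any(diag(adjacency) != 0)) {
    abort_contract("adjacency matrix must have a zero diagonal (no self-bonds)")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    abort_contract("adjacency matrix must be symmetric")
  }
  invisible(TRUE)
}

#' @export
print.molecule <- function(x, ...) {
  nb <- if (is.null(x$adjacency)) NA_integer_ else sum(x$adjacency) / 2
  cat(sprintf(
    "<molecule%s: %d atoms (%s), %s bonds>\n",
    if (is.null(x$name) || !nzchar(x$name)) "" else paste0(" ", x$name),
    nrow(x$coords),
    paste(names(sort(table(z_to_symbol(x$atomic_numbers)), decreasing = TRUE)),
      collapse = ""
    ),
    if (is.na(nb)) "no adjacency," else format(nb)
  ))
  invisible(x)
}

#' Centre coordinates on their centroid
#'
#' Subtracts the centroid so the output centroid is the zero vector. Pairwise
#' distances are unchanged. Rotation-minimised RMSD requires centred inputs;
#' [rmsd_qcp()] centres internally, so this is only needed when calling
#' [qcp_lambda_max()] directly.
#'
#' @param coords numeric N x 3 matrix.
#' @return the centred N x 3 matrix.
#' @examples
#' center_coords(rbind(c(1, 1, 1)))
#' @export
center_coords <- function(coords) {
  coords <- as_coords(coords)
  sweep(coords, 2L, colMeans(coords))
}
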