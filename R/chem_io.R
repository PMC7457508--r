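# Structure-file adapters: SDF via ChemmineR, MOL2 via bio3d, PDB via
# OpenBabel (ChemmineOB) conversion to SDF so bond perception is delegated
# entirely to the backend toolkit. The RMSD core never touches these; it
# consumes only coordinates, atomic numbers and adjacency matrices.

#' Load molecules from a structure file
#'
#' Reads one or more molecular records from an SDF, MOL2 or PDB file and
#' returns each as a [molecule()] with coordinates (Angstrom, as stored),
#' atomic numbers, and a binary adjacency matrix built from the file's bond
#' block (SDF, MOL2) or from OpenBabel's connectivity perception (PDB).
#' Hydrogens are retained; strip them afterwards with [strip_hydrogens()]
#' for heavy-atom RMSDs. Bond orders, aromaticity flags and charges are
#' discarded: adjacency is binary. Multi-fragment records stay one molecule
#' with a disconnected graph.
#'
#' @param path path to the structure file.
#' @param format `"sdf"`, `"mol2"` or `"pdb"`; inferred from the file
#'   extension when `NULL`.
#' @return an object of class `"loaded_structures"`: list with `molecules`
#'   (list of [molecule()], in file order), `names` (record identifiers) and
#'   `source_format`.
#' @export
load_structures <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort_input(sprintf("file not found: %s", path))
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      "sdf" = "sdf", "mol" = "sdf", "sd" = "sdf",
      "mol2" = "mol2",
      "pdb" = "pdb", "ent" = "pdb",
      abort_input(sprintf(
        "cannot infer format from extension '.%s' of %s", ext, path
      ))
    )
  }
  format <- match.arg(tolower(format), c("sdf", "mol2", "pdb"))
  mols <- switch(format,
    "sdf" = read_sdf_records(path),
    "mol2" = read_mol2_records(path),
    "pdb" = read_pdb_records(path)
  )
  if (length(mols) == 0L) {
    abort_input(sprintf("no molecular records found in %s", path))
  }
  structure(
    list(
      molecules = mols,
      names = vapply(mols, function(m) m$name, character(1)),
      source_format = format
    ),
    class = "loaded_structures"
  )
}

#' @export
print.loaded_structures <- function(x, ...) {
  cat(sprintf(
    "<loaded_structures: %d record(s) from %s>\n",
    length(x$molecules), toupper(x$source_format)
  ))
  invisible(x)
}

read_sdf_records <- function(path) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) {
      abort_input(sprintf("failed to parse SDF file %s: %s", path, conditionMessage(e)))
    }
  )
  lapply(seq_along(ChemmineR::cid(sdfset)), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(ab) || nrow(ab) == 0L) {
      abort_input(sprintf("record %d of %s has zero atoms", i, path))
    }
    coords <- unname(ab[, 1:3, drop = FALSE])
    sym <- sub("_.*$", "", rownames(ab))
    z <- tryCatch(symbol_to_z(sym), error = function(e) {
      abort_input(sprintf(
        "record %d of %s: %s", i, path, conditionMessage(e)
      ))
    })
    n <- nrow(coords)
    adj <- matrix(0, n, n)
    bb <- ChemmineR::bondblock(sdf)
    if (!is.null(bb) && nrow(bb) > 0L) {
      for (k in seq_len(nrow(bb))) {
        a <- bb[k, 1L]
        b <- bb[k, 2L]
        if (a < 1 || b < 1 || a > n || b > n) {
          abort_input(sprintf(
            "record %d of %s: bond references atom out of range", i, path
          ))
        }
        adj[a, b] <- 1
        adj[b, a] <- 1
      }
    }
    title <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (is.null(title) || is.na(title) || !nzchar(trimws(title))) {
      title <- sprintf("record_%d", i)
    }
    molecule(coords, z, adj, name = trimws(title))
  })
}

read_mol2_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0L) {
    abort_input(sprintf("no @<TRIPOS>MOLECULE record in %s", path))
  }
  ends <- c(starts[-1L] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    chunk <- lines[starts[i]:ends[i]]
    tmp <- tempfile(fileext = ".mol2")
    on.exit(unlink(tmp))
    writeLines(chunk, tmp)
    rec <- tryCatch(
      suppressWarnings(bio3d::read.mol2(tmp)),
      error = function(e) {
        abort_input(sprintf(
          "failed to parse MOL2 record %d of %s: %s",
          i, path, conditionMessage(e)
        ))
      }
    )
    atom <- rec$atom
    if (is.null(atom) || nrow(atom) == 0L) {
      abort_input(sprintf("record %d of %s has zero atoms", i, path))
    }
    coords <- as.matrix(atom[, c("x", "y", "z")])
    # element: SYBYL atom type prefix ("C.3" -> "C"), falling back to the
    # atom name stripped of digits
    sym <- sub("\\..*$", "", atom$elety)
    bad <- !sym %in% .element_symbols
    sym[bad] <- gsub("[0-9]", "", atom$elena[bad])
    z <- tryCatch(symbol_to_z(sym), error = function(e) {
      abort_input(sprintf("record %d of %s: %s", i, path, conditionMessage(e)))
    })
    n <- nrow(coords)
    adj <- matrix(0, n, n)
    if (!is.null(rec$bond) && nrow(rec$bond) > 0L) {
      for (k in seq_len(nrow(rec$bond))) {
        a <- rec$bond$origin[k]
        b <- rec$bond$target[k]
        adj[a, b] <- 1
        adj[b, a] <- 1
      }
    }
    nm <- if (!is.null(rec$name) && nzchar(trimws(rec$name)) &&
      rec$name != "*****") {
      trimws(rec$name)
    } else {
      sprintf("record_%d", i)
    }
    molecule(coords, z, adj, name = nm)
  })
}

read_pdb_records <- function(path) {
  # OpenBabel perceives connectivity (using CONECT records where present)
  # and hands us an SDF with an explicit bond block.
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  ok <- tryCatch(
    {
      # empty options: keep the file's 3D coordinates (ChemmineOB's default
      # would regenerate a 2D layout)
      ChemmineOB::convertFormatFile(
        "PDB", "SDF", path, tmp,
        options = data.frame(names = character(0), args = character(0))
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok || !file.exists(tmp) || file.size(tmp) == 0) {
    abort_input(sprintf("failed to parse PDB file %s", path))
  }
  mols <- read_sdf_records(tmp)
  base <- sub("\\.[^.]*$", "", basename(path))
  lapply(seq_along(mols), function(i) {
    m <- mols[[i]]
    if (grepl("^record_", m$name)) {
      m$name <- if (length(mols) == 1L) base else sprintf("%s_%d", base, i)
    }
    m
  })
}

#' Remove hydrogens from a molecule
#'
#' Drops all atoms with atomic number 1 and re-indexes the adjacency matrix
#' over the surviving atoms; bonds between two heavy atoms are preserved
#' exactly. Heavy-atom RMSD is the usual docking convention.
#'
#' @param m a [molecule()].
#' @return the heavy-atom [molecule()]; unchanged if hydrogen-free.
#' @export
strip_hydrogens <- function(m) {
  stopifnot(inherits(m, "molecule"))
  keep <- m$atomic_numbers != 1L
  if (!any(keep)) {
    abort_input("molecule contains only hydrogens")
  }
  if (all(keep)) {
    return(m)
  }
  molecule(
    m$coords[keep, , drop = FALSE],
    m$atomic_numbers[keep],
    if (is.null(m$adjacency)) NULL else m$adjacency[keep, keep, drop = FALSE],
    name = m$name
  )
}
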