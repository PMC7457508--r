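#' Solve a linear sum assignment problem
#'
#' Finds the permutation assignment X minimising the cost
#' \eqn{\sum_{ij} D_{ij} X_{ij}} for a square cost matrix D, under the
#' constraint that each row is assigned to exactly one column and each column
#' to exactly one row. Uses the Jonker-Volgenant shortest-augmenting-path
#' formulation of the Hungarian method (O(n^3)).
#'
#' @param d square numeric cost matrix with non-negative entries; here,
#'   squared distances (Angstrom^2) between same-element atoms of two
#'   conformers.
#' @return a list with `assignment` (integer vector, `assignment[i]` is the
#'   column assigned to row `i`) and `cost` (the minimised total).
#' @examples
#' hungarian_assign(rbind(c(0, 1), c(1, 0)))$cost # 0, identity assignment
#' @export
hungarian_assign <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    abort_contract("cost matrix must be square")
  }
  if (!all(is.finite(d))) {
    abort_contract("cost matrix entries must be finite")
  }
  if (any(d < 0)) {
    abort_contract("cost matrix entries must be non-negative")
  }
  n <- nrow(d)
  # Potentials u (rows), v (columns); p[j] is the row matched to column j.
  # Index 1 is a virtual column 0 used to seed each augmenting search.
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- d[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  list(
    assignment = assignment,
    cost = sum(d[cbind(seq_len(n), assignment)])
  )
}
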