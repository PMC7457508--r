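# Quaternion characteristic polynomial (QCP) superposition.
#
# The minimum RMSD over rigid rotations of centred coordinate sets A and B is
#   RMSD_min = sqrt((G_A + G_B - 2*lambda_max) / N)
# where G_A = Tr(A'A), G_B = Tr(B'B) and lambda_max is the largest eigenvalue
# of a 4x4 symmetric key matrix K built from the inner-product matrix
# S_ij = sum_k B_ki A_kj. lambda_max is found as the largest root of the
# quartic characteristic polynomial
#   P(lambda) = lambda^4 + C2 lambda^2 + C1 lambda + C0
# with C2 = -2 Tr(M'M) (M = B'A = S), C1 = -8 det(M), C0 = det(K),
# by Newton-Raphson started from (G_A + G_B)/2, which is an upper bound on
# lambda_max so the iteration descends monotonically onto the largest root.

qcp_key_matrix <- function(s) {
  rbind(
    c(
      s[1, 1] + s[2, 2] + s[3, 3], s[2, 3] - s[3, 2],
      s[3, 1] - s[1, 3], s[1, 2] - s[2, 1]
    ),
    c(
      s[2, 3] - s[3, 2], s[1, 1] - s[2, 2] - s[3, 3],
      s[1, 2] + s[2, 1], s[3, 1] + s[1, 3]
    ),
    c(
      s[3, 1] - s[1, 3], s[1, 2] + s[2, 1],
      -s[1, 1] + s[2, 2] - s[3, 3], s[2, 3] + s[3, 2]
    ),
    c(
      s[1, 2] - s[2, 1], s[3, 1] + s[1, 3],
      s[2, 3] + s[3, 2], -s[1, 1] - s[2, 2] + s[3, 3]
    )
  )
}

#' QCP key-matrix solve
#'
#' Builds the QCP intermediates for two centred coordinate sets and solves
#' the quartic characteristic polynomial for its largest root by
#' Newton-Raphson (absolute tolerance 1e-9 on lambda, at most 50 iterations),
#' started from the upper bound `(G_A + G_B) / 2`. If the iteration fails to
#' converge, or the iterate drifts above the bound, the largest eigenvalue of
#' the key matrix from a dense symmetric eigensolver is used instead; the
#' eigendecomposition is the defining value of `lambda_max`, Newton-Raphson
#' only a fast route to it.
#'
#' Inputs must already be centred on their centroids (see [center_coords()]);
#' [rmsd_qcp()] does this for you.
#'
#' @param a,b centred N x 3 coordinate matrices of the same molecule.
#' @return an object of class `"qcp_state"`: list with the inner-product
#'   matrix `S`, key matrix `K`, inner products `G_A`, `G_B`, `M` (equal to
#'   `S`), polynomial coefficients `C2`, `C1`, `C0`, and `lambda_max`.
#' @references Theobald, D. L. Acta Crystallogr. A 61, 478-480 (2005).
#' @export
qcp_lambda_max <- function(a, b) {
  a <- as_coords(a)
  b <- as_coords(b)
  if (nrow(a) != nrow(b)) {
    abort_contract(sprintf(
      "coordinate sets differ in atom count (%d vs %d)", nrow(a), nrow(b)
    ))
  }
  s <- crossprod(b, a) # S_ij = sum_k B_ki A_kj
  g_a <- sum(a * a)
  g_b <- sum(b * b)
  k <- qcp_key_matrix(s)
  c2 <- -2 * sum(s * s)
  c1 <- -8 * det(s)
  c0 <- det(k)

  upper <- (g_a + g_b) / 2
  lambda <- newton_quartic(c2, c1, c0, x0 = upper)
  if (is.na(lambda) || lambda > upper + 1e-6 * max(1, abs(upper))) {
    lambda <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  }
  structure(
    list(
      S = s, K = k, G_A = g_a, G_B = g_b, M = s,
      C2 = c2, C1 = c1, C0 = c0, lambda_max = lambda
    ),
    class = "qcp_state"
  )
}

# Largest root of x^4 + c2 x^2 + c1 x + c0 by Newton-Raphson from x0.
# Returns NA on non-convergence or a vanishing derivative.
newton_quartic <- function(c2, c1, c0, x0, tol = 1e-9, max_iter = 50L) {
  x <- x0
  scale <- max(1, abs(x0))
  for (iter in seq_len(max_iter)) {
    x2 <- x * x
    p <- x2 * x2 + c2 * x2 + c1 * x + c0
    dp <- 4 * x2 * x + 2 * c2 * x + c1
    if (!is.finite(p) || !is.finite(dp)) {
      return(NA_real_)
    }
    if (abs(dp) < 1e-12 * scale) {
      # Flat derivative: at the perfect-overlap root the step is 0/0; the
      # current iterate is then already the root to within noise.
      return(if (abs(p) < 1e-6 * scale^4 + 1e-9) x else NA_real_)
    }
    step <- p / dp
    x <- x - step
    if (abs(step) < tol) {
      return(x)
    }
  }
  NA_real_
}

#' @export
print.qcp_state <- function(x, ...) {
  cat(sprintf(
    "<qcp_state: G_A = %.6g, G_B = %.6g, lambda_max = %.6g>\n",
    x$G_A, x$G_B, x$lambda_max
  ))
  invisible(x)
}

#' Minimum RMSD over rigid motions (QCP)
#'
#' Centres both coordinate sets on their centroids (removing translation) and
#' evaluates `sqrt((G_A + G_B - 2*lambda_max) / N)` (removing rotation). When
#' the two sets overlap perfectly, `G_A + G_B - 2*lambda_max` is analytically
#' zero and can come out slightly negative in floating point; the radicand is
#' clamped at zero so the result is 0, never NaN. For a single atom the
#' minimised RMSD is 0 by definition (translation removes everything).
#'
#' @param a,b N x 3 coordinate matrices of the same molecule (any frame;
#'   centring is internal).
#' @return the minimised RMSD in Angstrom; always `<= rmsd_standard(a, b)`.
#' @examples
#' a <- matrix(rnorm(24), 8, 3)
#' rmsd_qcp(a, a + 5) # pure translation: 0
#' @export
rmsd_qcp <- function(a, b) {
  a <- as_coords(a)
  b <- as_coords(b)
  if (nrow(a) != nrow(b)) {
    abort_contract(sprintf(
      "coordinate sets differ in atom count (%d vs %d)", nrow(a), nrow(b)
    ))
  }
  n <- nrow(a)
  if (n == 1L) {
    return(0)
  }
  st <- qcp_lambda_max(center_coords(a), center_coords(b))
  sqrt(max(0, st$G_A + st$G_B - 2 * st$lambda_max) / n)
}
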