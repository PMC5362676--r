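#' Sparse 7-point Laplacian with zero-normal-derivative boundary
#'
#' Assembles the centered-finite-difference Laplacian on the grid as a
#' sparse matrix acting on lexicographically ordered per-component vectors
#' (axis 1 fastest, matching R's column-major `as.vector`).  The
#' zero-normal-derivative (Neumann) boundary condition is imposed by
#' replicated ghost values, so every row sums to zero, the operator is
#' symmetric, and constant vectors are in its null space.
#'
#' @param domain a [grid_domain()].
#' @return A `Matrix::sparseMatrix` of dimension N x N, N = prod(shape),
#'   with attributes `shape` and `bc = "neumann"`.
#' @export
assemble_laplacian <- function(domain) {
  stopifnot(inherits(domain, "grid_domain"))
  n <- domain$shape
  L1 <- laplacian_1d(n[1]); L2 <- laplacian_1d(n[2]); L3 <- laplacian_1d(n[3])
  I1 <- Matrix::Diagonal(n[1]); I2 <- Matrix::Diagonal(n[2])
  I3 <- Matrix::Diagonal(n[3])
  A <- Matrix::kronecker(I3, Matrix::kronecker(I2, L1)) +
    Matrix::kronecker(I3, Matrix::kronecker(L2, I1)) +
    Matrix::kronecker(L3, Matrix::kronecker(I2, I1))
  A <- methods::as(A, "CsparseMatrix")
  attr(A, "shape") <- n
  attr(A, "bc") <- "neumann"
  A
}

# 1D second-difference matrix with replicated-ghost Neumann ends:
# interior rows (1, -2, 1); end rows (-1, 1) / (1, -1).
laplacian_1d <- function(n) {
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(rep(1, n - 1), rep(-2, n),
                                           rep(1, n - 1)))
  A[1, 1] <- -1
  A[n, n] <- -1
  A
}
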