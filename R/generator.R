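#' Sparse generator of the truncated CME
#'
#' Builds the rate matrix of the master equation on the truncated lattice
#' in the column-source convention: entry (y, x) is the rate from state x
#' to state y and each column sums to zero, so the probability vector
#' evolves as dp/dt = A p.  Jumps that would leave the window (protein
#' birth at n = N-1, transcription at m = M-1) are suppressed, i.e. the
#' truncation is reflecting; the boundary-mass diagnostic of
#' [steadyState()] verifies this does not distort the solution.
#'
#' @param params a [GeneNetworkParams-class]
#' @param grid a [TruncationGrid-class]
#' @return a `dgCMatrix` of dimension `2*M*N`, with the grid and parameters
#'   attached as attributes
#' @examples
#' A <- buildGenerator(paramsPreset("slow"), truncationGrid(4, 6))
#' max(abs(Matrix::colSums(A)))  # probability conservation
#' @export
buildGenerator <- function(params, grid) {
  stopifnot(is(params, "GeneNetworkParams"), is(grid, "TruncationGrid"))
  M <- grid@M; N <- grid@N
  st <- expand.grid(m = 0:(M - 1), alpha = 0:1, n = 0:(N - 1))
  h <- occupancy(st$n, params)
  from <- stateIndex(st$alpha, st$m, st$n, grid)

  rate <- list(
    params@dG * (st$alpha == 1),
    (params@kG * h + params@kG0) * (st$alpha == 0),
    (params@kR * h + params@kR0) * (st$alpha == 1) * (st$m < M - 1),
    params@kP * st$m * (st$n < N - 1),
    params@dR * st$m,
    params@dP * st$n)
  to <- list(
    stateIndex(0L, st$m, st$n, grid),
    stateIndex(1L, st$m, st$n, grid),
    stateIndex(st$alpha, pmin(st$m + 1L, M - 1L), st$n, grid),
    stateIndex(st$alpha, st$m, pmin(st$n + 1L, N - 1L), grid),
    stateIndex(st$alpha, pmax(st$m - 1L, 0L), st$n, grid),
    stateIndex(st$alpha, st$m, pmax(st$n - 1L, 0L), grid))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (ch in 1:6) {
    keep <- rate[[ch]] > 0
    ii <- c(ii, to[[ch]][keep])
    jj <- c(jj, from[keep])
    xx <- c(xx, rate[[ch]][keep])
  }
  nst <- 2L * M * N
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nst, nst))
  Matrix::diag(A) <- Matrix::diag(A) - Matrix::colSums(A)
  attr(A, "grid") <- grid
  attr(A, "params") <- params
  A
}
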