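#' @rdname truncationGrid
#' @export
truncationGrid <- function(M, N) {
  new("TruncationGrid", M = as.integer(M), N = as.integer(N))
}

#' Truncation window for the CME lattice
#'
#' `autoGrid` chooses the window from the deterministic structure of the
#' parameter set: the protein cutoff is `protFactor` (default 1.8) times
#' the largest fixed-point protein count over the open-layer dynamics and
#' the adiabatically reduced dynamics, and the mRNA cutoff is `mrnaFactor`
#' (default 2.5) times the corresponding mRNA count, rounded up.  The
#' adequacy of any window is judged a posteriori by the boundary-mass
#' check of [steadyState()].
#'
#' @param M,N exclusive upper bounds for mRNA and protein counts
#' @param params parameter set
#' @param protFactor,mrnaFactor safety factors on the largest fixed point
#' @return a [TruncationGrid-class]
#' @export
autoGrid <- function(params, protFactor = 1.8, mrnaFactor = 2.5) {
  fp1 <- layerFixedPoint(1, params)
  cp <- tryCatch(findCriticalPoints(params), error = function(e) NULL)
  nTop <- max(fp1["n"], if (!is.null(cp)) max(cp$n) else 0)
  mTop <- max(fp1["m"], if (!is.null(cp)) max(cp$m) else 0)
  truncationGrid(M = max(8, ceiling(mrnaFactor * mTop)),
                 N = max(8, ceiling(protFactor * nTop)))
}

setMethod("show", "TruncationGrid", function(object) {
  cat("TruncationGrid: m < ", object@M, ", n < ", object@N,
      " (", 2L * object@M * object@N, " states)\n", sep = "")
  invisible(object)
})

#' Linear state indexing on the truncated lattice
#'
#' The 2*M*N states are ordered protein-level-major: within a level n,
#' the mRNA count varies fastest, then the gene state.  `stateIndex` maps
#' (alpha, m, n) to the 1-based linear index used by [buildGenerator()];
#' `indexState` inverts it.
#'
#' @param alpha,m,n state coordinates (vectorised)
#' @param i linear indices
#' @param grid a [TruncationGrid-class]
#' @return linear indices / a matrix with columns alpha, m, n
#' @export
stateIndex <- function(alpha, m, n, grid) {
  1L + m + grid@M * alpha + 2L * grid@M * n
}

#' @rdname stateIndex
#' @export
indexState <- function(i, grid) {
  i0 <- i - 1L
  n <- i0 %/% (2L * grid@M)
  r <- i0 %% (2L * grid@M)
  cbind(alpha = r %/% grid@M, m = r %% grid@M, n = n)
}
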