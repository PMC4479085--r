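#' Stationary distribution of the truncated CME
#'
#' The production path takes a parameter set and a truncation window and
#' eliminates protein levels of the block-tridiagonal generator one at a
#' time (each level couples only to its neighbours through diagonal
#' birth/death blocks), which scales to millions of lattice states.  A
#' generator matrix from [buildGenerator()] can be passed instead, in
#' which case the null vector is found by a direct sparse solve - meant
#' for small grids and used as the independent cross-check in the test
#' suite.
#'
#' @param object a [GeneNetworkParams-class] (block solver) or a sparse
#'   generator matrix (direct solve)
#' @param grid a [TruncationGrid-class]; defaults to [autoGrid()]
#' @param massTol maximum tolerated probability on the outermost shells;
#'   more mass than this flags the window as inadequate (warning)
#' @param checkResidual if TRUE, assemble the sparse generator and verify
#'   the stationarity residual (costly on large grids)
#' @param method "qbd" (level elimination), "lu" (direct sparse solve of
#'   the assembled generator) or "auto": lu below 20000 states - which
#'   also covers degenerate sub-models whose levels decouple - qbd above
#' @param ... unused
#' @return a [JointDistribution-class]
#' @examples
#' p <- kappaFamily(0.5, paramsPreset("slow"))
#' d <- steadyState(p, truncationGrid(20, 120))
#' sum(geneMarginal(d))
#' @export
setMethod("steadyState", "GeneNetworkParams",
  function(object, grid = autoGrid(object), massTol = 1e-8,
           checkResidual = FALSE, method = c("auto", "qbd", "lu"), ...) {
    method <- match.arg(method)
    M <- grid@M; N <- grid@N
    if (method == "auto")
      method <- if (2 * M * N <= 20000) "lu" else "qbd"
    if (method == "lu")
      return(steadyState(buildGenerator(object, grid), massTol = massTol,
                         ...))
    sol <- .qbd_steady_cpp(rates(object), M, N)
    P <- sol$P
    P0 <- P[1:M, , drop = FALSE]
    P1 <- P[(M + 1):(2 * M), , drop = FALSE]
    dist <- newJointDistribution(P0, P1, grid, object)
    if (checkResidual) {
      A <- buildGenerator(object, grid)
      p <- as.vector(rbind(P0, P1))
      dist@residual <- max(abs(A %*% p)) / max(p)
    }
    checkBoundaryMass(dist, massTol)
    dist
  })

#' @rdname steadyState
#' @export
setMethod("steadyState", "Matrix",
  function(object, massTol = 1e-8, ...) {
    grid <- attr(object, "grid")
    params <- attr(object, "params")
    nst <- nrow(object)
    if (nst > 4e5)
      stop("direct solve is for small grids; use the parameter-set method")
    A <- as(object, "CsparseMatrix")
    # replace one balance equation by the normalisation constraint
    A[nst, ] <- 1
    b <- c(rep(0, nst - 1), 1)
    p <- as.vector(Matrix::solve(A, b))
    p[p < 0] <- 0
    p <- p / sum(p)
    M <- grid@M; N <- grid@N
    Pm <- matrix(p, nrow = 2 * M, ncol = N)
    dist <- newJointDistribution(Pm[1:M, , drop = FALSE],
                                 Pm[(M + 1):(2 * M), , drop = FALSE],
                                 grid, params)
    dist@residual <- max(abs(as.vector(object %*% p))) / max(p)
    checkBoundaryMass(dist, massTol)
    dist
  })

newJointDistribution <- function(P0, P1, grid, params) {
  tot <- sum(P0) + sum(P1)
  P0 <- P0 / tot; P1 <- P1 / tot
  bm <- c(mEdge = sum(P0[grid@M, ]) + sum(P1[grid@M, ]),
          nEdge = sum(P0[, grid@N]) + sum(P1[, grid@N]))
  new("JointDistribution", P0 = P0, P1 = P1, grid = grid, params = params,
      boundaryMass = bm, residual = NA_real_)
}

checkBoundaryMass <- function(dist, massTol) {
  if (any(dist@boundaryMass > massTol))
    warning(sprintf(
      "truncation may be inadequate: boundary mass m-edge %.3g, n-edge %.3g exceeds %.3g",
      dist@boundaryMass[1], dist@boundaryMass[2], massTol))
  invisible(dist)
}

#' Marginals of a joint distribution
#'
#' @param dist a [JointDistribution-class]
#' @return `jointProbability`: the layer-summed M x N table P(m, n);
#'   `geneMarginal`: named probabilities of the closed/open gene state;
#'   `proteinMarginal` / `mrnaMarginal`: marginal mass functions indexed
#'   from count 0.
#' @export
jointProbability <- function(dist) dist@P0 + dist@P1

#' @rdname jointProbability
#' @export
geneMarginal <- function(dist) {
  c(closed = sum(dist@P0), open = sum(dist@P1))
}

#' @rdname jointProbability
#' @export
proteinMarginal <- function(dist) colSums(dist@P0 + dist@P1)

#' @rdname jointProbability
#' @export
mrnaMarginal <- function(dist) rowSums(dist@P0 + dist@P1)

setMethod("show", "JointDistribution", function(object) {
  cat("JointDistribution on", object@grid@M, "x", object@grid@N,
      "lattice (2 gene layers)\n")
  gm <- geneMarginal(object)
  cat(sprintf("  P(closed) = %.4g, P(open) = %.4g\n", gm[1], gm[2]))
  cat(sprintf("  boundary mass: m-edge %.3g, n-edge %.3g\n",
              object@boundaryMass[1], object@boundaryMass[2]))
  if (!is.na(object@residual))
    cat(sprintf("  stationarity residual: %.3g\n", object@residual))
  invisible(object)
})

#' Potential landscape of a stationary distribution
#'
#' U(m, n) = -log max(P(m, n), floor) on the layer-summed table, the
#' standard "energy landscape" reading of a stationary law.  The floor
#' keeps the potential finite on cells the truncated solution leaves
#' empty; its default matches the convention used for the divergence
#' comparisons (1e-16).
#'
#' @param object a [JointDistribution-class] or a bare probability matrix
#' @param floor probability floor (> 0)
#' @param ... unused
#' @return a [Landscape-class]
#' @export
setMethod("landscape", "JointDistribution", function(object, floor = 1e-16,
                                                     ...) {
  stopifnot(floor > 0)
  new("Landscape", U = -log(pmax(jointProbability(object), floor)),
      floor = floor, grid = object@grid)
})

#' @rdname landscape
#' @export
setMethod("landscape", "matrix", function(object, floor = 1e-16, ...) {
  stopifnot(floor > 0)
  new("Landscape", U = -log(pmax(object, floor)), floor = floor,
      grid = truncationGrid(nrow(object), ncol(object)))
})

#' Kullback-Leibler divergence between two probability tables
#'
#' Both tables are floored at `floor`, renormalised, and compared as
#' sum p log(p / q).  The flooring convention makes the divergence well
#' defined on truncated lattices where either solution may carry exact
#' zeros.
#'
#' @param p,q non-negative arrays of identical shape
#' @param floor probability floor applied to both tables
#' @return a non-negative scalar (0 iff the floored tables agree)
#' @export
klDivergence <- function(p, q, floor = 1e-16) {
  if (!identical(dim(p), dim(q)) || length(p) != length(q))
    stop("p and q must have identical shape")
  p <- pmax(as.numeric(p), floor); p <- p / sum(p)
  q <- pmax(as.numeric(q), floor); q <- q / sum(q)
  sum(p * (log(p) - log(q)))
}
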