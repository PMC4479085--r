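#' Mean first-passage times on the truncated lattice
#'
#' Solves the linear first-passage system: for every non-target state x,
#' sum_y q(x -> y) (tau(y) - tau(x)) = -1 with tau = 0 on the target set.
#' The parameter-set method handles the production case where the target
#' is a protein half-plane (all states beyond the basin threshold) and
#' eliminates protein levels block by block; the generator-matrix method
#' accepts arbitrary source/target index sets and is the small-fixture
#' reference path.
#'
#' @param object a [GeneNetworkParams-class] or a generator matrix from
#'   [buildGenerator()]
#' @param direction "off_on" (first entry into the high-protein basin) or
#'   "on_off"
#' @param grid truncation window, defaults to [autoGrid()]
#' @param threshold protein split between the basins; defaults to the
#'   reduced-drift saddle via [basinThreshold()]
#' @param start integer `c(alpha, m, n)` starting microstate; defaults to
#'   the source basin's metastable point
#' @param ... unused
#' @return the mean first-passage time, with the start state, threshold
#'   and restricted level range attached as attributes
#' @examples
#' p <- kappaFamily(1, paramsPreset("slow"))
#' \donttest{meanFirstPassage(p, direction = "off_on")}
#' @export
setMethod("meanFirstPassage", "GeneNetworkParams",
  function(object, direction = c("off_on", "on_off"),
           grid = autoGrid(object), threshold = NULL, start = NULL, ...) {
    direction <- match.arg(direction)
    if (is.null(threshold)) threshold <- basinThreshold(object)
    mp <- metastablePoints(object)
    if (is.null(start))
      start <- if (direction == "off_on") mp$off else mp$on
    M <- grid@M; N <- grid@N
    if (direction == "off_on") { lo <- 0L; hi <- as.integer(threshold) }
    else { lo <- as.integer(threshold) + 1L; hi <- N - 1L }
    if (start[3] < lo || start[3] > hi)
      stop("start state lies inside the target basin")
    sol <- .qbd_mfpt_cpp(rates(object), M, N, lo, hi)
    i <- 1L + start[2] + M * start[1]          # index within a level block
    tau <- sol$tau[i, start[3] - lo + 1L]
    structure(tau, start = start, threshold = threshold,
              levels = c(lo, hi), direction = direction)
  })

#' @rdname meanFirstPassage
#' @param source,target state index sets (1-based, in the ordering of
#'   [stateIndex()]); the generator-matrix method averages tau over
#'   `sourceDist` (uniform on `source` by default)
#' @param sourceDist optional probability weights over `source`
#' @export
setMethod("meanFirstPassage", "Matrix",
  function(object, source, target, sourceDist = NULL, ...) {
    nst <- nrow(object)
    source <- as.integer(source); target <- as.integer(target)
    if (length(intersect(source, target)) > 0) {
      if (all(source %in% target)) return(0)
      stop("source and target sets must be disjoint")
    }
    keep <- setdiff(seq_len(nst), target)
    Q <- Matrix::t(object)[keep, keep, drop = FALSE]
    tau <- tryCatch(
      as.vector(Matrix::solve(Q, rep(-1, length(keep)))),
      error = function(e)
        stop("first-passage system is singular; is the target reachable?"))
    full <- numeric(nst)
    full[keep] <- tau
    if (is.null(sourceDist)) sourceDist <- rep(1 / length(source),
                                               length(source))
    sum(sourceDist * full[source])
  })
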