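#' Stationary basin occupancancies and the bistability call
#'
#' Occupancy of the two protein-count basins under the stationary CME
#' solution.  The system counts as bistable when both basins hold more
#' than `occupancyThreshold` of the stationary mass (default 0.01).
#'
#' @param params parameter set
#' @param grid truncation window (default [autoGrid()])
#' @param threshold protein basin split (default [basinThreshold()])
#' @param occupancyThreshold minimum stationary mass per basin
#' @param dist optional precomputed [JointDistribution-class]
#' @return list with `occupancy` (named off/on), `bistable`, `threshold`,
#'   and the distribution used
#' @export
bistabilityReport <- function(params, grid = autoGrid(params),
                              threshold = NULL,
                              occupancyThreshold = 0.01, dist = NULL) {
  if (is.null(threshold)) threshold <- basinThreshold(params)
  if (is.null(dist)) dist <- steadyState(params, grid)
  pm <- proteinMarginal(dist)
  off <- sum(pm[seq_len(min(threshold + 1L, length(pm)))])
  occ <- c(off = off, on = 1 - off)
  list(occupancy = occ, bistable = all(occ > occupancyThreshold),
       threshold = threshold, occupancyThreshold = occupancyThreshold,
       dist = dist)
}

#' Feedback strength at which a basin's stationary mass crosses a
#' threshold
#'
#' Along a family of parameter sets differing only in K, the stationary
#' mass of the off basin grows with K (weaker feedback) while the on
#' basin's shrinks.  The bistability window is delimited by the two K
#' values where the minority basin's mass crosses `occupancyThreshold`:
#' `side = "lower"` locates the crossing of the off-basin mass,
#' `side = "upper"` that of the on-basin mass.  The crossing is found by
#' Illinois-damped regula falsi on the log-occupancy, which is close to
#' linear in K; the truncation window and the basin split are recomputed
#' for every K.
#'
#' @param params base parameter set (its K is ignored)
#' @param side "lower" or "upper"
#' @param occupancyThreshold the occupancy defining the boundary
#' @param bracket `c(Klo, Khi)` bracketing the crossing
#' @param tolK stop when the bracket is narrower than this
#' @param maxIter evaluation cap (each costs one CME solve)
#' @return the boundary K, with the evaluation history attached as
#'   attribute `trace`
#' @export
findKBoundary <- function(params, side = c("lower", "upper"),
                          occupancyThreshold = 0.01, bracket = NULL,
                          tolK = 5, maxIter = 12L) {
  side <- match.arg(side)
  if (is.null(bracket))
    bracket <- if (side == "lower") c(2500, 3000) else c(3000, 3500)
  basin <- if (side == "lower") "off" else "on"
  trace <- data.frame(K = numeric(0), occupancy = numeric(0))
  f <- function(K) {
    p <- params; p@K <- K; validObject(p)
    rep <- bistabilityReport(p)
    occ <- rep$occupancy[[basin]]
    trace <<- rbind(trace, data.frame(K = K, occupancy = occ))
    log10(max(occ, 1e-300)) - log10(occupancyThreshold)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop(sprintf(
      "bracket [%g, %g] does not straddle the %s boundary (occupancies %.3g, %.3g)",
      lo, hi, side, 10^(flo) * occupancyThreshold,
      10^(fhi) * occupancyThreshold))
  sideFlag <- 0L
  for (it in seq_len(maxIter)) {
    K <- (lo * fhi - hi * flo) / (fhi - flo)
    K <- min(max(K, lo + 0.05 * (hi - lo)), hi - 0.05 * (hi - lo))
    fk <- f(K)
    if (fk * flo < 0) {
      hi <- K; fhi <- fk
      if (sideFlag == -1L) flo <- flo / 2   # Illinois damping
      sideFlag <- -1L
    } else {
      lo <- K; flo <- fk
      if (sideFlag == 1L) fhi <- fhi / 2
      sideFlag <- 1L
    }
    if (hi - lo <= tolK || abs(fk) < 1e-3) break
  }
  K <- (lo * fhi - hi * flo) / (fhi - flo)
  structure(K, trace = trace, side = side)
}

#' Mean switching time sweep over the adiabaticity ratio
#'
#' Traverses a kappa grid with locked ratios dG/kG and dG/kG0 (via
#' [kappaFamily()]) and estimates the mean switching time for each
#' (kappa, K, direction), either by replicated stochastic simulation
#' (`method = "ssa"`, tau-leaping on by default for these long sweeps)
#' or by the deterministic first-passage solve (`method = "mfpt"`).
#'
#' @param kappas vector of adiabaticity ratios
#' @param Ks vector of feedback strengths
#' @param directions subset of `c("off_on", "on_off")`
#' @param params base parameter set
#' @param replicates SSA replicates per point
#' @param seed integer seed (advanced deterministically per point)
#' @param method "ssa" or "mfpt"
#' @param threshold explicit protein basin split; default the
#'   reduced-drift saddle, recomputed per parameter set
#' @param leap use tau-leaping for the SSA path
#' @param maxEvents per-replicate event budget
#' @return data.frame with columns kappa, K, direction, mst, se,
#'   transitionTime, censoredFraction, replicates, method
#' @export
mstSweep <- function(kappas, Ks = 3000, directions = c("off_on", "on_off"),
                     params = paramsPreset("slow"), replicates = 10L,
                     seed = 1L, method = c("ssa", "mfpt"),
                     threshold = NULL, leap = TRUE, maxEvents = 2e9) {
  method <- match.arg(method)
  out <- list()
  point <- 0L
  for (K in Ks) for (kap in kappas) {
    pk <- kappaFamily(kap, params)
    pk@K <- as.numeric(K)
    thr <- if (is.null(threshold)) basinThreshold(pk) else threshold
    for (dir in directions) {
      point <- point + 1L
      if (method == "ssa") {
        r <- estimateMST(pk, dir, replicates = replicates,
                         seed = seed + 7919 * point, threshold = thr,
                         method = if (leap) "tau" else "exact",
                         maxEvents = maxEvents)
        row <- data.frame(kappa = kap, K = K, direction = dir,
                          mst = r@mst, se = r@se,
                          transitionTime = r@transitionTime,
                          censoredFraction = r@censoredFraction,
                          replicates = replicates, method = method)
      } else {
        mf <- meanFirstPassage(pk, dir, threshold = thr)
        row <- data.frame(kappa = kap, K = K, direction = dir,
                          mst = as.numeric(mf), se = NA_real_,
                          transitionTime = NA_real_,
                          censoredFraction = 0,
                          replicates = NA_integer_, method = method)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Deterministic reference transition time
#'
#' The a-priori estimate of the dwell-excluded transition time: the time
#' the destination layer's deterministic relaxation (from the source
#' metastable point, gene switched) takes to carry the protein count
#' across `threshold`.  For the on-to-off direction this is the decay of
#' the linear closed-layer system, solved in closed form; for off-to-on
#' the open-layer dynamics is integrated numerically until the threshold
#' crossing.
#'
#' @param params parameter set
#' @param direction "on_off" or "off_on"
#' @param threshold protein threshold crossed on arrival (default 400,
#'   the cytometry sorting convention)
#' @param horizon give up after this time (error)
#' @return crossing time in model time units
#' @export
referenceTime <- function(params, direction = c("on_off", "off_on"),
                          threshold = 400, horizon = 1e4) {
  direction <- match.arg(direction)
  if (direction == "on_off") {
    fp <- layerFixedPoint(1, params)
    m0 <- fp[["m"]]; n0 <- fp[["n"]]
    if (threshold >= n0) return(0)
    dR <- params@dR; dP <- params@dP; kP <- params@kP
    nOf <- function(t) {
      if (abs(dP - dR) < 1e-12) {
        n0 * exp(-dP * t) + kP * m0 * t * exp(-dP * t)
      } else {
        n0 * exp(-dP * t) + kP * m0 * (exp(-dR * t) - exp(-dP * t)) /
          (dP - dR)
      }
    }
    if (nOf(horizon) > threshold)
      stop("threshold not crossed within the horizon")
    stats::uniroot(function(t) nOf(t) - threshold, c(0, horizon),
                   tol = 1e-10)$root
  } else {
    if (threshold <= 0) return(0)
    fp <- layerFixedPoint(1, params)
    if (fp[["n"]] <= threshold)
      stop("open-layer fixed point below threshold: no crossing")
    rhs <- function(t, y, parms) list(layerDrift(1, y, params))
    root <- function(t, y, parms) y[2] - threshold
    out <- deSolve::lsodar(c(0, 0), c(0, horizon), rhs, NULL,
                           rootfunc = root)
    tr <- attr(out, "troot")
    if (is.null(tr) || length(tr) == 0)
      stop("threshold not crossed within the horizon")
    tr[1]
  }
}
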