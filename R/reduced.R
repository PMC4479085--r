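# Quasi-steady-state reduction for the fast-switching (adiabatic) regime.
# Averaging over the rapid gene flips leaves a two-species jump process in
# (m, n) whose mRNA synthesis channel carries the effective rate
#   (kR0 + kR h) * (kG0 + kG h) / (dG + kG0 + kG h),
# the product of the transcription rate and the stationary open fraction.

effectiveSynthesis <- function(n, params) {
  h <- occupancy(n, params)
  act <- params@kG0 + params@kG * h
  (params@kR0 + params@kR * h) * act / (params@dG + act)
}

#' Mean-field drift of the adiabatically reduced dynamics
#'
#' @param x numeric `c(m, n)`
#' @param params parameter set
#' @return drift vector `c(dm/dt, dn/dt)`
#' @export
reducedDrift <- function(x, params) {
  if (x[2] < 0) stop("protein coordinate must be non-negative")
  c(effectiveSynthesis(x[2], params) - params@dR * x[1],
    params@kP * x[1] - params@dP * x[2])
}

#' Reaction channels of the reduced two-species process
#'
#' Four channels: effective mRNA synthesis, mRNA decay, translation and
#' protein decay.  Summing jump x rate over the channels reproduces
#' [reducedDrift()] identically; the same channel set defines the
#' Freidlin-Wentzell Hamiltonian used by the quasi-potential machinery.
#'
#' @param params parameter set
#' @return list with `jumps` (4 x 2 integer matrix) and `rate`, a function
#'   mapping a state `c(m, n)` to the four channel rates
#' @export
reducedChannels <- function(params) {
  list(
    jumps = matrix(c(1, 0, -1, 0, 0, 1, 0, -1), 4, 2, byrow = TRUE,
                   dimnames = list(c("mRNA birth", "mRNA decay",
                                     "translation", "protein decay"),
                                   c("m", "n"))),
    rate = function(x) c(effectiveSynthesis(x[2], params),
                         params@dR * max(x[1], 0),
                         params@kP * max(x[1], 0),
                         params@dP * max(x[2], 0)),
    rateJac = function(x) {
      dsyn <- reducedJacobian(x, params)[1, 2]   # d synth / dn
      matrix(c(0, dsyn,
               params@dR, 0,
               params@kP, 0,
               0, params@dP), 4, 2, byrow = TRUE)
    })
}

reducedJacobian <- function(x, params) {
  n <- max(x[2], 0)
  h <- occupancy(n, params)
  k <- params@hillK; K <- params@K
  dh <- if (k == 1L) K / (n + K)^2 else
    k * K^k * n^(k - 1) / (n^k + K^k)^2
  act <- params@kG0 + params@kG * h
  A <- params@kR0 + params@kR * h
  # d/dh of A * act / (dG + act)
  dsyn_dh <- (params@kR * act * (params@dG + act) +
              A * params@kG * (params@dG + act) -
              A * act * params@kG) / (params@dG + act)^2
  matrix(c(-params@dR, params@kP, dsyn_dh * dh, -params@dP), 2, 2)
}

#' Fixed points and saddle of the reduced dynamics
#'
#' Locates all roots of the reduced drift by eliminating m along the
#' protein nullcline (m = dP n / kP), scanning the remaining scalar
#' equation for sign changes and polishing with bracketed root-finding.
#' Each root is classified by the eigenvalues of the reduced Jacobian.
#' A bistable set yields two stable nodes/foci and one saddle; monostable
#' parameter sets are legal outputs and are flagged.
#'
#' @param params parameter set
#' @param nMax upper end of the protein scan (default: 1.5 x the open-layer
#'   fixed point)
#' @return data.frame with columns m, n, type ("stable"/"saddle"/"unstable"),
#'   eig1, eig2, and attribute `bistable`
#' @export
findCriticalPoints <- function(params, nMax = NULL) {
  if (is.null(nMax)) nMax <- 1.5 * layerFixedPoint(1, params)["n"] + 10
  g <- function(n) (params@kP / params@dR) * effectiveSynthesis(n, params) -
    params@dP * n
  ns <- seq(0, nMax, length.out = 8192)
  gs <- g(ns)
  idx <- which(diff(sign(gs)) != 0)
  roots <- vapply(idx, function(i)
    stats::uniroot(g, c(ns[i], ns[i + 1]), tol = 1e-12)$root, numeric(1))
  if (gs[1] == 0) roots <- c(0, roots)
  if (length(roots) == 0) stop("no fixed point of the reduced drift found")
  res <- do.call(rbind, lapply(roots, function(n) {
    m <- params@dP * n / params@kP
    ev <- eigen(reducedJacobian(c(m, n), params), only.values = TRUE)$values
    type <- if (all(Re(ev) < 0)) "stable"
            else if (prod(Re(ev)) < 0) "saddle" else "unstable"
    data.frame(m = m, n = n, type = type,
               eig1 = Re(ev[1]), eig2 = Re(ev[2]))
  }))
  res <- res[order(res$n), ]
  rownames(res) <- NULL
  attr(res, "bistable") <- sum(res$type == "stable") == 2L &&
    sum(res$type == "saddle") == 1L
  res
}
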