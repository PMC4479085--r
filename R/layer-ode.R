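# Per-layer deterministic dynamics and linear-noise moments for the slow
# (two-layer) regime.  On each gene layer alpha the copy-number means obey
#   dm/dt = alpha * (kR0 + kR * h(n)) - dR * m
#   dn/dt = kP * m - dP * n
# and the covariance follows the Lyapunov flow sigma' = sigma J' + J sigma
# + 2 D with the diffusion D read off the same birth/death rates.

layerSynthesis <- function(n, alpha, params) {
  if (alpha == 0) rep(0, length(n))
  else params@kR0 + params@kR * occupancy(n, params)
}

#' Deterministic drift on one gene layer
#'
#' @param alpha layer indicator (0 closed, 1 open)
#' @param x numeric `c(m, n)` mean copy numbers
#' @param params parameter set
#' @return the drift vector `c(dm/dt, dn/dt)`
#' @export
layerDrift <- function(alpha, x, params) {
  c(layerSynthesis(x[2], alpha, params) - params@dR * x[1],
    params@kP * x[1] - params@dP * x[2])
}

layerJacobian <- function(alpha, x, params) {
  dsyn <- if (alpha == 0) 0 else {
    k <- params@hillK; K <- params@K; n <- max(x[2], 0)
    if (k == 1L) params@kR * K / (n + K)^2
    else params@kR * k * K^k * n^(k - 1) / (n^k + K^k)^2
  }
  matrix(c(-params@dR, params@kP, dsyn, -params@dP), 2, 2)
}

layerDiffusion <- function(alpha, x, params) {
  # one half the sum of (jump)^2 * rate over the four copy-number channels
  0.5 * diag(c(layerSynthesis(x[2], alpha, params) + params@dR * x[1],
               params@kP * x[1] + params@dP * x[2]))
}

#' Fixed point of the layer dynamics
#'
#' The closed layer decays to the origin.  On the open layer the protein
#' nullcline condition n = (kP / (dP dR)) (kR0 + kR h(n)) is solved by a
#' sign scan plus bracketed root polishing; for a Hill exponent of 1 the
#' root is unique, otherwise the largest root (the expressed state) is
#' returned.
#'
#' @param alpha layer indicator (0 or 1)
#' @param params parameter set
#' @return named numeric `c(m, n)`
#' @examples
#' layerFixedPoint(1, paramsPreset("slow"))
#' @export
layerFixedPoint <- function(alpha, params) {
  stopifnot(alpha %in% c(0, 1))
  if (alpha == 0) return(c(m = 0, n = 0))
  cc <- params@kP / (params@dP * params@dR)
  g <- function(n) cc * (params@kR0 + params@kR * occupancy(n, params)) - n
  hi <- cc * (params@kR0 + params@kR) * 1.05 + 1
  ns <- seq(0, hi, length.out = 4096)
  gs <- g(ns)
  idx <- which(diff(sign(gs)) != 0)
  if (length(idx) == 0) {
    # g(0) > 0 always (basal synthesis); no sign change means the root is
    # beyond the scan, which cannot happen with the 1.05 margin
    stop("no fixed point found on the open layer")
  }
  i <- idx[length(idx)]
  n <- stats::uniroot(g, c(ns[i], ns[i + 1]), tol = 1e-10)$root
  c(m = (params@kR0 + params@kR * occupancy(n, params)) / params@dR, n = n)
}

#' Stationary covariance of one layer by a Lyapunov solve
#'
#' Solves sigma J' + J sigma + 2 D = 0 at the layer fixed point.  On the
#' closed layer all rates vanish at the origin, so the stationary
#' "Gaussian" degenerates to a point mass (sigma = 0).
#'
#' @inheritParams layerFixedPoint
#' @return list with `x` (fixed point) and `sigma` (2 x 2 covariance)
#' @export
layerStationaryMoments <- function(alpha, params) {
  x <- layerFixedPoint(alpha, params)
  J <- layerJacobian(alpha, x, params)
  D <- layerDiffusion(alpha, x, params)
  sigma <- lyapunovSolve(J, 2 * D)
  list(x = x, sigma = sigma)
}

# solve J S + S J' + Q = 0 for symmetric S (2x2, via vectorisation)
lyapunovSolve <- function(J, Q) {
  if (max(abs(Q)) == 0) return(matrix(0, 2, 2))
  A <- kronecker(diag(2), J) + kronecker(J, diag(2))
  S <- matrix(solve(A, -as.vector(Q)), 2, 2)
  (S + t(S)) / 2
}

#' Integrate the mean/covariance flow of one layer
#'
#' Evolves the coupled mean and covariance equations from an initial
#' [MomentState-class] and returns the trajectory at the requested times.
#' The covariance is re-symmetrised after every output step.
#'
#' @param initial a [MomentState-class]
#' @param params parameter set
#' @param times increasing vector of output times (first element the
#'   initial time)
#' @return data.frame with columns time, m, n, s11, s12, s22
#' @export
integrateMoments <- function(initial, params, times) {
  stopifnot(is(initial, "MomentState"))
  alpha <- initial@alpha
  rhs <- function(t, y, parms) {
    x <- y[1:2]
    S <- matrix(c(y[3], y[4], y[4], y[5]), 2, 2)
    J <- layerJacobian(alpha, x, params)
    dS <- S %*% t(J) + J %*% S + 2 * layerDiffusion(alpha, x, params)
    list(c(layerDrift(alpha, x, params), dS[1, 1], dS[1, 2], dS[2, 2]))
  }
  y0 <- c(initial@x, initial@sigma[1, 1], initial@sigma[1, 2],
          initial@sigma[2, 2])
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  data.frame(time = out[, 1], m = out[, 2], n = out[, 3],
             s11 = out[, 4], s12 = out[, 5], s22 = out[, 6])
}

#' @rdname integrateMoments
#' @param alpha layer indicator
#' @param x mean vector
#' @param sigma covariance matrix
#' @export
momentState <- function(alpha, x, sigma = matrix(0, 2, 2)) {
  new("MomentState", alpha = as.integer(alpha), x = as.numeric(x),
      sigma = (sigma + t(sigma)) / 2)
}
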