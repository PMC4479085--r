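# Gaussian-mixture pictures of the slow-regime stationary landscape.
# With rare gene switching the system equilibrates on each gene layer
# between switches, so the stationary law is a two-component mixture
# weighted by the fraction of time spent on each layer.  The mixture
# weight of the closed layer is the dwell-time balance
#   w = (1/kG0) / (1/kG0 + 1/dG) = dG / (dG + kG0),
# the escape rates being kG0 from the closed layer (occupancy ~ 0 there)
# and dG from the open layer.

#' Closed-layer mixture weight
#'
#' @param params parameter set
#' @return the stationary probability of the closed gene state implied by
#'   the two-layer dwell-time balance
#' @export
mixtureWeight <- function(params) params@dG / (params@dG + params@kG0)

warnIfNotSlow <- function(params) {
  if (kappa(params) > 0.01)
    warning(sprintf(
      "kappa = %.3g > 0.01: two-layer mixture approximations assume the slow regime",
      kappa(params)))
}

#' Simple Gaussian-mixture approximation of the stationary law
#'
#' One Gaussian per gene layer, centred at the layer fixed point with the
#' stationary covariance from the Lyapunov equation, weighted by the
#' dwell-time balance.  On the closed layer every rate vanishes at the
#' origin, so its component degenerates to a point mass there.
#'
#' @param params parameter set (warns outside the slow regime)
#' @return a [GaussianMixtureLandscape-class]
#' @export
simpleMixture <- function(params) {
  warnIfNotSlow(params)
  s0 <- layerStationaryMoments(0, params)
  s1 <- layerStationaryMoments(1, params)
  new("GaussianMixtureLandscape", w = mixtureWeight(params),
      components = list(
        closed = list(list(weight = 1, mean = s0$x, sigma = s0$sigma)),
        open = list(list(weight = 1, mean = s1$x, sigma = s1$sigma))),
      method = "simple", params = params)
}

#' Modified (time-averaged) Gaussian-mixture approximation
#'
#' Refines the simple mixture with the relaxation information carried by
#' switching paths: the component of layer alpha is the time-average of
#' the Gaussians obtained by integrating the mean/covariance flow of that
#' layer from the *other* layer's stationary pair over one mean dwell
#' time (T1 = 1/dG on the open layer, T0 = 1/kG0 on the closed layer).
#' The average is a trapezoid quadrature on a log-spaced time grid, which
#' resolves the fast early relaxation; as kappa tends to 0 the dwell
#' times dwarf the relaxation and the mixture collapses back to the
#' simple one.
#'
#' @param params parameter set (warns outside the slow regime)
#' @param nTime number of quadrature nodes per layer
#' @param tMin earliest quadrature node (the t = 0 contribution is kept
#'   as a point at the starting pair with its trapezoid weight)
#' @return a [GaussianMixtureLandscape-class]
#' @export
modifiedMixture <- function(params, nTime = 200L, tMin = 1e-3) {
  warnIfNotSlow(params)
  s0 <- layerStationaryMoments(0, params)
  s1 <- layerStationaryMoments(1, params)
  Topen <- 1 / params@dG
  Tclosed <- 1 / params@kG0

  timeAveraged <- function(alpha, from, Tavg) {
    tg <- unique(c(0, exp(seq(log(tMin), log(Tavg), length.out = nTime))))
    tr <- integrateMoments(momentState(alpha, from$x, from$sigma), params, tg)
    wts <- diff(c(0, (tg[-1] + tg[-length(tg)]) / 2, Tavg)) / Tavg
    lapply(seq_along(tg), function(i) {
      list(weight = wts[i], mean = c(tr$m[i], tr$n[i]),
           sigma = matrix(c(tr$s11[i], tr$s12[i], tr$s12[i], tr$s22[i]),
                          2, 2))
    })
  }

  new("GaussianMixtureLandscape", w = mixtureWeight(params),
      components = list(
        closed = timeAveraged(0, s1, Tclosed),
        open = timeAveraged(1, s0, Topen)),
      method = "modified", params = params)
}

setMethod("show", "GaussianMixtureLandscape", function(object) {
  cat("GaussianMixtureLandscape (", object@method, "): w_closed = ",
      format(object@w), ", ", length(object@components$closed), "+",
      length(object@components$open), " components\n", sep = "")
  invisible(object)
})

# density of one (possibly degenerate) Gaussian piece accumulated onto an
# M x N lattice; pieces with a near-singular covariance deposit their
# weight on the nearest lattice cell
accumulatePiece <- function(dens, piece, M, N, nSd = 8) {
  mu <- piece$mean; S <- piece$sigma
  detS <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (detS < 1e-10 || S[1, 1] < 1e-12 || S[2, 2] < 1e-12) {
    i <- min(max(round(mu[1]), 0), M - 1) + 1
    j <- min(max(round(mu[2]), 0), N - 1) + 1
    dens[i, j] <- dens[i, j] + piece$weight
    return(dens)
  }
  sd1 <- sqrt(S[1, 1]); sd2 <- sqrt(S[2, 2])
  i <- max(0, floor(mu[1] - nSd * sd1)):min(M - 1, ceiling(mu[1] + nSd * sd1))
  j <- max(0, floor(mu[2] - nSd * sd2)):min(N - 1, ceiling(mu[2] + nSd * sd2))
  if (length(i) == 0 || length(j) == 0) return(dens)
  Sinv <- solve(S)
  dx <- i - mu[1]; dy <- j - mu[2]
  Q <- outer(dx^2 * Sinv[1, 1], dy^2 * Sinv[2, 2], "+") +
    2 * Sinv[1, 2] * outer(dx, dy)
  val <- exp(-Q / 2) / (2 * pi * sqrt(detS))
  dens[i + 1, j + 1] <- dens[i + 1, j + 1] + piece$weight * val
  dens
}

#' Evaluate a mixture landscape on the integer lattice
#'
#' Densities are evaluated at the lattice points of the truncation window
#' and renormalised per layer, making the continuous mixture directly
#' comparable with a truncated CME solution.
#'
#' @param object a [GaussianMixtureLandscape-class]
#' @param grid a [TruncationGrid-class]
#' @param ... unused
#' @return a [JointDistribution-class] with `P0 = w * closed density` and
#'   `P1 = (1 - w) * open density`
#' @export
setMethod("mixtureDensity", "GaussianMixtureLandscape",
  function(object, grid, ...) {
    M <- grid@M; N <- grid@N
    lay <- lapply(object@components, function(pieces) {
      dens <- matrix(0, M, N)
      for (pc in pieces) dens <- accumulatePiece(dens, pc, M, N)
      dens / sum(dens)
    })
    newJointDistribution(object@w * lay$closed, (1 - object@w) * lay$open,
                         grid, object@params)
  })

#' Compare the mixture approximations against the CME solution
#'
#' For each requested kappa (gene rates rescaled with locked ratios via
#' [kappaFamily()]), solves the truncated CME, builds both mixtures,
#' evaluates them on the same lattice and reports the Kullback-Leibler
#' divergence KL(CME || approximation) on the closed layer, the open
#' layer (each as conditional distributions) and globally.  Both tables
#' are floored at `floor` before the comparison.
#'
#' @param params base parameter set
#' @param kappas vector of adiabaticity ratios to sweep
#' @param grid truncation window (defaults to [autoGrid()], which is
#'   kappa-independent along a locked-ratio family)
#' @param floor probability floor
#' @param direction "cme_first" gives KL(CME || approx); "approx_first"
#'   the reverse
#' @param nTime quadrature nodes for the modified mixture
#' @return data.frame with columns kappa, layer, method, kl
#' @export
compareLandscapes <- function(params, kappas = 10^seq(-5, -2, by = 1),
                              grid = NULL, floor = 1e-16,
                              direction = c("cme_first", "approx_first"),
                              nTime = 200L) {
  direction <- match.arg(direction)
  if (is.null(grid)) grid <- autoGrid(params)
  out <- list()
  for (k in kappas) {
    pk <- kappaFamily(k, params)
    cme <- steadyState(pk, grid)
    mx <- list(simple = simpleMixture(pk),
               modified = modifiedMixture(pk, nTime = nTime))
    for (mth in names(mx)) {
      ap <- mixtureDensity(mx[[mth]], grid)
      for (lay in c("closed", "open", "global")) {
        pq <- switch(lay,
          closed = list(cme@P0, ap@P0),
          open = list(cme@P1, ap@P1),
          global = list(jointProbability(cme), jointProbability(ap)))
        kl <- if (direction == "cme_first")
          klDivergence(pq[[1]], pq[[2]], floor)
        else klDivergence(pq[[2]], pq[[1]], floor)
        out[[length(out) + 1L]] <- data.frame(
          kappa = k, layer = lay, method = mth, kl = kl)
      }
    }
  }
  do.call(rbind, out)
}
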