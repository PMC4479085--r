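#' Minimum-action path by geometric curve relaxation
#'
#' Minimises the geometric (Maupertuis) form of the Freidlin-Wentzell
#' action over curves joining `start` to `end`: the action of a curve is
#' the sum over segments of sup { p . dphi : H(x, p) <= 0 }, the support
#' function of the zero level set of the Hamiltonian, evaluated at the
#' segment midpoint.  The inner constrained problem is solved per segment
#' (Newton in p nested in a bracketed root-find for the multiplier), the
#' outer problem by L-BFGS-B on the interior images with the analytic
#' envelope gradient, re-parameterising the curve to equal arc length
#' between optimisation cycles.  Downhill (relaxation) paths cost zero
#' action; uphill paths against the drift carry the quasi-potential
#' difference.
#'
#' @param start,end endpoints in state space; `start` should be an
#'   attractor of the drift for the local quasi-potential reading
#' @param params parameter set (its [reducedChannels()] are used) - or
#'   supply `channels` directly for other jump processes
#' @param channels optional channel set (list with `jumps`, `rate`,
#'   optionally `rateJac`)
#' @param nImages number of curve images (>= 8)
#' @param tol relative action-change tolerance between cycles
#' @param maxCycles maximum relaxation cycles
#' @param init optional initial path (nImages x d matrix)
#' @param lower componentwise lower bound for the images (default 0)
#' @param scale per-coordinate scaling applied internally (curve
#'   relaxation and arc-length parameterisation happen in scaled
#'   coordinates, momenta are scaled back); defaults to the coordinate
#'   span of the endpoints, which conditions strongly anisotropic
#'   mRNA/protein problems
#' @return an [ActionPath-class]
#' @examples
#' p <- paramsPreset("fast")
#' cp <- findCriticalPoints(p)
#' @export
gmamPath <- function(start, end, params = NULL, channels = NULL,
                     nImages = 64L, tol = 1e-4, maxCycles = 30L,
                     init = NULL, lower = 0, scale = NULL) {
  if (is.null(channels)) {
    stopifnot(!is.null(params))
    channels <- reducedChannels(params)
  }
  d <- length(start)
  stopifnot(length(end) == d, nImages >= 8)

  if (is.null(scale)) scale <- pmax(abs(end - start), 1e-8)
  chOrig <- channels
  channels <- list(
    jumps = sweep(chOrig$jumps, 2, scale, "/"),
    rate = function(x) chOrig$rate(x * scale),
    rateJac = if (!is.null(chOrig$rateJac))
      function(x) sweep(chOrig$rateJac(x * scale), 2, scale, "*"))
  start <- start / scale; end <- end / scale
  lower <- lower / scale

  phi <- if (!is.null(init)) sweep(as.matrix(init), 2, scale, "/") else
    outer(seq(0, 1, length.out = nImages), end - start) +
      matrix(start, nImages, d, byrow = TRUE)

  nSeg <- nImages - 1L
  warms <- vector("list", nSeg)

  actionAndGrad <- function(phiMat) {
    S <- 0
    segP <- matrix(0, nSeg, d)
    segMu <- numeric(nSeg)
    segHx <- matrix(0, nSeg, d)
    for (i in seq_len(nSeg)) {
      delta <- phiMat[i + 1L, ] - phiMat[i, ]
      mid <- pmax((phiMat[i + 1L, ] + phiMat[i, ]) / 2, 0)
      l <- supportAction(mid, delta, channels, warm = warms[[i]])
      warms[[i]] <<- list(p = attr(l, "p"), mu = attr(l, "mu"))
      S <- S + as.numeric(l)
      segP[i, ] <- attr(l, "p")
      segMu[i] <- attr(l, "mu")
      segHx[i, ] <- hamiltonianGradX(mid, attr(l, "p"), channels)
    }
    segMu[!is.finite(segMu)] <- 0
    G <- matrix(0, nImages, d)
    for (k in 2:(nImages - 1L)) {
      G[k, ] <- segP[k - 1L, ] - segP[k, ] -
        0.5 * (segMu[k - 1L] * segHx[k - 1L, ] + segMu[k] * segHx[k, ])
    }
    list(S = S, G = G, segP = segP, segMu = segMu)
  }

  reparam <- function(phiMat) {
    s <- c(0, cumsum(sqrt(rowSums((phiMat[-1, , drop = FALSE] -
      phiMat[-nImages, , drop = FALSE])^2))))
    if (s[nImages] == 0) return(phiMat)
    sNew <- seq(0, s[nImages], length.out = nImages)
    apply(phiMat, 2, function(col) stats::approx(s, col, sNew)$y)
  }

  hist <- numeric(0)
  Sprev <- Inf
  converged <- FALSE
  idx <- 2:(nImages - 1L)
  lowerVec <- if (length(lower) == d) rep(lower, each = length(idx))
              else lower
  lastPar <- NULL
  lastRes <- NULL
  evalAt <- function(par) {
    if (is.null(lastPar) || !identical(par, lastPar)) {
      phi[idx, ] <- matrix(par, ncol = d)
      lastRes <<- actionAndGrad(phi)
      lastPar <<- par
    }
    lastRes
  }
  for (cycle in seq_len(maxCycles)) {
    fn <- function(par) evalAt(par)$S
    gr <- function(par) as.vector(evalAt(par)$G[idx, ])
    opt <- stats::optim(as.vector(phi[idx, ]), fn, gr, method = "L-BFGS-B",
                        lower = lowerVec,
                        control = list(maxit = 40, factr = 1e4))
    phi[idx, ] <- matrix(opt$par, ncol = d)
    lastPar <- NULL
    phi <- reparam(phi)
    res <- actionAndGrad(phi)
    hist <- c(hist, res$S)
    if (is.finite(Sprev) &&
        abs(Sprev - res$S) < tol * max(abs(res$S), 1e-10)) {
      converged <- TRUE
      break
    }
    Sprev <- res$S
  }

  res <- actionAndGrad(phi)
  segLen <- sqrt(rowSums((phi[-1, , drop = FALSE] -
    phi[-nImages, , drop = FALSE])^2))
  lambda <- numeric(nSeg)
  Hres <- numeric(nSeg)
  crossRes <- numeric(nSeg)
  for (i in seq_len(nSeg)) {
    mid <- pmax((phi[i + 1L, ] + phi[i, ]) / 2, 0)
    Hh <- hamiltonian(mid, res$segP[i, ], channels)
    Hp <- attr(Hh, "Hp")
    lambda[i] <- sqrt(sum(Hp^2)) / max(segLen[i], 1e-300)
    Hres[i] <- abs(as.numeric(Hh))
    delta <- phi[i + 1L, ] - phi[i, ]
    if (d == 2) {
      crossRes[i] <- abs(Hp[1] * delta[2] - Hp[2] * delta[1]) /
        max(sqrt(sum(Hp^2)) * sqrt(sum(delta^2)), 1e-300)
    }
  }
  segAct <- vapply(seq_len(nSeg), function(i)
    sum(res$segP[i, ] * (phi[i + 1L, ] - phi[i, ])), numeric(1))
  nodeP <- rbind(res$segP[1, , drop = FALSE],
                 (res$segP[-nSeg, , drop = FALSE] +
                  res$segP[-1, , drop = FALSE]) / 2,
                 res$segP[nSeg, , drop = FALSE])
  phi <- sweep(phi, 2, scale, "*")      # back to original coordinates
  nodeP <- sweep(nodeP, 2, scale, "/")
  new("ActionPath", phi = phi, p = nodeP,
      lambda = c(lambda[1], (lambda[-nSeg] + lambda[-1]) / 2,
                 lambda[nSeg]),
      action = max(res$S, 0), cumulative = c(0, cumsum(pmax(segAct, 0))),
      converged = converged,
      diagnostics = list(history = hist, Hresidual = max(Hres),
                         tangentResidual = max(crossRes),
                         cycles = length(hist)))
}

setMethod("show", "ActionPath", function(object) {
  cat(sprintf(
    "ActionPath: %d images, action S = %.6g (%sconverged, %d cycles)\n",
    nrow(object@phi), object@action,
    if (object@converged) "" else "NOT ", object@diagnostics$cycles))
  cat(sprintf("  max |H| on path: %.2e, tangency residual: %.2e\n",
              object@diagnostics$Hresidual,
              object@diagnostics$tangentResidual))
  invisible(object)
})
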