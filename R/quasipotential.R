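#' Global quasi-potential landscape by sticking local quasi-potentials
#'
#' Computes the local quasi-potential of each attractor on a fan of
#' minimum-action paths (one gMAM run per fan target, with the cumulative
#' action recorded along each path), interpolates each local surface onto
#' a regular (m, n) grid by inverse-distance weighting in scaled
#' coordinates, and sticks the two surfaces together: the on-surface is
#' shifted so that both assign the saddle the same value (the offset -
#' the difference of the two saddle barriers - encodes the relative
#' stability of the attractors), the global landscape is the pointwise
#' minimum of the two shifted surfaces, and the result is anchored at
#' zero minimum.  The two optimal switching paths (off-to-on and
#' on-to-off) are part of the result.
#'
#' The fan targets are spread over the grid boundary and interior; grid
#' nodes further than `maxDist` (scaled) from every fan point are left NA
#' and counted in the diagnostics rather than extrapolated.
#'
#' @param params a bistable parameter set
#' @param gridSize `c(nM, nN)` evaluation grid resolution
#' @param nFan number of fan paths per attractor
#' @param nImages images per fan path (switching paths use 72)
#' @param mMax,nMax grid extent; defaults to 1.15 x the span of the
#'   critical points
#' @param maxDist masking radius for the interpolation (scaled units)
#' @return a [QuasiPotential-class]
#' @export
globalQuasiPotential <- function(params, gridSize = c(48L, 48L),
                                 nFan = 10L, nImages = 48L,
                                 mMax = NULL, nMax = NULL,
                                 maxDist = 0.15) {
  cp <- findCriticalPoints(params)
  if (!isTRUE(attr(cp, "bistable")))
    stop("parameter set is not bistable in the reduced dynamics")
  st <- cp[cp$type == "stable", ]
  st <- st[order(st$n), ]
  sad <- cp[cp$type == "saddle", ][1, ]
  off <- c(st$m[1], st$n[1]); on <- c(st$m[2], st$n[2])
  if (is.null(mMax)) mMax <- 1.15 * max(cp$m) + 1
  if (is.null(nMax)) nMax <- 1.15 * max(cp$n) + 1
  mGrid <- seq(0, mMax, length.out = gridSize[1])
  nGrid <- seq(0, nMax, length.out = gridSize[2])
  sc <- c(mMax, nMax)

  pathUp <- gmamPath(off, on, params = params, nImages = 72L)
  pathDown <- gmamPath(on, off, params = params, nImages = 72L)

  fanTargets <- function(center) {
    ang <- seq(0, 2 * pi, length.out = nFan + 1L)[-(nFan + 1L)]
    r <- 0.45
    t <- cbind(center[1] / sc[1] + r * cos(ang),
               center[2] / sc[2] + r * sin(ang))
    t[, 1] <- pmin(pmax(t[, 1], 0.02), 1) * sc[1]
    t[, 2] <- pmin(pmax(t[, 2], 0.005), 1) * sc[2]
    t
  }

  localSurface <- function(center, mainPath) {
    pts <- cbind(mainPath@phi, S = mainPath@cumulative)
    for (i in seq_len(nFan)) {
      tgt <- fanTargets(center)[i, ]
      ap <- tryCatch(
        gmamPath(center, tgt, params = params, nImages = nImages,
                 maxCycles = 12L, tol = 1e-3),
        error = function(e) NULL)
      if (!is.null(ap))
        pts <- rbind(pts, cbind(ap@phi, S = ap@cumulative))
    }
    pts
  }

  idw <- function(pts) {
    px <- pts[, 1] / sc[1]; py <- pts[, 2] / sc[2]
    S <- matrix(NA_real_, length(mGrid), length(nGrid))
    for (i in seq_along(mGrid)) {
      dx2 <- (mGrid[i] / sc[1] - px)^2
      for (j in seq_along(nGrid)) {
        d2 <- dx2 + (nGrid[j] / sc[2] - py)^2
        near <- d2 < maxDist^2
        if (!any(near)) next
        w <- 1 / (d2[near] + 1e-6)
        S[i, j] <- sum(w * pts[near, 3]) / sum(w)
      }
    }
    S
  }

  ptsOff <- localSurface(off, pathUp)
  ptsOn <- localSurface(on, pathDown)
  Soff <- idw(ptsOff)
  Son <- idw(ptsOn)

  # value of each local surface at the saddle (nearest fan point)
  atSaddle <- function(pts) {
    d2 <- (pts[, 1] / sc[1] - sad$m / sc[1])^2 +
      (pts[, 2] / sc[2] - sad$n / sc[2])^2
    near <- order(d2)[1:min(8, nrow(pts))]
    w <- 1 / (d2[near] + 1e-6)
    sum(w * pts[near, 3]) / sum(w)
  }
  sOffSad <- atSaddle(ptsOff)
  sOnSad <- atSaddle(ptsOn)
  # Freidlin-Wentzell consistency: the on-surface is offset by the
  # difference of the two saddle barriers, which makes the assembly
  # continuous at the saddle and encodes the relative stability of the
  # attractors; the whole landscape is then anchored at zero minimum
  shift <- sOffSad - sOnSad
  S <- pmin(Soff, Son + shift, na.rm = TRUE)
  S <- S - min(S, na.rm = TRUE)

  new("QuasiPotential", S = S, mGrid = mGrid, nGrid = nGrid,
      paths = list(off_on = pathUp, on_off = pathDown),
      criticalPoints = cp,
      shift = c(onSurface = shift, saddleOff = sOffSad, saddleOn = sOnSad,
                masked = sum(is.na(S))))
}

setMethod("show", "QuasiPotential", function(object) {
  cat("QuasiPotential on", length(object@mGrid), "x", length(object@nGrid),
      "grid\n")
  cat(sprintf("  saddle barriers: off %.4g / on %.4g; on-surface shift %.4g; %d masked nodes\n",
              object@shift[["saddleOff"]], object@shift[["saddleOn"]],
              object@shift[["onSurface"]],
              as.integer(object@shift[["masked"]])))
  cat(sprintf("  switching actions: off->on %.4g, on->off %.4g\n",
              object@paths$off_on@action, object@paths$on_off@action))
  invisible(object)
})
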