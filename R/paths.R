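#' Extract reactive switching segments from a trajectory
#'
#' A reactive segment starts at a gene-switch event (closed-to-open for
#' the off-to-on direction, open-to-closed for on-to-off) that occurs
#' while the system is inside the source basin, and ends when the protein
#' count first comes within `arrivalFrac` of the destination metastable
#' protein level.  Excursions that switch back before arriving are not
#' reactive and are dropped.  Residence time is accumulated on the (m, n)
#' lattice for every visited state along the reactive segments.
#'
#' @param traj a [Trajectory-class] (jump or sampled records)
#' @param direction "off_on" or "on_off"
#' @param threshold protein-count basin split; defaults to
#'   [basinThreshold()] of the trajectory's parameters
#' @param arrivalFrac arrival window as a fraction of the distance between
#'   the two metastable protein levels (default 0.1)
#' @return a [PathEnsemble-class]; empty (zero segments) when the
#'   trajectory contains no completed switch
#' @export
reactiveSegments <- function(traj, direction = c("off_on", "on_off"),
                             threshold = NULL, arrivalFrac = 0.1) {
  stopifnot(is(traj, "Trajectory"))
  direction <- match.arg(direction)
  params <- traj@params
  if (is.null(threshold))
    threshold <- tryCatch(basinThreshold(params), error = function(e) NULL)
  mp <- metastablePoints(params)
  nOff <- mp$off[["n"]]; nOn <- mp$on[["n"]]
  if (is.null(threshold)) threshold <- floor((nOff + nOn) / 2)
  dat <- traj@data
  up <- direction == "off_on"
  destN <- if (up) nOn else nOff
  win <- max(arrivalFrac * abs(nOn - nOff), 2)

  # gene-switch records: alpha changes between consecutive rows
  swRows <- which(diff(dat$alpha) != 0) + 1L
  swRows <- swRows[dat$alpha[swRows] == as.integer(up)]
  # switch must fire inside the source basin
  inSource <- if (up) dat$n[swRows] <= threshold else dat$n[swRows] > threshold
  swRows <- swRows[inSource]

  segs <- list()
  lastEnd <- 0L
  for (r in swRows) {
    if (r <= lastEnd) next                 # still inside the last segment
    after <- dat[r:nrow(dat), ]
    arrive <- which(abs(after$n - destN) <= win)
    back <- which(after$alpha != as.integer(up))
    endRel <- if (length(arrive) == 0) NA_integer_ else arrive[1]
    if (is.na(endRel) || (length(back) > 0 && back[1] < endRel)) next
    segs[[length(segs) + 1L]] <- after[seq_len(endRel), , drop = FALSE]
    lastEnd <- r + endRel - 1L
  }

  Mx <- max(dat$m) + 1L; Nx <- max(dat$n) + 1L
  dens <- matrix(0, Mx, Nx)
  tot <- 0
  for (s in segs) {
    dt <- diff(s$time)
    if (length(dt) == 0) next
    for (i in seq_along(dt)) {
      dens[s$m[i] + 1L, s$n[i] + 1L] <- dens[s$m[i] + 1L, s$n[i] + 1L] + dt[i]
    }
    tot <- tot + sum(dt)
  }
  new("PathEnsemble", segments = segs, density = dens, totalTime = tot,
      direction = direction)
}

setMethod("show", "PathEnsemble", function(object) {
  cat("PathEnsemble [", object@direction, "]: ", length(object@segments),
      " reactive segments, total reactive time ",
      format(object@totalTime), "\n", sep = "")
  invisible(object)
})

#' Average switching path of a reactive ensemble
#'
#' Each segment is reparameterised to [0, 1] by normalised arc length in
#' the (m, n) plane and the ensemble is averaged bin-wise on a common
#' progress grid - a robust stand-in for a principal-curve fit of the
#' shaded transition density.
#'
#' @param ensemble a [PathEnsemble-class]
#' @param bins number of progress bins (default 50)
#' @param minSegments attach a warning below this ensemble size
#' @return data.frame with columns `s` (progress), `m`, `n`
#' @export
averagePath <- function(ensemble, bins = 50L, minSegments = 5L) {
  stopifnot(is(ensemble, "PathEnsemble"))
  segs <- ensemble@segments
  if (length(segs) == 0) stop("empty ensemble")
  if (length(segs) < minSegments)
    warning(sprintf("only %d segments; averaged path may be noisy",
                    length(segs)))
  sGrid <- seq(0, 1, length.out = bins)
  acc <- matrix(0, bins, 2)
  for (seg in segs) {
    d <- sqrt(diff(seg$m)^2 + diff(seg$n)^2)
    s <- c(0, cumsum(d))
    if (s[length(s)] == 0) { acc <- acc + cbind(seg$m[1], seg$n[1]); next }
    s <- s / s[length(s)]
    keep <- !duplicated(s)
    acc <- acc + cbind(stats::approx(s[keep], seg$m[keep], sGrid)$y,
                       stats::approx(s[keep], seg$n[keep], sGrid)$y)
  }
  data.frame(s = sGrid, m = acc[, 1] / length(segs),
             n = acc[, 2] / length(segs))
}

#' Distance between a polyline and a reference curve
#'
#' Mean distance from the points of `path` to the nearest point of the
#' (densely sampled) reference polyline, normalised by the reference arc
#' length.  Coordinates can be scaled per axis first, which keeps the
#' mRNA and protein axes comparable.
#'
#' @param path data.frame or matrix with columns m, n
#' @param ref reference polyline, same layout
#' @param scale optional `c(mScale, nScale)` divisors
#' @return list with `mean`, `max` (scaled distances) and `refLength`
#' @export
pathDistance <- function(path, ref, scale = NULL) {
  P <- as.matrix(path[, c("m", "n")])
  R <- as.matrix(ref[, c("m", "n")])
  if (!is.null(scale)) {
    P <- sweep(P, 2, scale, "/")
    R <- sweep(R, 2, scale, "/")
  }
  refLen <- sum(sqrt(rowSums(diff(R)^2)))
  d <- vapply(seq_len(nrow(P)), function(i) {
    min(sqrt(rowSums((R - matrix(P[i, ], nrow(R), 2, byrow = TRUE))^2)))
  }, numeric(1))
  list(mean = mean(d), max = max(d), refLength = refLen)
}
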