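#' Exact stochastic simulation of the expression network
#'
#' Samples the jump process defined by the six reaction channels with the
#' Gillespie direct method.  The run is reproducible given `seed`; all
#' derived streams (replicates, cohort cells) are split deterministically
#' from the same seed, so enlarging a batch never changes earlier members.
#'
#' @param params a [GeneNetworkParams-class]
#' @param init integer `c(alpha, m, n)` initial microstate
#' @param tmax simulation horizon (model time units)
#' @param seed integer seed
#' @param record "jumps" stores every reaction event; "sampled" stores
#'   states on a `sampleDt` grid plus all gene-switch events; "end" stores
#'   only the first and last state
#' @param sampleDt grid spacing for `record = "sampled"`
#' @param maxEvents event budget; exhausting it ends the run and is
#'   reported in the `exhausted` slot (distinct from reaching `tmax`)
#' @return a [Trajectory-class]
#' @examples
#' tr <- simulateSSA(paramsPreset("slow"), c(1, 2, 100), tmax = 5, seed = 1)
#' head(trajectoryData(tr))
#' @export
simulateSSA <- function(params, init, tmax, seed,
                        record = c("jumps", "sampled", "end"),
                        sampleDt = 0.1, maxEvents = 1e9) {
  stopifnot(is(params, "GeneNetworkParams"), tmax > 0, length(init) == 3L)
  record <- match.arg(record)
  rec <- match(record, c("end", "jumps", "sampled")) - 1L
  out <- .ssa_simulate_cpp(rates(params), as.integer(init), tmax,
                           maxEvents, as.numeric(seed), rec, sampleDt)
  new("Trajectory",
      data = data.frame(time = out$time, alpha = out$alpha, m = out$m,
                        n = out$n),
      record = record, params = params, seed = as.numeric(seed),
      tEnd = out$tEnd, events = out$events, exhausted = out$exhausted)
}

#' @rdname simulateSSA
#' @param object a [Trajectory-class]
#' @export
trajectoryData <- function(object) object@data

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@data), "records (", object@record,
      "), t in [0,", format(object@tEnd), "],", object@events, "events\n")
  if (object@exhausted) cat("  NOTE: event budget exhausted before horizon\n")
  invisible(object)
})

#' Mean switching time from replicated first-passage simulations
#'
#' Each replicate starts at the source basin's metastable point and runs
#' until the protein count first enters the target basin (the half-plane
#' beyond `threshold`).  Besides the mean switching time, the mean
#' dwell-excluded transition time T is reported: the span from the last
#' visit to the source metastable protein level to arrival.  Replicates
#' that exhaust the event budget are flagged censored and excluded from
#' the mean; the censoring fraction is part of the result.
#'
#' @param params parameter set
#' @param direction "off_on" or "on_off"
#' @param replicates number of independent replicates (>= 2)
#' @param seed integer seed
#' @param threshold protein-count basin split; defaults to
#'   [basinThreshold()]
#' @param start optional explicit starting microstate `c(alpha, m, n)`
#' @param method "exact" for the pure direct method; "tau" enables
#'   tau-leaping of the high-copy channels (gene flips and low-copy
#'   species are always treated exactly), for long sweeps
#' @param maxEvents per-replicate event budget
#' @param eps tau-leap relative-change control
#' @return an [MSTResult-class]
#' @export
estimateMST <- function(params, direction = c("off_on", "on_off"),
                        replicates = 10L, seed = 1L, threshold = NULL,
                        start = NULL, method = c("exact", "tau"),
                        maxEvents = 5e9, eps = 0.03) {
  stopifnot(is(params, "GeneNetworkParams"), replicates >= 2)
  direction <- match.arg(direction)
  method <- match.arg(method)
  if (is.null(threshold)) threshold <- basinThreshold(params)
  mp <- metastablePoints(params)
  if (is.null(start))
    start <- if (direction == "off_on") mp$off else mp$on
  up <- direction == "off_on"
  meta <- if (up) mp$off[["n"]] else mp$on[["n"]]
  out <- .ssa_fpt_cpp(rates(params), as.integer(start), threshold, up,
                      meta, as.integer(replicates), maxEvents,
                      as.numeric(seed), method == "tau", eps)
  ok <- !out$censored
  mst <- if (any(ok)) mean(out$hit[ok]) else NA_real_
  se <- if (sum(ok) > 1) stats::sd(out$hit[ok]) / sqrt(sum(ok)) else NA_real_
  new("MSTResult", direction = direction,
      replicates = as.integer(replicates), mst = mst, se = se,
      transitionTime = if (any(ok)) mean(out$transition[ok]) else NA_real_,
      censoredFraction = mean(out$censored), times = out$hit,
      threshold = as.numeric(threshold))
}

setMethod("show", "MSTResult", function(object) {
  cat(sprintf("MSTResult [%s]: mst = %.4g +/- %.3g (%d replicates",
              object@direction, object@mst, object@se, object@replicates))
  if (object@censoredFraction > 0)
    cat(sprintf(", %.0f%% censored", 100 * object@censoredFraction))
  cat(")\n")
  cat(sprintf("  dwell-excluded transition time T = %.4g\n",
              object@transitionTime))
  invisible(object)
})
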