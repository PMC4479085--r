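# The in-silico flow-cytometry experiment: sample a cohort of cells from
# the stationary law, sort on protein count, culture the sorted groups
# separately, and watch the sorted P+ fractions relax back to the
# stationary P+ mass.  The relaxation speed relative to the a-priori
# transition time T identifies the intermediate regime; the response of
# the recovery time to an upward kappa perturbation separates slow
# (faster recovery) from fast (unchanged or slower).

#' In-silico cell-sorting experiment
#'
#' Samples `cohort` cells jointly over (gene state, mRNA, protein) from
#' the stationary distribution, splits them at the protein `threshold`
#' into P+ and P- groups, evolves every cell by exact simulation, and
#' records each group's P+ fraction at the record times.
#'
#' @param params parameter set
#' @param cohort number of cells (default 50000; a warning is attached
#'   below 100)
#' @param threshold protein count defining P+ cells (default 400)
#' @param recordTimes times at which fractions are recorded; default a
#'   geometric grid spanning `[0.1 T, 30 T]` with T = [referenceTime()]
#' @param seed integer seed
#' @param dist optional precomputed stationary [JointDistribution-class]
#'   (else solved here); also used for the equilibrium P+ mass
#' @param grid truncation window when `dist` is solved here
#' @return a [SortingExperimentResult-class]
#' @export
sortingExperiment <- function(params, cohort = 50000L, threshold = 400,
                              recordTimes = NULL, seed = 1L, dist = NULL,
                              grid = autoGrid(params)) {
  if (cohort < 100)
    warning("cohort < 100 cells: fraction standard errors will be large")
  if (is.null(dist)) dist <- steadyState(params, grid)
  Tref <- referenceTime(params, "on_off", threshold)
  if (is.null(recordTimes))
    recordTimes <- exp(seq(log(0.1 * Tref), log(30 * Tref),
                           length.out = 24L))
  recordTimes <- sort(recordTimes)

  M <- dist@grid@M
  p <- as.vector(rbind(dist@P0, dist@P1))   # level-major (m, alpha) layout
  set.seed(seed)
  idx <- sample.int(length(p), cohort, replace = TRUE, prob = p)
  st <- indexState(idx, dist@grid)
  plus <- st[, "n"] > threshold

  pm <- proteinMarginal(dist)
  equilibrium <- sum(pm[(threshold + 2L):length(pm)])

  evolve <- function(states, seedOff) {
    if (nrow(states) == 0)
      return(rep(NA_real_, length(recordTimes)))
    nMat <- .ssa_cohort_cpp(states, recordTimes, rates(params),
                            as.numeric(seed) * 1000003 + seedOff)
    colMeans(nMat > threshold)
  }
  fracPlus <- evolve(st[plus, , drop = FALSE], 1)
  fracMinus <- evolve(st[!plus, , drop = FALSE], 2)

  new("SortingExperimentResult", threshold = as.numeric(threshold),
      cohort = as.integer(cohort), times = recordTimes,
      fractionPlus = rbind(plus = fracPlus, minus = fracMinus),
      groupSizes = c(plus = sum(plus), minus = sum(!plus)),
      equilibrium = equilibrium, referenceT = Tref, params = params,
      seed = as.numeric(seed))
}

setMethod("show", "SortingExperimentResult", function(object) {
  cat(sprintf(
    "SortingExperimentResult: %d cells (%d P+, %d P-), threshold n > %g\n",
    object@cohort, object@groupSizes[1], object@groupSizes[2],
    object@threshold))
  cat(sprintf("  equilibrium P+ mass %.4f, reference T = %.3g\n",
              object@equilibrium, object@referenceT))
  cat(sprintf("  P+ group fraction: %.3f -> %.3f over [%.3g, %.3g]\n",
              object@fractionPlus[1, 1],
              object@fractionPlus[1, ncol(object@fractionPlus)],
              object@times[1], object@times[length(object@times)]))
  invisible(object)
})

# time at which |f(t) - eq| first drops to half of |f(0+) - eq|;
# censored at the last record time (flagged)
halfRecoveryTime <- function(times, frac, equilibrium, start = 1) {
  gap0 <- abs(start - equilibrium)
  if (gap0 < 1e-12) return(list(t = 0, censored = FALSE))
  gap <- abs(frac - equilibrium) / gap0
  below <- which(gap <= 0.5)
  if (length(below) == 0)
    return(list(t = times[length(times)], censored = TRUE))
  i <- below[1]
  if (i == 1) return(list(t = times[1], censored = FALSE))
  t <- stats::approx(gap[c(i - 1, i)], times[c(i - 1, i)], 0.5)$y
  list(t = t, censored = FALSE)
}

#' Perturbation-response of the sorting experiment to kappa changes
#'
#' Repeats the sorting experiment with the gene-switching rates scaled up
#' by each multiplier (locked ratios, via [kappaFamily()]); the cohort is
#' still sampled from the *baseline* stationary law (the perturbation
#' hits cells at their unperturbed steady state), while recovery is
#' measured towards the perturbed equilibrium.  The response statistic is
#' the signed change of the P+ group's time-to-half-recovery relative to
#' baseline.
#'
#' @param params baseline parameter set
#' @param multipliers kappa multipliers (> 0; 1 reproduces the baseline
#'   up to Monte-Carlo noise).  The default includes x30, which carries
#'   the slow preset into the switching-time valley and so elicits a
#'   strong negative response there
#' @param baseline optional precomputed baseline
#'   [SortingExperimentResult-class] (same seed and settings)
#' @param recomputeEquilibrium solve the perturbed CME for the perturbed
#'   equilibrium (default TRUE; FALSE reuses the baseline equilibrium,
#'   which is nearly exact under locked ratios)
#' @inheritParams sortingExperiment
#' @return list with the baseline result and, per multiplier, the
#'   perturbed result plus `response` (t_half difference, model time
#'   units) and `responseRel` (relative to the baseline t_half)
#' @export
perturbationResponse <- function(params, multipliers = c(4, 30),
                                 cohort = 50000L, threshold = 400,
                                 recordTimes = NULL, seed = 1L,
                                 dist = NULL, grid = autoGrid(params),
                                 baseline = NULL,
                                 recomputeEquilibrium = TRUE) {
  stopifnot(all(multipliers > 0))
  if (is.null(dist)) dist <- steadyState(params, grid)
  if (is.null(baseline))
    baseline <- sortingExperiment(params, cohort, threshold, recordTimes,
                                  seed, dist = dist)
  hrBase <- halfRecoveryTime(baseline@times, baseline@fractionPlus[1, ],
                             baseline@equilibrium)
  perturbed <- lapply(multipliers, function(mult) {
    pk <- kappaFamily(mult * kappa(params), base = params)
    eq <- baseline@equilibrium
    if (recomputeEquilibrium && mult != 1) {
      dk <- steadyState(pk, grid)
      pmk <- proteinMarginal(dk)
      eq <- sum(pmk[(threshold + 2L):length(pmk)])
    }
    res <- sortingExperiment(pk, cohort, threshold,
                             recordTimes = baseline@times, seed = seed,
                             dist = dist)
    res@equilibrium <- eq
    hr <- halfRecoveryTime(res@times, res@fractionPlus[1, ], eq)
    list(multiplier = mult, result = res, tHalf = hr$t,
         censored = hr$censored, response = hr$t - hrBase$t,
         responseRel = (hr$t - hrBase$t) / max(hrBase$t, 1e-12))
  })
  list(baseline = baseline, tHalfBaseline = hrBase$t,
       baselineCensored = hrBase$censored, perturbed = perturbed)
}

#' Classify the gene-switching regime from sorting experiments
#'
#' Decision rule: (i) if the baseline P+ group's fraction has moved more
#' than `moveFrac` of the way to equilibrium by time `cFactor * T`
#' (T the reference transition time), the regime is intermediate -
#' cellular memory is weak; otherwise (ii) a clearly negative
#' perturbation response (recovery at least `respFrac` faster under
#' increased kappa) indicates the slow regime, anything else the fast
#' regime.  The evidence, including an `inconclusive` flag when the
#' relaxation statistic falls near the decision boundary, is attached.
#'
#' @param baseline a [SortingExperimentResult-class]
#' @param responses output of [perturbationResponse()] for the same
#'   baseline (its largest multiplier drives rule ii)
#' @param cFactor observation window in units of the reference time
#' @param moveFrac fraction of the gap to equilibrium that must close
#'   within the window to call "intermediate"
#' @param respFrac relative recovery speed-up that counts as a slow-regime
#'   response
#' @return a [RegimeCall-class]
#' @export
classifyRegime <- function(baseline, responses, cFactor = 30,
                           moveFrac = 0.5, respFrac = 0.25) {
  tObs <- cFactor * baseline@referenceT
  f <- baseline@fractionPlus[1, ]
  fAt <- stats::approx(baseline@times, f, tObs, rule = 2)$y
  gap0 <- abs(1 - baseline@equilibrium)
  relaxFrac <- if (gap0 < 1e-12) 1 else (1 - abs(fAt - baseline@equilibrium) / gap0)
  resp <- responses$perturbed[[which.max(vapply(
    responses$perturbed, function(z) z$multiplier, numeric(1)))]]
  if (relaxFrac >= moveFrac) {
    verdict <- "intermediate"
  } else if (resp$responseRel < -respFrac) {
    verdict <- "slow"
  } else {
    verdict <- "fast"
  }
  inconclusive <- relaxFrac > 0.7 * moveFrac && relaxFrac < 1.3 * moveFrac
  new("RegimeCall", verdict = verdict,
      evidence = list(relaxFrac = relaxFrac, windowTime = tObs,
                      responseRel = resp$responseRel,
                      responseMultiplier = resp$multiplier,
                      baselineCensored = responses$baselineCensored,
                      inconclusive = inconclusive))
}

setMethod("show", "RegimeCall", function(object) {
  cat("RegimeCall:", object@verdict,
      if (isTRUE(object@evidence$inconclusive)) "(inconclusive)" else "",
      "\n")
  cat(sprintf("  relaxation within %.3g tu: %.0f%% of the gap; kappa x%g response: %+.0f%%\n",
              object@evidence$windowTime, 100 * object@evidence$relaxFrac,
              object@evidence$responseMultiplier,
              100 * object@evidence$responseRel))
  invisible(object)
})
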