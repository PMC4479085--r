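#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom Matrix Matrix
#' @importFrom stats approx dpois integrate optim rnorm runif sd setNames uniroot
#' @useDynLib switchscape, .registration = TRUE
NULL

#' Kinetic parameters of the two-state positive-feedback network
#'
#' Holds the nine rate constants of the six-reaction expression network
#' (gene activation/inactivation, transcription, translation, mRNA and
#' protein degradation, and the feedback strength \code{K}) together with
#' the Hill exponent of the feedback occupancy.  All rates are in inverse
#' model time units; \code{K} is a protein copy number.  The adiabaticity
#' ratio kappa = dG / dP is derived, not stored.
#'
#' @slot kG activation gain (occupancy-dependent part of the opening rate)
#' @slot kG0 basal gene activation rate
#' @slot dG gene inactivation rate
#' @slot kR transcription gain (occupancy-dependent)
#' @slot kR0 basal transcription rate
#' @slot kP translation rate per mRNA molecule
#' @slot dR mRNA degradation rate
#' @slot dP protein degradation rate
#' @slot K feedback strength: protein count at half occupancy
#' @slot hillK Hill exponent of the occupancy function (default 1)
#'
#' @seealso [geneNetworkParams()], [paramsPreset()], [kappa()], [kappaFamily()]
#' @export
setClass("GeneNetworkParams",
  representation(kG = "numeric", kG0 = "numeric", dG = "numeric",
                 kR = "numeric", kR0 = "numeric", kP = "numeric",
                 dR = "numeric", dP = "numeric", K = "numeric",
                 hillK = "integer"))

setValidity("GeneNetworkParams", function(object) {
  r <- c(kG = object@kG, kG0 = object@kG0, dG = object@dG, kR = object@kR,
         kR0 = object@kR0, kP = object@kP, dR = object@dR, dP = object@dP)
  if (any(!is.finite(r)) || any(r < 0))
    return("all rates must be finite and non-negative")
  if (object@dP <= 0) return("dP must be strictly positive")
  if (!is.finite(object@K) || object@K <= 0) return("K must be positive")
  if (object@hillK < 1L) return("hillK must be a positive integer")
  TRUE
})

#' Truncation window of the CME lattice
#'
#' Exclusive upper bounds for the mRNA (\code{M}) and protein (\code{N})
#' copy numbers: the chain lives on \code{0 <= m < M}, \code{0 <= n < N}
#' with reflecting truncation (outflow across the boundary suppressed).
#'
#' @slot M mRNA cutoff (exclusive)
#' @slot N protein cutoff (exclusive)
#' @seealso [truncationGrid()], [autoGrid()]
#' @export
setClass("TruncationGrid", representation(M = "integer", N = "integer"))

setValidity("TruncationGrid", function(object) {
  if (length(object@M) != 1L || length(object@N) != 1L) return("M, N scalar")
  if (object@M < 2L || object@N < 2L) return("M and N must both be >= 2")
  TRUE
})

#' Stationary joint distribution on the truncated lattice
#'
#' Probability tables \code{P0[m+1, n+1]} and \code{P1[m+1, n+1]} for the
#' gene-closed and gene-open layers.  Total mass is 1; `boundaryMass`
#' records the probability on the outermost mRNA row and protein column so
#' the adequacy of the truncation can be judged.
#'
#' @slot P0,P1 M x N probability matrices (closed / open layer)
#' @slot grid the [TruncationGrid-class] used
#' @slot params the [GeneNetworkParams-class] solved for
#' @slot boundaryMass named numeric: mass on the m = M-1 and n = N-1 shells
#' @slot residual relative stationarity residual max|A p| / max(p)
#' @export
setClass("JointDistribution",
  representation(P0 = "matrix", P1 = "matrix", grid = "TruncationGrid",
                 params = "GeneNetworkParams", boundaryMass = "numeric",
                 residual = "numeric"))

setValidity("JointDistribution", function(object) {
  if (!identical(dim(object@P0), dim(object@P1)))
    return("P0 and P1 must have identical dimensions")
  if (any(object@P0 < 0) || any(object@P1 < 0))
    return("probabilities must be non-negative")
  tot <- sum(object@P0) + sum(object@P1)
  if (abs(tot - 1) > 1e-8) return("total mass must be 1")
  TRUE
})

#' Potential landscape U = -log P
#'
#' @slot U matrix of potential values on the (m, n) lattice
#' @slot floor probability floor applied before taking logs
#' @slot grid the underlying truncation window
#' @export
setClass("Landscape",
  representation(U = "matrix", floor = "numeric", grid = "TruncationGrid"))

#' Mean/covariance state of the per-layer linear-noise dynamics
#'
#' @slot alpha layer indicator (0 closed, 1 open)
#' @slot x mean vector (m, n)
#' @slot sigma 2 x 2 symmetric covariance matrix
#' @export
setClass("MomentState",
  representation(alpha = "integer", x = "numeric", sigma = "matrix"))

setValidity("MomentState", function(object) {
  if (length(object@x) != 2L) return("x must have length 2")
  if (!identical(dim(object@sigma), c(2L, 2L))) return("sigma must be 2 x 2")
  if (max(abs(object@sigma - t(object@sigma))) > 1e-8)
    return("sigma must be symmetric")
  TRUE
})

#' Two-layer Gaussian-mixture approximation of the stationary landscape
#'
#' Either the simple mixture (one Gaussian per layer, at the layer fixed
#' point with its stationary covariance) or the modified mixture (a
#' time-average of Gaussians along the relaxation trajectory of each
#' layer).  Components with a singular covariance are stored as point
#' masses.
#'
#' @slot w mixture weight of the closed layer
#' @slot components list with elements `closed` and `open`; each is a list
#'   of Gaussian pieces `(weight, mean, sigma)`
#' @slot method "simple" or "modified"
#' @slot params parameter set the mixture was built from
#' @export
setClass("GaussianMixtureLandscape",
  representation(w = "numeric", components = "list", method = "character",
                 params = "GeneNetworkParams"))

setValidity("GaussianMixtureLandscape", function(object) {
  if (object@w <= 0 || object@w >= 1) return("w must lie in (0, 1)")
  if (!all(c("closed", "open") %in% names(object@components)))
    return("components must contain 'closed' and 'open'")
  TRUE
})

#' Minimum-action path between two points of the reduced dynamics
#'
#' Discretised curve phi(s), s in [0, 1], with the conjugate momenta p(s),
#' the speed multiplier lambda(s) and the accumulated geometric action.
#'
#' @slot phi nImages x d matrix of curve points
#' @slot p nImages x d matrix of momenta on the H = 0 level set
#' @slot lambda numeric vector of speed multipliers
#' @slot action total action S = integral of p . dphi
#' @slot cumulative running action along the curve
#' @slot converged logical; FALSE if the outer relaxation hit its
#'   iteration cap before meeting the tolerance
#' @slot diagnostics list with the action history and constraint residuals
#' @export
setClass("ActionPath",
  representation(phi = "matrix", p = "matrix", lambda = "numeric",
                 action = "numeric", cumulative = "numeric",
                 converged = "logical", diagnostics = "list"))

setValidity("ActionPath", function(object) {
  if (!identical(dim(object@phi), dim(object@p)))
    return("phi and p must have identical dimensions")
  if (object@action < -1e-8) return("action must be non-negative")
  TRUE
})

#' Global quasi-potential assembled from two local quasi-potentials
#'
#' @slot S matrix of quasi-potential values on an (m, n) evaluation grid
#' @slot mGrid,nGrid axis coordinates of the evaluation grid
#' @slot paths list of the two optimal switching [ActionPath-class]s
#' @slot criticalPoints data.frame of fixed points and saddle
#' @slot shift numeric shifts applied to the two local surfaces at sticking
#' @export
setClass("QuasiPotential",
  representation(S = "matrix", mGrid = "numeric", nGrid = "numeric",
                 paths = "list", criticalPoints = "data.frame",
                 shift = "numeric"))

#' Result of an in-silico sorting experiment
#'
#' @slot threshold protein threshold defining P+ cells
#' @slot cohort number of sampled cells
#' @slot times record times (model time units)
#' @slot fractionPlus matrix (2 x times): P+ fraction of the sorted P+ and
#'   P- groups at each record time
#' @slot groupSizes sizes of the sorted P+ / P- groups
#' @slot equilibrium stationary P+ mass
#' @slot referenceT deterministic transition-time scale used for the window
#' @slot params parameter set of the run
#' @slot seed integer seed used
#' @export
setClass("SortingExperimentResult",
  representation(threshold = "numeric", cohort = "integer",
                 times = "numeric", fractionPlus = "matrix",
                 groupSizes = "integer", equilibrium = "numeric",
                 referenceT = "numeric", params = "GeneNetworkParams",
                 seed = "numeric"))

setValidity("SortingExperimentResult", function(object) {
  f <- object@fractionPlus
  if (any(f < -1e-12 | f > 1 + 1e-12)) return("fractions must lie in [0, 1]")
  TRUE
})

#' Verdict of the regime classifier
#'
#' @slot verdict one of "slow", "intermediate", "fast"
#' @slot evidence list with the relaxation statistic, the
#'   perturbation-response statistic, and an `inconclusive` flag
#' @export
setClass("RegimeCall",
  representation(verdict = "character", evidence = "list"))

setValidity("RegimeCall", function(object) {
  if (!object@verdict %in% c("slow", "intermediate", "fast"))
    return("verdict must be slow/intermediate/fast")
  TRUE
})

#' Jump trajectory of the expression network
#'
#' Records of an exact simulation: either every jump, or states sampled on
#' a regular time grid plus all gene-switch events (`record = "sampled"`),
#' which keeps long production runs in memory while preserving the exact
#' switch times that delimit reactive segments.
#'
#' @slot data data.frame with columns time, alpha, m, n
#' @slot record "jumps", "sampled" or "end"
#' @slot params parameter set simulated
#' @slot seed integer seed
#' @slot tEnd final simulated time
#' @slot events number of reaction events executed
#' @slot exhausted TRUE if the event budget ended the run before the
#'   horizon
#' @export
setClass("Trajectory",
  representation(data = "data.frame", record = "character",
                 params = "GeneNetworkParams", seed = "numeric",
                 tEnd = "numeric", events = "numeric",
                 exhausted = "logical"))

setValidity("Trajectory", function(object) {
  t <- object@data$time
  if (is.unsorted(t)) return("times must be non-decreasing")
  TRUE
})

#' Mean switching time estimate from replicated first-passage runs
#'
#' @slot direction "off_on" or "on_off"
#' @slot replicates number of independent replicates
#' @slot mst,se mean switching time and its standard error (uncensored
#'   replicates only)
#' @slot transitionTime mean dwell-excluded transition time T (time from
#'   the last visit to the source metastable protein level to arrival)
#' @slot censoredFraction fraction of replicates that hit the event budget
#' @slot times the individual replicate switching times (NA if censored)
#' @slot threshold protein split used for the target basin
#' @export
setClass("MSTResult",
  representation(direction = "character", replicates = "integer",
                 mst = "numeric", se = "numeric",
                 transitionTime = "numeric", censoredFraction = "numeric",
                 times = "numeric", threshold = "numeric"))

setValidity("MSTResult", function(object) {
  if (!is.na(object@mst) && object@mst < 0) return("mst must be >= 0")
  TRUE
})

#' Ensemble of reactive (switching) trajectory segments
#'
#' @slot segments list of data.frames (time, alpha, m, n), each starting
#'   at a gene-switch event and ending on first arrival in the
#'   destination basin
#' @slot density residence-time-weighted visit density on the (m, n)
#'   lattice (matrix, m by n, counts in time units)
#' @slot totalTime total reactive time accumulated in `density`
#' @slot direction "off_on" or "on_off"
#' @export
setClass("PathEnsemble",
  representation(segments = "list", density = "matrix",
                 totalTime = "numeric", direction = "character"))
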