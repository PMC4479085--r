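#' Feedback occupancy of the DNA binding site
#'
#' The fraction of time the regulatory site is occupied at protein count n:
#' `n^k / (n^k + K^k)` with k the Hill exponent.  It multiplies both the
#' activation gain kG and the transcription gain kR, closing the positive
#' feedback loop.
#'
#' @param n protein copy number (vectorised, non-negative)
#' @param params a [GeneNetworkParams-class]
#' @return occupancy values in `[0, 1]`
#' @examples
#' occupancy(3000, paramsPreset("slow"))  # 0.5 at n = K
#' @export
occupancy <- function(n, params) {
  stopifnot(is(params, "GeneNetworkParams"))
  if (any(n < 0)) stop("protein count must be non-negative")
  k <- params@hillK
  if (k == 1L) return(n / (n + params@K))
  r <- (n / params@K)^k
  ifelse(n == 0, 0, r / (r + 1))
}

#' Reaction channels of the two-state network
#'
#' Returns the six channels in table order: (1) gene inactivation, (2) gene
#' activation, (3) transcription, (4) translation, (5) mRNA decay,
#' (6) protein decay.  Each channel carries its state change as an integer
#' increment of (alpha, m, n).  Translation fires at rate `kP * m` and
#' leaves the mRNA count unchanged.
#'
#' @return a data.frame with columns `index`, `dAlpha`, `dM`, `dN`, `label`
#' @export
reactionChannels <- function() {
  data.frame(
    index = 1:6,
    dAlpha = c(-1L, 1L, 0L, 0L, 0L, 0L),
    dM = c(0L, 0L, 1L, 0L, -1L, 0L),
    dN = c(0L, 0L, 0L, 1L, 0L, -1L),
    label = c("gene inactivation", "gene activation", "transcription",
              "translation", "mRNA decay", "protein decay"))
}

#' Propensities of the six reaction channels at a microstate
#'
#' @param state integer vector `c(alpha, m, n)` with alpha in `{0, 1}` and
#'   non-negative copy numbers
#' @param params a [GeneNetworkParams-class]
#' @return numeric vector of six non-negative rates; channels that do not
#'   apply in the current gene state are exactly 0
#' @examples
#' propensities(c(1, 2, 0), paramsPreset("slow"))
#' @export
propensities <- function(state, params) {
  stopifnot(is(params, "GeneNetworkParams"), length(state) == 3L)
  alpha <- state[[1]]; m <- state[[2]]; n <- state[[3]]
  if (!alpha %in% c(0, 1) || m < 0 || n < 0)
    stop("invalid microstate: need alpha in {0,1} and m, n >= 0")
  h <- occupancy(n, params)
  c(params@dG * (alpha == 1),
    (params@kG * h + params@kG0) * (alpha == 0),
    (params@kR * h + params@kR0) * (alpha == 1),
    params@kP * m,
    params@dR * m,
    params@dP * n)
}
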