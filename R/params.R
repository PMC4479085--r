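#' Construct a parameter set for the two-state expression network
#'
#' @param kG,kG0,dG gene activation gain, basal activation, inactivation
#'   rates (1/time)
#' @param kR,kR0 transcription gain and basal transcription (molecules/time)
#' @param kP translation rate per mRNA (1/time)
#' @param dR,dP mRNA and protein degradation rates (1/time)
#' @param K feedback strength (protein copies at half occupancy)
#' @param hillK Hill exponent of the feedback occupancy; 1 corresponds to a
#'   monomer regulator, 2 to a dimer, and so on
#' @return a validated [GeneNetworkParams-class]
#' @examples
#' p <- paramsPreset("slow")
#' kappa(p)
#' @export
geneNetworkParams <- function(kG, kG0, dG, kR, kR0, kP, dR, dP, K,
                              hillK = 1L) {
  new("GeneNetworkParams", kG = as.numeric(kG), kG0 = as.numeric(kG0),
      dG = as.numeric(dG), kR = as.numeric(kR), kR0 = as.numeric(kR0),
      kP = as.numeric(kP), dR = as.numeric(dR), dP = as.numeric(dP),
      K = as.numeric(K), hillK = as.integer(hillK))
}

#' Canonical parameter presets
#'
#' `"slow"` is the non-adiabatic reference set (kappa = 0.001): kR = 100,
#' kR0 = 0.1, kP = 51.5, dR = 0.7, dP = 1.4, dG = 0.0014, kG = 0.028,
#' kG0 = 0.00028, K = 3000.  `"fast"` keeps all synthesis/degradation
#' rates and rescales the three gene-switching rates to dG = 140,
#' kG = 2800, kG0 = 28 (kappa = 100), preserving the ratios
#' dG/kG = 0.05 and dG/kG0 = 5.
#'
#' @param name "slow" or "fast"
#' @param K optional override of the feedback strength
#' @param hillK optional override of the Hill exponent
#' @return a [GeneNetworkParams-class]
#' @export
paramsPreset <- function(name = c("slow", "fast"), K = 3000, hillK = 1L) {
  name <- match.arg(name)
  base <- geneNetworkParams(kG = 0.028, kG0 = 0.00028, dG = 0.0014,
                            kR = 100, kR0 = 0.1, kP = 51.5, dR = 0.7,
                            dP = 1.4, K = K, hillK = hillK)
  if (name == "slow") base else kappaFamily(100, base)
}

#' Rescale the gene-switching rates to a target adiabaticity
#'
#' Sets dG = kappa * dP and rescales kG and kG0 so that the ratios dG/kG
#' and dG/kG0 keep their values in `base`; all other rates are untouched.
#' This is the one-parameter family traversed by the mean-switching-time
#' sweeps and by kappa perturbations in the sorting experiment.
#'
#' @param kappa target ratio dG / dP (> 0)
#' @param base reference [GeneNetworkParams-class]
#' @return a new parameter set with `kappa(result) == kappa`
#' @export
kappaFamily <- function(kappa, base = paramsPreset("slow")) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa > 0)
  dG <- kappa * base@dP
  p <- base
  p@dG <- dG
  p@kG <- dG / (base@dG / base@kG)
  p@kG0 <- dG / (base@dG / base@kG0)
  validObject(p)
  p
}

#' @describeIn geneNetworkParams named vector of the nine rate constants
#'   plus the Hill exponent, in the layout the C++ kernels expect
#' @param object a parameter set
#' @export
setMethod("rates", "GeneNetworkParams", function(object) {
  c(kG = object@kG, kG0 = object@kG0, dG = object@dG, kR = object@kR,
    kR0 = object@kR0, kP = object@kP, dR = object@dR, dP = object@dP,
    K = object@K, hillK = as.numeric(object@hillK))
})

setMethod("show", "GeneNetworkParams", function(object) {
  cat("GeneNetworkParams (kappa =", format(kappa(object)), ")\n")
  cat("  gene:  kG =", object@kG, " kG0 =", object@kG0,
      " dG =", object@dG, "\n")
  cat("  mRNA:  kR =", object@kR, " kR0 =", object@kR0,
      " dR =", object@dR, "\n")
  cat("  prot:  kP =", object@kP, " dP =", object@dP, "\n")
  cat("  feedback: K =", object@K, " hill =", object@hillK, "\n")
  invisible(object)
})
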