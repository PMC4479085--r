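#' Load a run configuration
#'
#' Reads a YAML configuration with either a `preset` ("slow"/"fast") or
#' an explicit `rates` block naming all nine constants, plus optional
#' `kappa` (locked-ratio rescale), `K`, `hillK`, truncation overrides,
#' seeds and experiment settings.  Unknown keys are rejected so typos
#' fail loudly.
#'
#' @param path path to a YAML file
#' @return list with elements `params` (a [GeneNetworkParams-class]),
#'   `grid` (NULL for automatic), `seed`, and `experiment` settings
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("preset", "rates", "kappa", "K", "hillK", "grid", "seed",
             "experiment")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))

  params <- if (!is.null(cfg$rates)) {
    need <- c("kG", "kG0", "dG", "kR", "kR0", "kP", "dR", "dP", "K")
    miss <- setdiff(need, names(cfg$rates))
    if (length(miss) > 0)
      stop("rates block is missing: ", paste(miss, collapse = ", "))
    do.call(geneNetworkParams,
            c(cfg$rates[need],
              list(hillK = cfg$rates$hillK %||other% 1L)))
  } else {
    preset <- cfg$preset %||other% "slow"
    if (!preset %in% c("slow", "fast"))
      stop("preset must be 'slow' or 'fast'")
    paramsPreset(preset)
  }
  if (!is.null(cfg$K)) { params@K <- as.numeric(cfg$K); validObject(params) }
  if (!is.null(cfg$hillK)) {
    params@hillK <- as.integer(cfg$hillK); validObject(params)
  }
  if (!is.null(cfg$kappa)) params <- kappaFamily(cfg$kappa, params)

  grid <- if (!is.null(cfg$grid)) {
    # keys are spelled out because bare M/N collide with YAML booleans
    if (!all(c("mrna", "protein") %in% names(cfg$grid)))
      stop("grid block needs 'mrna' and 'protein' cutoffs")
    truncationGrid(cfg$grid$mrna, cfg$grid$protein)
  }
  exp <- cfg$experiment %||other% list()
  expKnown <- c("threshold", "cohort", "recordTimes", "replicates",
                "multipliers")
  badExp <- setdiff(names(exp), expKnown)
  if (length(badExp) > 0)
    stop("unknown experiment keys: ", paste(badExp, collapse = ", "))
  list(params = params, grid = grid, seed = cfg$seed %||other% 1L,
       experiment = exp)
}

`%||other%` <- function(a, b) if (is.null(a)) b else a

#' Reference fixtures with closed-form oracles
#'
#' Small reduced models used throughout the test suite, each paired with
#' the analytic expectation that verifies the numerical machinery:
#' \describe{
#'   \item{poisson_mrna}{gene pinned open (dG = 0), feedback off: the
#'     stationary mRNA law is Poisson with mean kR0 / dR.}
#'   \item{pure_death}{all rates zero except protein decay: the mean
#'     first-passage time from n0 to 0 is the harmonic sum
#'     (1/dP) * sum_{k<=n0} 1/k.}
#'   \item{two_state_gene}{gene flips only: the stationary open
#'     probability is kG0 / (kG0 + dG).}
#'   \item{tiny_bistable}{a scaled-down bistable switch (on state near
#'     n = 20) solvable exactly on a 16 x 110 lattice; the oracle is the
#'     direct sparse solve of its generator.}
#'   \item{oneD_birth_death}{protein-only birth-death channels (birth 20,
#'     unit decay) whose quasi-potential is the closed form
#'     integral of log(d n / b).}
#' }
#'
#' @param name fixture name
#' @return list with `params` (or `channels`), `grid` where relevant,
#'   and `oracle`, a list of closed-form values/functions
#' @export
makeFixture <- function(name = c("poisson_mrna", "pure_death",
                                 "two_state_gene", "tiny_bistable",
                                 "oneD_birth_death")) {
  name <- match.arg(name)
  switch(name,
    poisson_mrna = {
      p <- geneNetworkParams(kG = 0, kG0 = 1, dG = 0, kR = 0, kR0 = 5,
                             kP = 0, dR = 1, dP = 1, K = 1e6)
      list(params = p, grid = truncationGrid(30, 2),
           init = c(1L, 0L, 0L),
           oracle = list(mean = 5, variance = 5,
                         pmf = function(m) stats::dpois(m, 5)))
    },
    pure_death = {
      p <- geneNetworkParams(kG = 0, kG0 = 0, dG = 0, kR = 0, kR0 = 0,
                             kP = 0, dR = 1, dP = 1, K = 1)
      list(params = p, grid = truncationGrid(2, 8),
           init = c(1L, 0L, 3L),
           oracle = list(
             mfpt = function(n0, dP = 1) sum(1 / (1:n0)) / dP))
    },
    two_state_gene = {
      p <- geneNetworkParams(kG = 0, kG0 = 0.7, dG = 0.35, kR = 0,
                             kR0 = 0, kP = 0, dR = 1, dP = 1, K = 1)
      list(params = p, grid = truncationGrid(2, 2),
           oracle = list(pOpen = 0.7 / (0.7 + 0.35)))
    },
    tiny_bistable = {
      p <- geneNetworkParams(kG = 2, kG0 = 0.1, dG = 0.3, kR = 5,
                             kR0 = 0.05, kP = 10, dR = 1, dP = 1, K = 12)
      list(params = p, grid = truncationGrid(16, 110), threshold = 8L,
           oracle = list(reference = "direct sparse solve of the generator"))
    },
    oneD_birth_death = {
      b <- 20; d <- 1
      list(channels = list(
             jumps = matrix(c(1, -1), 2, 1),
             rate = function(x) c(b, d * max(x[1], 0)),
             rateJac = function(x) matrix(c(0, d), 2, 1)),
           birth = b, death = d, attractor = b / d,
           oracle = list(
             action = function(target, n0 = b / d)
               abs(stats::integrate(function(n) log(d * n / b), n0,
                                    target)$value)))
    })
}

#' Export a result object to text files
#'
#' Distributions and quasi-potentials are written as delimited grid
#' tables with axis columns; data.frames as CSV; anything else as JSON.
#' Every file is accompanied by a `<file>.meta.json` carrying the
#' package version, the export timestamp-free content hash inputs
#' (class, dimensions) and the seed when the object records one, so
#' re-runs are byte-comparable.
#'
#' @param result object to export
#' @param file output path
#' @param format "delimited" or "json" (grids ignore "json")
#' @return the output path, invisibly
#' @export
exportResult <- function(result, file, format = c("delimited", "json")) {
  format <- match.arg(format)
  meta <- list(package = "switchscape",
               version = as.character(utils::packageVersion("switchscape")),
               class = class(result)[1])
  if (is(result, "JointDistribution")) {
    M <- result@grid@M; N <- result@grid@N
    df <- data.frame(
      m = rep(0:(M - 1), times = 2 * N),
      n = rep(rep(0:(N - 1), each = M), times = 2),
      alpha = rep(c(0L, 1L), each = M * N),
      p = c(as.vector(result@P0), as.vector(result@P1)))
    utils::write.csv(df, file, row.names = FALSE)
    meta$dims <- c(M = M, N = N)
  } else if (is(result, "QuasiPotential")) {
    df <- expand.grid(m = result@mGrid, n = result@nGrid)
    df$S <- as.vector(result@S)
    utils::write.csv(df, file, row.names = FALSE)
  } else if (is(result, "SortingExperimentResult")) {
    df <- data.frame(time = result@times,
                     fractionPlus = result@fractionPlus["plus", ],
                     fractionMinus = result@fractionPlus["minus", ])
    utils::write.csv(df, file, row.names = FALSE)
    meta$seed <- result@seed
    meta$equilibrium <- result@equilibrium
  } else if (is.data.frame(result)) {
    if (format == "json")
      jsonlite::write_json(result, file, dataframe = "rows", digits = NA)
    else utils::write.csv(result, file, row.names = FALSE)
  } else if (is(result, "RegimeCall")) {
    jsonlite::write_json(list(verdict = result@verdict,
                              evidence = result@evidence),
                         file, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(result, file, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  jsonlite::write_json(meta, paste0(file, ".meta.json"), auto_unbox = TRUE)
  invisible(file)
}
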