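# Shared fixtures and memoised heavyweight objects.  Full-size CME
# solves take ~45 s each, so the stationary solutions of the canonical
# presets are computed once per test run and reused by every test that
# needs them.

.cache <- new.env(parent = emptyenv())

cachedSteadyState <- function(kap) {
  key <- paste0("ss_", kap)
  if (is.null(.cache[[key]])) {
    pk <- kappaFamily(kap, paramsPreset("slow"))
    .cache[[key]] <- steadyState(pk, autoGrid(pk))
  }
  .cache[[key]]
}

cachedTinySolution <- function() {
  if (is.null(.cache$tiny)) {
    fx <- makeFixture("tiny_bistable")
    .cache$tiny <- suppressWarnings(
      steadyState(fx$params, fx$grid, method = "qbd"))
  }
  .cache$tiny
}

# empirical residence-time histogram of a jump-record trajectory on the
# (alpha, m, n) lattice of `grid`
empiricalHistogram <- function(traj, grid) {
  td <- trajectoryData(traj)
  dt <- diff(c(td$time, traj@tEnd))
  M <- grid@M
  emp <- matrix(0, 2 * M, grid@N)
  i <- td$m + 1L + M * td$alpha
  j <- pmin(td$n, grid@N - 1L) + 1L
  for (k in seq_len(nrow(td))) emp[i[k], j[k]] <- emp[i[k], j[k]] + dt[k]
  emp / sum(emp)
}

totalVariation <- function(p, q) 0.5 * sum(abs(p - q))
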