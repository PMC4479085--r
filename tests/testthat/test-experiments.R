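test_that("bistability is reported from stationary basin masses", {
  fx <- makeFixture("tiny_bistable")
  rep <- bistabilityReport(fx$params, grid = fx$grid,
                           threshold = fx$threshold,
                           dist = cachedTinySolution())
  expect_true(rep$bistable)
  expect_equal(sum(rep$occupancy), 1, tolerance = 1e-10)
  expect_gt(rep$occupancy[["off"]], 0.5)
  expect_gt(rep$occupancy[["on"]], 0.05)
  # crank the feedback threshold K up: the on basin starves
  pk <- fx$params; pk@K <- 70
  rep2 <- suppressWarnings(
    bistabilityReport(pk, grid = fx$grid, threshold = fx$threshold))
  expect_lt(rep2$occupancy[["on"]], 0.01)
  expect_false(rep2$bistable)
})

test_that("reference transition times match their closed forms", {
  p <- paramsPreset("slow")
  fp <- layerFixedPoint(1, p)
  # threshold at the starting level: no time needed
  expect_equal(referenceTime(p, "on_off", threshold = fp[["n"]]), 0)
  expect_equal(referenceTime(p, "off_on", threshold = 0), 0)
  # the closed-layer decay is sandwiched between pure protein decay
  # (rate dP, ignoring the mRNA tail) and the slowest decay mode (dR):
  T400 <- referenceTime(p, "on_off", 400)
  T800 <- referenceTime(p, "on_off", 800)
  expect_gt(T400, T800)           # farther threshold takes longer
  # protein decays no faster than pure exponential at rate dP
  expect_gte(T400, log(fp[["n"]] / 400) / p@dP - 1e-9)
  # and no slower than the slowest relevant decay mode (rate dR)
  expect_lte(T400, log((fp[["n"]] + p@kP * fp[["m"]] / (p@dP - p@dR)) /
                         400) / p@dR)
  expect_error(referenceTime(p, "off_on", threshold = 1e6), "threshold|fixed")
})

test_that("switching-time sweeps carry censoring and both back-ends", {
  fx <- makeFixture("tiny_bistable")
  tab <- mstSweep(c(0.1, 1), Ks = fx$params@K, directions = "off_on",
                  params = fx$params, replicates = 40, seed = 2,
                  threshold = fx$threshold, leap = FALSE)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$mst > 0))
  tabM <- mstSweep(c(0.1, 1), Ks = fx$params@K, directions = "off_on",
                   params = fx$params, method = "mfpt",
                   threshold = fx$threshold)
  # stochastic and deterministic back-ends agree within sampling error
  expect_true(all(abs(tab$mst - tabM$mst) < 4 * tab$se))
})
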