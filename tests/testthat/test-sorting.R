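test_that("sorted groups start pure and stay martingale-consistent", {
  fx <- makeFixture("tiny_bistable")
  d <- cachedTinySolution()
  res <- suppressWarnings(
    sortingExperiment(fx$params, cohort = 4000, threshold = fx$threshold,
                      recordTimes = c(0.01, 0.5, 2, 8, 30, 120),
                      seed = 21, dist = d))
  f <- res@fractionPlus
  # immediately after sorting the groups are still (almost) pure
  expect_gt(f["plus", 1], 0.95)
  expect_lt(f["minus", 1], 0.05)
  # cohort-weighted average stays at the stationary P+ mass throughout
  w <- res@groupSizes / sum(res@groupSizes)
  mixed <- w[["plus"]] * f["plus", ] + w[["minus"]] * f["minus", ]
  pTrue <- res@equilibrium
  tolBinom <- 4 * sqrt(pTrue * (1 - pTrue) / res@cohort)
  expect_true(all(abs(mixed - pTrue) < tolBinom))
  # long-run convergence of both groups to the stationary mass
  expect_lt(abs(f["plus", 6] - pTrue), 0.05)
  expect_lt(abs(f["minus", 6] - pTrue), 0.05)
})

test_that("a unit kappa multiplier leaves the recovery time unchanged", {
  fx <- makeFixture("tiny_bistable")
  d <- cachedTinySolution()
  pr <- suppressWarnings(
    perturbationResponse(fx$params, multipliers = 1, cohort = 3000,
                         threshold = fx$threshold, seed = 13, dist = d,
                         recordTimes = c(0.5, 2, 5, 10, 20, 40, 80)))
  expect_lt(abs(pr$perturbed[[1]]$responseRel), 0.35)
})

test_that("the classifier separates the three canonical regimes", {
  # full-size presets; stationary solutions shared across seeds
  verdicts <- list(slow = character(0), intermediate = character(0),
                   fast = character(0))
  for (kap in c(0.001, 0.03, 50)) {
    pk <- kappaFamily(kap, paramsPreset("slow"))
    d <- cachedSteadyState(kap)
    lab <- switch(as.character(kap), "0.001" = "slow",
                  "0.03" = "intermediate", "50" = "fast")
    for (seed in 1:5) {
      pr <- perturbationResponse(pk, multipliers = 30, cohort = 600,
                                 seed = seed, dist = d,
                                 recomputeEquilibrium = FALSE)
      call <- classifyRegime(pr$baseline, pr)
      verdicts[[lab]] <- c(verdicts[[lab]], call@verdict)
    }
  }
  expect_true(all(verdicts$slow == "slow"))
  expect_true(all(verdicts$intermediate == "intermediate"))
  expect_true(all(verdicts$fast == "fast"))
})
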