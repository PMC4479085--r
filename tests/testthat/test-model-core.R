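test_that("occupancy follows the Hill form and its limits", {
  p <- paramsPreset("slow")            # K = 3000, hill 1
  expect_equal(occupancy(0, p), 0)
  expect_equal(occupancy(3000, p), 0.5)
  p2 <- paramsPreset("slow", hillK = 2L)
  expect_equal(occupancy(3000, p2), 0.5)   # n = K for any exponent
  # monotone in n, monotone decreasing in K, saturating at 1
  ns <- c(0, 1, 10, 100, 1e3, 1e4, 1e6, 1e9)
  expect_true(all(diff(occupancy(ns, p)) >= 0))
  expect_gt(occupancy(500, kappaFamily(1, paramsPreset("slow"))) -
              occupancy(500, p), -1e-15)
  expect_lt(abs(occupancy(1e12, p) - 1), 1e-6)
  expect_error(occupancy(-1, p), "non-negative")
})

test_that("propensities reproduce the reaction-table rates", {
  p <- paramsPreset("slow")
  # open gene, 2 mRNAs, no protein: transcription at basal rate, both
  # mRNA channels active, inactivation live, the rest silent
  r <- propensities(c(1, 2, 0), p)
  expect_equal(r, c(0.0014, 0, 0.1, 103.0, 1.4, 0), tolerance = 1e-12)
  # closed state at the origin: only basal activation fires
  r0 <- propensities(c(0, 0, 0), p)
  expect_equal(r0[2], 0.00028)
  expect_equal(sum(r0[-2]), 0)
  # absorbing-boundary consistency: decay channels vanish at zero counts
  expect_equal(propensities(c(1, 0, 0), p)[5], 0)
  # random states: all rates finite and non-negative
  set.seed(1)
  for (i in 1:50) {
    s <- c(sample(0:1, 1), sample(0:200, 1), sample(0:5000, 1))
    r <- propensities(s, p)
    expect_true(all(is.finite(r)) && all(r >= 0))
  }
})

test_that("kappa families lock the gene-rate ratios", {
  base <- paramsPreset("slow")
  expect_equal(kappa(base), 0.001)
  p1 <- kappaFamily(0.001, base)
  expect_equal(c(p1@dG, p1@kG, p1@kG0), c(0.0014, 0.028, 0.00028))
  p2 <- kappaFamily(100, base)
  expect_equal(c(p2@dG, p2@kG, p2@kG0), c(140, 2800, 28))
  p3 <- kappaFamily(1, base)
  expect_equal(c(p3@dG, p3@kG, p3@kG0), c(1.4, 28, 0.28))
  # round trip and ratio locking across magnitudes
  for (kap in 10^seq(-5, 5, by = 2)) {
    pk <- kappaFamily(kap, base)
    expect_equal(kappa(pk), kap)
    expect_equal(pk@dG / pk@kG, base@dG / base@kG)
    expect_equal(pk@dG / pk@kG0, base@dG / base@kG0)
  }
  expect_error(kappaFamily(-1, base))
})

test_that("parameter validity is enforced", {
  expect_error(geneNetworkParams(kG = 1, kG0 = 1, dG = 1, kR = 1, kR0 = 1,
                                 kP = 1, dR = 1, dP = 0, K = 10), "dP")
  expect_error(geneNetworkParams(kG = 1, kG0 = 1, dG = 1, kR = 1, kR0 = 1,
                                 kP = 1, dR = 1, dP = 1, K = -5), "K")
  expect_error(propensities(c(2, 0, 0), paramsPreset("slow")))
  expect_error(propensities(c(1, -1, 0), paramsPreset("slow")))
})

test_that("reaction channels carry consistent state changes", {
  ch <- reactionChannels()
  expect_equal(nrow(ch), 6L)
  # net protein change comes only from translation and decay
  expect_equal(sum(ch$dN), 0L)
  expect_equal(ch$dM[3], 1L)      # transcription makes one mRNA
  expect_equal(ch$dAlpha[1:2], c(-1L, 1L))
})
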