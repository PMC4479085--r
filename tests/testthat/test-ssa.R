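test_that("simulation is exact on closed-form sub-models", {
  # pure death from n = 5: mean absorption time is the harmonic sum
  pd <- makeFixture("pure_death")$params
  times <- vapply(1:400, function(r) {
    tr <- simulateSSA(pd, c(1, 0, 5), tmax = 100, seed = r)
    tr@tEnd
  }, numeric(1))
  exact <- sum(1 / (1:5))
  expect_lt(abs(mean(times) - exact), 3 * sd(times) / sqrt(length(times)))

  # Poisson sub-model: time-averaged mRNA mean and variance agree
  pf <- makeFixture("poisson_mrna")
  tr <- simulateSSA(pf$params, c(1, 5, 0), tmax = 4000, seed = 9)
  td <- trajectoryData(tr)
  dt <- diff(c(td$time, tr@tEnd))
  mBar <- sum(td$m * dt) / sum(dt)
  vBar <- sum((td$m - mBar)^2 * dt) / sum(dt)
  expect_equal(mBar, 5, tolerance = 0.1)
  expect_equal(vBar, 5, tolerance = 0.15)
})

test_that("the same seed reproduces the trajectory exactly", {
  p <- makeFixture("tiny_bistable")$params
  a <- simulateSSA(p, c(0, 0, 0), tmax = 50, seed = 123)
  b <- simulateSSA(p, c(0, 0, 0), tmax = 50, seed = 123)
  expect_identical(trajectoryData(a), trajectoryData(b))
  c <- simulateSSA(p, c(0, 0, 0), tmax = 50, seed = 124)
  expect_false(identical(trajectoryData(a), trajectoryData(c)))
})

test_that("the long-run SSA histogram matches the stationary CME", {
  fx <- makeFixture("tiny_bistable")
  d <- cachedTinySolution()
  tr <- simulateSSA(fx$params, c(0, 0, 0), tmax = 40000, seed = 5,
                    maxEvents = 5e6)
  emp <- empiricalHistogram(tr, fx$grid)
  expect_lt(totalVariation(emp, rbind(d@P0, d@P1)), 0.02)
})

test_that("switching-time estimates agree with the first-passage solve", {
  fx <- makeFixture("tiny_bistable")
  thr <- fx$threshold
  mf <- meanFirstPassage(fx$params, "off_on", grid = fx$grid,
                         threshold = thr, start = c(0L, 0L, 0L))
  est <- estimateMST(fx$params, "off_on", replicates = 200, seed = 31,
                     threshold = thr, start = c(0L, 0L, 0L))
  expect_lt(abs(est@mst - as.numeric(mf)), 3 * est@se)
  expect_equal(est@censoredFraction, 0)
  # event-budget exhaustion is reported as censoring, not as a result
  est2 <- estimateMST(fx$params, "off_on", replicates = 5, seed = 3,
                      threshold = thr, maxEvents = 10)
  expect_equal(est2@censoredFraction, 1)
  expect_true(is.na(est2@mst))
})

test_that("tau-leaping reproduces the exact switching time distributionally", {
  p <- kappaFamily(0.03, paramsPreset("slow"))
  thr <- basinThreshold(p)
  ex <- estimateMST(p, "on_off", replicates = 30, seed = 8, threshold = thr,
                    method = "exact")
  tl <- estimateMST(p, "on_off", replicates = 30, seed = 8, threshold = thr,
                    method = "tau")
  se <- sqrt(ex@se^2 + tl@se^2)
  expect_lt(abs(ex@mst - tl@mst), 3 * se)
})

test_that("reactive segments follow the extraction rule and conserve time", {
  fx <- makeFixture("tiny_bistable")
  tr <- simulateSSA(fx$params, c(0, 0, 0), tmax = 3000, seed = 77)
  ens <- reactiveSegments(tr, "off_on", threshold = fx$threshold)
  expect_gt(length(ens@segments), 0)
  for (seg in ens@segments) {
    expect_equal(seg$alpha[1], 1L)                      # starts at a switch
  }
  recomputed <- sum(vapply(ens@segments,
                           function(s) diff(range(s$time)), numeric(1)))
  expect_equal(ens@totalTime, recomputed, tolerance = 1e-9)
  expect_equal(sum(ens@density), ens@totalTime, tolerance = 1e-9)
})

test_that("averaged paths preserve single segments and symmetry", {
  seg <- data.frame(time = 0:10 / 10,
                    alpha = 1L, m = 0:10, n = (0:10)^2)
  ens1 <- new("PathEnsemble", segments = list(seg),
              density = matrix(0, 1, 1), totalTime = 1,
              direction = "off_on")
  ap <- suppressWarnings(averagePath(ens1, bins = 11))
  # the average of one segment is that segment as a curve (the progress
  # grid resamples it by arc length, so compare geometrically)
  expect_equal(unlist(ap[1, c("m", "n")]), c(m = 0, n = 0))
  expect_equal(unlist(ap[11, c("m", "n")]), c(m = 10, n = 100))
  dense <- data.frame(m = seq(0, 10, by = 0.01),
                      n = seq(0, 10, by = 0.01)^2)
  expect_lt(pathDistance(ap, dense)$mean, 0.35)

  # two mirror-image segments about m = 5 average onto the symmetry line
  s1 <- data.frame(time = 0:10 / 10, alpha = 1L, m = 5 + 0:10 * 0,
                   n = 0:10)
  s1$m <- 5 + c(0, 1, 2, 3, 2, 1, 0, -1, -2, -1, 0)
  s2 <- s1; s2$m <- 10 - s1$m
  ens2 <- new("PathEnsemble", segments = list(s1, s2),
              density = matrix(0, 1, 1), totalTime = 2,
              direction = "off_on")
  ap2 <- suppressWarnings(averagePath(ens2, bins = 21))
  expect_true(all(abs(ap2$m - 5) < 1e-8))
})
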