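test_that("layer fixed points solve the per-layer nullclines", {
  p <- paramsPreset("slow")
  expect_equal(unname(layerFixedPoint(0, p)), c(0, 0))
  # independent fixed-point iteration as oracle for the open layer
  cc <- p@kP / (p@dP * p@dR)
  n <- 1000
  for (i in 1:200) n <- cc * (p@kR0 + p@kR * n / (n + p@K))
  fp <- layerFixedPoint(1, p)
  expect_equal(unname(fp["n"]), n, tolerance = 1e-8)
  expect_equal(unname(fp["m"]), unname(p@dP * fp["n"] / p@kP),
               tolerance = 1e-8)
  # feedback removed: linear closed form
  p0 <- p; p0@kR <- 0
  fp0 <- layerFixedPoint(1, p0)
  expect_equal(unname(fp0), c(p@kR0 / p@dR,
                              p@kP * p@kR0 / (p@dR * p@dP)),
               tolerance = 1e-10)
})

test_that("the moment flow is stationary at the Lyapunov pair and exact on
           the linear sub-model", {
  p <- kappaFamily(0.005, paramsPreset("slow"))
  sm <- layerStationaryMoments(1, p)
  tr <- integrateMoments(momentState(1, sm$x, sm$sigma), p,
                         times = c(0, 1, 5, 20))
  expect_equal(tr$m, rep(sm$x[["m"]], 4), tolerance = 1e-5)
  expect_equal(tr$n, rep(sm$x[["n"]], 4), tolerance = 1e-5)
  expect_equal(tr$s22, rep(sm$sigma[2, 2], 4), tolerance = 1e-4)

  # closed layer from the origin stays put
  tr0 <- integrateMoments(momentState(0, c(0, 0)), p, times = c(0, 2, 10))
  expect_true(all(abs(as.matrix(tr0[, -1])) < 1e-10))

  # linear birth-death: stationary mRNA variance equals the mean
  pl <- p; pl@kR <- 0
  sml <- layerStationaryMoments(1, pl)
  expect_equal(sml$sigma[1, 1], pl@kR0 / pl@dR, tolerance = 1e-8)
})

test_that("covariance stays symmetric and positive semidefinite along the
           flow", {
  p <- kappaFamily(0.002, paramsPreset("slow"))
  tr <- integrateMoments(momentState(1, c(0, 0)), p,
                         times = seq(0, 30, by = 0.5))
  for (i in seq_len(nrow(tr))) {
    S <- matrix(c(tr$s11[i], tr$s12[i], tr$s12[i], tr$s22[i]), 2, 2)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9 * max(abs(ev), 1))
  }
})

test_that("mixture weight is the dwell-time balance of the two layers", {
  p <- paramsPreset("slow")
  # closed dwell 1/kG0 = 3571 vs open dwell 1/dG = 714: the gene is
  # closed five sixths of the time
  expect_equal(mixtureWeight(p), 5 / 6, tolerance = 1e-12)
  # gene that never closes spends no time on the closed layer
  p0 <- p; p0@dG <- 1e-9
  expect_lt(mixtureWeight(p0), 1e-5)
  expect_warning(simpleMixture(kappaFamily(0.5, p)), "slow regime")
})

test_that("mixture densities normalise and the modified mixture collapses
           to the simple one in the frozen-gene limit", {
  p <- kappaFamily(1e-5, paramsPreset("slow"))
  g <- truncationGrid(40, 300)   # reduced window around both components
  # (kept small on purpose: densities are renormalised on the window)
  pSmall <- p
  pSmall@kR <- 2; pSmall@K <- 60; pSmall@kP <- 8; pSmall@kR0 <- 0.05
  simple <- mixtureDensity(simpleMixture(pSmall), g)
  modified <- mixtureDensity(modifiedMixture(pSmall, nTime = 120), g)
  expect_equal(sum(jointProbability(simple)), 1, tolerance = 1e-6)
  expect_equal(sum(jointProbability(modified)), 1, tolerance = 1e-6)
  expect_lt(klDivergence(jointProbability(modified),
                         jointProbability(simple)), 5e-3)
})

test_that("the modified mixture beats the simple one against the CME on a
           small slow switch", {
  base <- makeFixture("tiny_bistable")$params
  # the fixture window intentionally trades edge mass for speed
  tab <- suppressWarnings(
    compareLandscapes(base, kappas = c(3e-4, 3e-3),
                      grid = makeFixture("tiny_bistable")$grid,
                      nTime = 120))
  wide <- reshape(tab, idvar = c("kappa", "layer"), timevar = "method",
                  direction = "wide")
  expect_true(all(wide$kl.modified <= wide$kl.simple + 1e-9))
})
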