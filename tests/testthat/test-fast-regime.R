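test_that("reduced drift matches its channel decomposition and origin
           value", {
  p <- paramsPreset("fast")
  d0 <- reducedDrift(c(0, 0), p)
  expect_equal(d0, c(p@kR0 * p@kG0 / (p@dG + p@kG0), 0),
               tolerance = 1e-12)
  ch <- reducedChannels(p)
  set.seed(7)
  for (i in 1:100) {
    x <- c(runif(1, 0, 80), runif(1, 0, 4000))
    viaChannels <- as.vector(t(ch$jumps) %*% ch$rate(x))
    expect_equal(viaChannels, reducedDrift(x, p), tolerance = 1e-12)
  }
  # adiabatic saturation: huge kG pins the gene open
  pBig <- p; pBig@kG <- 1e9; pBig@kG0 <- 1e7
  x <- c(10, 500)
  h <- occupancy(500, pBig)
  expect_equal(reducedDrift(x, pBig)[1],
               (pBig@kR0 + pBig@kR * h) - pBig@dR * 10, tolerance = 1e-4)
})

test_that("critical points of the reduced drift are located and
           classified", {
  p <- paramsPreset("fast")
  cp <- findCriticalPoints(p)
  expect_equal(nrow(cp), 3L)
  expect_equal(sum(cp$type == "stable"), 2L)
  expect_equal(sum(cp$type == "saddle"), 1L)
  expect_true(isTRUE(attr(cp, "bistable")))
  for (i in seq_len(nrow(cp))) {
    expect_lt(sqrt(sum(reducedDrift(c(cp$m[i], cp$n[i]), p)^2)), 1e-8)
  }
  # far outside the bistable window only the off state survives
  pMono <- p; pMono@K <- 6000
  cpM <- findCriticalPoints(pMono)
  expect_false(isTRUE(attr(cpM, "bistable")))
  expect_equal(sum(cpM$type == "stable"), 1L)
})

test_that("the Hamiltonian vanishes at zero momentum with the drift as its
           gradient", {
  p <- paramsPreset("fast")
  set.seed(11)
  for (i in 1:20) {
    x <- c(runif(1, 0, 60), runif(1, 0, 3000))
    H <- hamiltonian(x, c(0, 0), params = p)
    expect_equal(as.numeric(H), 0, tolerance = 1e-12)
    expect_equal(attr(H, "Hp"), reducedDrift(x, p), tolerance = 1e-12)
  }
  # 1-D birth-death: the H = 0 momentum is log(d n / b)
  fx <- makeFixture("oneD_birth_death")
  n <- 31
  pstar <- log(fx$death * n / fx$birth)
  expect_equal(as.numeric(hamiltonian(n, pstar, channels = fx$channels)),
               0, tolerance = 1e-10)
})

test_that("minimum-action paths recover the 1-D closed form and cost
           nothing downhill", {
  fx <- makeFixture("oneD_birth_death")
  n0 <- fx$attractor
  ap <- gmamPath(n0, 35, channels = fx$channels, nImages = 64)
  expect_true(ap@converged)
  expect_equal(ap@action, fx$oracle$action(35), tolerance = 0.01)
  ap2 <- gmamPath(n0, 8, channels = fx$channels, nImages = 64)
  expect_equal(ap2@action, fx$oracle$action(8), tolerance = 0.01)
  # endpoints downstream of the flow cost (numerically) zero action
  down <- gmamPath(35, n0 + 0.5, channels = fx$channels, nImages = 32)
  expect_lt(down@action, 1e-4)
  # action is non-negative and accumulates monotonically
  expect_true(all(diff(ap@cumulative) > -1e-10))
  expect_lt(ap@diagnostics$Hresidual, 1e-6)
})

test_that("the stuck-together quasi-potential is anchored at the deep
           attractor with the saddle above both basins", {
  qp <- globalQuasiPotential(paramsPreset("fast"), gridSize = c(36L, 36L),
                             nFan = 8L)
  cp <- qp@criticalPoints
  st <- cp[cp$type == "stable", ]; st <- st[order(st$n), ]
  sad <- cp[cp$type == "saddle", ][1, ]
  atGrid <- function(m, n) {
    qp@S[which.min(abs(qp@mGrid - m)), which.min(abs(qp@nGrid - n))]
  }
  sOff <- atGrid(st$m[1], st$n[1])
  sOn <- atGrid(st$m[2], st$n[2])
  sSad <- atGrid(sad$m, sad$n)
  expect_equal(min(qp@S, na.rm = TRUE), 0)
  expect_lt(min(sOff, sOn), 0.15)          # one attractor sits at the floor
  expect_gt(sSad, max(sOff, sOn))          # barrier tops both basins
  # both uphill branches carry positive action and the sticking offset
  # equals the difference of the saddle barriers
  expect_gt(qp@paths$off_on@action, 0)
  expect_gt(qp@paths$on_off@action, 0)
  expect_equal(qp@shift[["onSurface"]],
               qp@shift[["saddleOff"]] - qp@shift[["saddleOn"]])
  # most of the grid is covered by the path fans
  expect_lt(sum(is.na(qp@S)) / length(qp@S), 0.5)
})
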