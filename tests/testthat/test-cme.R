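test_that("the generator conserves probability and matches the toy laws", {
  p <- kappaFamily(0.5, paramsPreset("slow"))
  g <- truncationGrid(6, 12)
  A <- buildGenerator(p, g)
  expect_lt(max(abs(Matrix::colSums(A))), 1e-12)

  # degenerate sub-model: gene pinned open, feedback off -> Poisson mRNA
  pf <- makeFixture("poisson_mrna")
  d <- suppressWarnings(steadyState(pf$params, pf$grid))
  expect_lt(totalVariation(mrnaMarginal(d), dpois(0:29, 5)), 1e-10)

  # two-state toy: stationary gene marginal equals the flip-rate balance
  ts <- makeFixture("two_state_gene")
  d2 <- suppressWarnings(steadyState(ts$params, ts$grid))
  expect_equal(unname(geneMarginal(d2)["open"]), ts$oracle$pOpen,
               tolerance = 1e-10)
})

test_that("block-elimination and direct sparse solves agree", {
  fx <- makeFixture("tiny_bistable")
  dq <- suppressWarnings(steadyState(fx$params, fx$grid, method = "qbd"))
  dl <- suppressWarnings(steadyState(fx$params, fx$grid, method = "lu"))
  expect_lt(totalVariation(jointProbability(dq), jointProbability(dl)),
            1e-12)
  expect_equal(sum(dq@P0) + sum(dq@P1), 1, tolerance = 1e-12)
  # residual of the block solution against the assembled generator
  A <- buildGenerator(fx$params, fx$grid)
  pv <- as.vector(rbind(dq@P0, dq@P1))
  expect_lt(max(abs(A %*% pv)) / max(pv), 1e-8)
})

test_that("the steady state is stable under grid enlargement", {
  fx <- makeFixture("tiny_bistable")
  d1 <- suppressWarnings(steadyState(fx$params, fx$grid))
  g2 <- truncationGrid(fx$grid@M + 4L, fx$grid@N + 30L)
  d2 <- suppressWarnings(steadyState(fx$params, g2))
  common <- jointProbability(d2)[1:fx$grid@M, 1:fx$grid@N]
  # the fixture leaves ~5e-6 mass on the n-edge, which bounds how much
  # the solution can move when the window grows
  expect_lt(totalVariation(jointProbability(d1), common), 1e-4)
})

test_that("a too-small window trips the boundary-mass check", {
  fx <- makeFixture("tiny_bistable")
  expect_warning(steadyState(fx$params, truncationGrid(16, 25)),
                 "truncation")
})

test_that("landscape is the floored negative log with matching extrema", {
  u <- landscape(matrix(0.25, 2, 2))
  expect_true(all(abs(u@U - log(4)) < 1e-12))
  # a zero entry lands exactly on the floor
  P <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  u2 <- landscape(P, floor = 1e-16)
  expect_equal(max(u2@U), -log(1e-16))
  # argmin U == argmax P on a real solution
  d <- cachedTinySolution()
  L <- landscape(d)
  expect_equal(which.max(jointProbability(d)), which.min(L@U))
})

test_that("KL divergence obeys the Gibbs inequality and the flooring
           convention", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # dominant term of KL((1,0) || (1/2,1/2)) with a 1e-16 floor is log 2
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2),
               tolerance = 1e-10)
  set.seed(42)
  for (i in 1:25) {
    p <- matrix(rexp(12), 3); p <- p / sum(p)
    q <- matrix(rexp(12), 3); q <- q / sum(q)
    expect_gte(klDivergence(p, q), 0)
  }
  expect_error(klDivergence(c(1, 0), c(1, 0, 0)), "shape")
})

test_that("first-passage solves match the closed-form death chain and the
           block solver", {
  pd <- makeFixture("pure_death")
  A <- buildGenerator(pd$params, pd$grid)
  src <- stateIndex(1L, 0L, 3L, pd$grid)
  tgt <- stateIndex(c(0L, 1L), c(0L, 0L), c(0L, 0L), pd$grid)
  tau <- meanFirstPassage(A, source = src, target = tgt)
  expect_equal(tau, 11 / 6, tolerance = 1e-10)
  expect_equal(meanFirstPassage(A, source = tgt[2], target = tgt), 0)

  # block-tridiagonal path against the generic solve on the tiny switch
  fx <- makeFixture("tiny_bistable")
  thr <- fx$threshold
  mfB <- meanFirstPassage(fx$params, "off_on", grid = fx$grid,
                          threshold = thr, start = c(0L, 0L, 0L))
  Afx <- buildGenerator(fx$params, fx$grid)
  tgtSet <- which(indexState(seq_len(nrow(Afx)), fx$grid)[, "n"] > thr)
  mfG <- meanFirstPassage(Afx, source = stateIndex(0L, 0L, 0L, fx$grid),
                          target = tgtSet)
  expect_equal(as.numeric(mfB), mfG, tolerance = 1e-8)
})
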