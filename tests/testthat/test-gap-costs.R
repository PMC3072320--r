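test_that("chainability is half-open non-overlap on both axes", {
  pred <- list(begX = 0, endX = 10, begY = 0, endY = 10)
  expect_true(isChainable(pred, list(begX = 20, endX = 30, begY = 15, endY = 25)))
  # overlap on the query axis only forbids chaining
  expect_false(isChainable(pred, list(begX = 20, endX = 30, begY = 5, endY = 15)))
  expect_false(isChainable(pred, pred))
  # abutting on either axis is allowed (zero characters between blocks)
  expect_true(isChainable(pred, list(begX = 10, endX = 20, begY = 10, endY = 20)))
})

test_that("gap distances count characters strictly between blocks", {
  pred <- list(begX = 0, endX = 10, begY = 0, endY = 10)
  expect_equal(gapDistances(pred, list(begX = 10, endX = 20, begY = 10, endY = 20)),
               list(dx = 0, dy = 0))
  expect_equal(gapDistances(pred, list(begX = 20, endX = 30, begY = 14, endY = 24)),
               list(dx = 10, dy = 4))
  expect_error(gapDistances(pred, list(begX = 5, endX = 30, begY = 15, endY = 25)),
               "non-chainable")
})

test_that("linear gap cost is the weighted sum of the distances", {
  expect_equal(gapLinear(0, 0, gapParams("linear", 2, 3)), 0)
  expect_equal(gapLinear(10, 4, gapParams("linear", 1, 1)), 14)
  expect_equal(gapLinear(10, 4, gapParams("linear", 1, 0)), 10)
})

test_that("sum-of-pair gap cost matches its closed form and semantics", {
  expect_equal(gapSop(10, 10, gapParams("sop", 5, 0)), 0)
  expect_equal(gapSop(10, 4, gapParams("sop", 1, 0.5)), 8)
  expect_equal(gapSop(0, 0, gapParams("sop", 1, 1)), 0)
  # symmetric in the two distances
  p <- gapParams("sop", 0.7, 0.9)
  expect_equal(gapSop(17, 3, p), gapSop(3, 17, p))
  # with eps = 0, cost is zero exactly when the distances match
  g <- expand.grid(dx = 0:20, dy = 0:20)
  cost <- gapSop(g$dx, g$dy, gapParams("sop", 1, 0))
  expect_equal(cost == 0, g$dx == g$dy)
})

test_that("sum-of-pair closed form equals the anonymous-block alignment oracle", {
  # cheapest alignment of two anonymous blocks: pair a characters at cost
  # eps each, gap the remaining dx + dy - 2a at cost lam each
  grid <- expand.grid(dx = 0:25, dy = 0:25)
  for (par in list(c(1, 0), c(1, 0.5), c(1, 2), c(0.5, 0.9), c(2, 1))) {
    p <- gapParams("sop", par[1], par[2])
    oracle <- mapply(fragchain:::.sopAlignmentOracle, grid$dx, grid$dy,
                     MoreArgs = list(lam = par[1], eps = par[2]))
    expect_equal(gapSop(grid$dx, grid$dy, p), unname(oracle))
  }
})

test_that("epsilon above twice lambda warns for the sum-of-pair model", {
  expect_warning(gapParams("sop", 1, 2.5), "epsilon > 2 \\* lambda")
  expect_silent(gapParams("sop", 1, 2))
  expect_silent(gapParams("linear", 1, 2.5))
})

test_that("linear priority transform selects the optimal predecessor", {
  set.seed(101)
  for (rep in 1:100) {
    p <- randomParams("linear")
    X <- 500; Y <- 400  # successor start
    m <- 30
    endX <- runif(m, 0, X); endY <- runif(m, 0, Y)
    score <- runif(m, 0, 50)
    value <- score - gapLinear(X - endX, Y - endY, p)
    prio <- priorityLinear(score, endX, endY, p)
    expect_equal(max(value), value[which.max(prio)], tolerance = 1e-9)
  }
})

test_that("octant priority transforms select the optimal sop predecessor", {
  set.seed(202)
  for (rep in 1:100) {
    p <- randomParams("sop")
    X <- 500; Y <- 400
    m <- 30
    endX <- runif(m, 0, X); endY <- runif(m, 0, Y)
    score <- runif(m, 0, 50)
    value <- score - gapSop(X - endX, Y - endY, p)
    oct1 <- (X - endX) >= (Y - endY)
    best <- -Inf
    if (any(oct1)) {
      prio <- prioritySop(score[oct1], endX[oct1], endY[oct1], p, 1)
      best <- max(best, value[oct1][which.max(prio)])
    }
    if (any(!oct1)) {
      prio <- prioritySop(score[!oct1], endX[!oct1], endY[!oct1], p, 2)
      best <- max(best, value[!oct1][which.max(prio)])
    }
    expect_equal(best, max(value), tolerance = 1e-9)
  }
})

test_that("both octant formulas agree on the boundary and at lam == eps", {
  p <- gapParams("sop", 1.3, 1.3)
  expect_equal(prioritySop(10, 7, 4, p, 1), 10 + 1.3 * 7)
  expect_equal(prioritySop(10, 7, 4, p, 2), 10 + 1.3 * 4)
  # on the octant boundary dx == dy both transforms give the same value
  p2 <- gapParams("sop", 1, 0.4)
  X <- 100; Y <- 80; endX <- 60; endY <- 40  # dx == dy == 40
  v <- 12 - gapSop(X - endX, Y - endY, p2)
  expect_equal(prioritySop(12, endX, endY, p2, 1) - p2@lambda * X + (p2@lambda - p2@epsilon) * Y, v)
  expect_equal(prioritySop(12, endX, endY, p2, 2) + (p2@lambda - p2@epsilon) * X - p2@lambda * Y, v)
})
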