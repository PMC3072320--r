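bothModels <- list(linear = gapParams("linear", 1, 1),
                   sop = gapParams("sop", 1, 0.5))

test_that("single fragments and zero-gap colinear runs chain additively", {
  for (p in bothModels) {
    one <- frags(c(0, 10, 0, 10, 5))
    rec <- sweepChain(one, p)
    expect_equal(rec$score, 5)
    expect_true(is.na(rec$pred))

    three <- frags(c(0, 10, 0, 10, 3), c(10, 20, 10, 20, 4), c(20, 30, 20, 30, 5))
    rec <- sweepChain(three, p)
    expect_equal(rec$score[3], 12)
    cs <- reportChains(rec, three, minScore = 0)
    expect_equal(chains(cs)$chainScore[1], 12)
    expect_equal(chainMembers(cs)[[1]], 0:2)
  }
})

test_that("fragments overlapping on the query are never chained", {
  # f1 and f3 overlap on y; f2 is chainable after f1
  f <- frags(c(0, 10, 0, 10, 5),      # f1
             c(12, 20, 12, 20, 5),    # f2, after f1 on both axes
             c(30, 40, 5, 15, 5))     # f3, overlaps f1 on y only
  for (p in bothModels) {
    rec <- sweepChain(f, p)
    expect_false(isTRUE(rec$pred[3] == 1L))
    expect_equal(rec$score[2], 10 - gapCost(2, 2, p))
  }
})

test_that("half-open abutment chains; one shared base does not", {
  for (p in bothModels) {
    abut <- frags(c(0, 10, 0, 10, 5), c(10, 20, 10, 20, 7))
    rec <- sweepChain(abut, p)
    expect_equal(rec$pred[2], 1L)
    expect_equal(rec$score[2], 12)   # gap (0,0) costs nothing

    olap <- frags(c(0, 10, 0, 10, 5), c(9, 20, 10, 20, 7))
    rec <- sweepChain(olap, p)
    expect_true(is.na(rec$pred[2]))
    expect_equal(rec$score[2], 7)
  }
})

test_that("the connect decision is pred_score - gap >= 0, ties connect", {
  expect_true(connectDecision(0))
  expect_false(connectDecision(-1e-9))
  # pred score 10, gap exactly 10: connection made, score unchanged
  p <- gapParams("linear", 1, 0)
  f <- frags(c(0, 10, 0, 10, 10), c(20, 30, 11, 21, 6))
  rec <- sweepChain(f, p)
  expect_equal(rec$pred[2], 1L)
  expect_equal(rec$score[2], 6)
  # gap 11 > 10: start fresh
  f2 <- frags(c(0, 10, 0, 10, 10), c(21, 30, 11, 21, 6))
  rec2 <- sweepChain(f2, p)
  expect_true(is.na(rec2$pred[2]))
})

test_that("reporting groups by first fragment and keeps the group maximum", {
  # A -> B and A -> C share first fragment A; only the best is reported
  f <- frags(c(0, 10, 0, 10, 5),
             c(12, 22, 12, 22, 3),
             c(12, 22, 13, 23, 8))
  p <- gapParams("sop", 1, 0)
  rec <- sweepChain(f, p)
  expect_equal(rec$first, c(1L, 1L, 1L))
  cs <- reportChains(rec, f)
  expect_equal(length(cs), 1L)
  expect_equal(chains(cs)$chainScore, max(rec$score))
  # an interior fragment heads no report
  expect_false(any(vapply(chainMembers(cs), function(m) m[1], 0L) == 1L))

  # minimum score filter drops low chains
  expect_equal(length(reportChains(rec, f, minScore = 1e6)), 0L)
})

test_that("sweep equals the quadratic oracle on random instances", {
  set.seed(1234)
  for (model in c("linear", "sop")) {
    for (rep in 1:60) {
      n <- sample(5:60, 1)
      fs <- randomInstance(n)
      p <- randomParams(model)
      swp <- sweepChain(fs, p)
      orc <- bruteForceChain(fs, p)
      expect_equal(swp$score, orc$score, tolerance = 1e-9)
      # local chaining lower bound
      expect_true(all(swp$score >= fragments(fs)$score - 1e-12))
      # reported chains match by score
      expect_equal(sort(chains(reportChains(swp, fs))$chainScore),
                   sort(chains(reportChains(orc, fs))$chainScore),
                   tolerance = 1e-9)
    }
  }
})

test_that("reported chains are recomputable and strictly colinear", {
  set.seed(77)
  for (model in c("linear", "sop")) {
    fs <- randomInstance(80)
    p <- randomParams(model)
    cs <- reportChains(sweepChain(fs, p), fs)
    df <- fragments(fs)
    for (k in seq_len(length(cs))) {
      m <- chainMembers(cs)[[k]]
      expect_equal(scoreChain(fs, m, p), chains(cs)$chainScore[k],
                   tolerance = 1e-9)
      ix <- match(m, df$uid)
      if (length(ix) > 1) {
        expect_true(all(diff(df$begX[ix]) > 0) && all(diff(df$endX[ix]) > 0))
        expect_true(all(diff(df$begY[ix]) > 0) && all(diff(df$endY[ix]) > 0))
        expect_true(all(df$endX[ix][-length(ix)] <= df$begX[ix][-1]))
        expect_true(all(df$endY[ix][-length(ix)] <= df$begY[ix][-1]))
      }
    }
  }
})

test_that("both sum-of-pair octant structures are load-bearing", {
  set.seed(555)
  p <- gapParams("sop", 1, 0.5)
  worse1 <- FALSE; worse2 <- FALSE
  for (rep in 1:40) {
    fs <- randomInstance(40)
    full <- sweepChain(fs, p)$score
    no1 <- sweepChain(fs, p, octants = 2L)$score
    no2 <- sweepChain(fs, p, octants = 1L)$score
    expect_true(all(no1 <= full + 1e-9) && all(no2 <= full + 1e-9))
    if (any(no1 < full - 1e-9)) worse1 <- TRUE
    if (any(no2 < full - 1e-9)) worse2 <- TRUE
  }
  expect_true(worse1)   # removing octant 1 loses some optimal predecessor
  expect_true(worse2)   # removing octant 2 likewise
})

test_that("empty and non-chainable inputs give singleton records", {
  p <- gapParams("linear", 1, 1)
  expect_equal(nrow(sweepChain(fragmentSet(fragchain:::.emptyFragDf()), p)), 0L)
  expect_equal(nrow(bruteForceChain(fragmentSet(fragchain:::.emptyFragDf()), p)), 0L)
  two <- frags(c(0, 10, 20, 30, 5), c(5, 15, 0, 10, 7))  # cross on y
  rec <- bruteForceChain(two, p)
  expect_true(all(is.na(rec$pred)))
  expect_equal(rec$score, c(5, 7))
})
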