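test_that("identity needs zero inversions", {
  p <- newPermutation(0:5, 2L)
  r <- minInversionScenarios(p)
  expect_equal(r$dMin, 0L)
  expect_length(r$scenarios, 1L)
  expect_equal(nrow(r$scenarios[[1]]), 0L)
})

test_that("a single displaced block is one paracentric inversion", {
  ## centromere after all markers: any interval is paracentric
  p <- newPermutation(c(0L, 2L, 1L, 3L), 4L)
  r <- minInversionScenarios(p)
  expect_equal(r$dMin, 1L)
  expect_length(r$scenarios, 1L)
  sc <- r$scenarios[[1]]
  expect_equal(sc$start, 1L)
  expect_equal(sc$end, 3L)
  expect_equal(sc$classification, "PaI")
})

test_that("markers mirrored across the centromere are one pericentric", {
  ## reference ..m1 m2 | m3.. observed ..m1 | m3 m2.. : the block (m2, CEN)
  ## reversed; one step whose interval spans the token
  p <- newPermutation(c(0L, 2L, 1L, 3L), 3L, refCentromereSlot = 1L)
  r <- minInversionScenarios(p)
  expect_equal(r$dMin, 1L)
  expect_equal(r$scenarios[[1]]$classification, "PeI")
  expect_true(all(vapply(r$scenarios, function(sc)
    identical(applyScenario(p, sc), observedSeq(p)), TRUE)))
})

test_that("two breakpoint-disjoint reversals need exactly two steps", {
  s <- 0:7
  s[2:3] <- s[3:2]  # markers 1,2
  s[6:7] <- s[7:6]  # markers 5,6
  p <- newPermutation(s, 8L)
  expect_equal(countBreakpoints(p), 4L)
  r <- minInversionScenarios(p)
  expect_equal(r$dMin, 2L)
  ## disjoint reversals commute: both orderings are minimal scenarios
  expect_length(r$scenarios, 2L)
  keys <- scenarioSetKeys(r$scenarios)
  expect_equal(keys[1], "001,003,PaI;005,007,PaI")
})

test_that("scenarios are canonically ordered and reproduce the map", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:8, 1L)
    p <- randomPermutation(n)
    r <- minInversionScenarios(p, maxDepth = 3L)
    if (is.infinite(r$dMin)) {
      expect_length(r$scenarios, 0L)
      next
    }
    keys <- vapply(r$scenarios, function(sc)
      paste(sprintf("%03d,%03d", sc$start, sc$end), collapse = ";"), "")
    expect_false(is.unsorted(keys))
    for (sc in r$scenarios)
      expect_identical(applyScenario(p, sc), observedSeq(p))
    expect_gte(r$dMin, ceiling(countBreakpoints(p) / 2))
  }
})

test_that("reversing the same interval twice is the identity", {
  set.seed(5)
  for (rep in 1:20) {
    state <- append(sample(0:6), -1L, after = sample(0:7, 1L))
    a <- sample(0:(length(state) - 2L), 1L)
    bChoices <- (a + 2L):length(state)
    b <- bChoices[sample.int(length(bChoices), 1L)]
    expect_identical(applyReversal(applyReversal(state, a, b), a, b),
                     state)
  }
})

test_that("classification is by token containment", {
  expect_equal(classifyInversion(c(1, 4), 2), "PeI")
  expect_equal(classifyInversion(c(1, 4), 4), "PaI")
  expect_equal(classifyInversion(c(3, 5), 0), "PaI")
})

test_that("depth-capped searches report Inf with no scenarios", {
  ## distance 3 permutation searched at depth 2
  p <- newPermutation(c(2L, 0L, 4L, 1L, 3L, 5L), 6L)
  full <- minInversionScenarios(p, maxDepth = 4L)
  expect_true(is.finite(full$dMin))
  if (full$dMin > 2L) {
    capped <- minInversionScenarios(p, maxDepth = full$dMin - 1L)
    expect_identical(capped$dMin, Inf)
    expect_length(capped$scenarios, 0L)
  }
})

test_that("search agrees with the independent oracle on random cases", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(4:6, 1L)
    p <- randomPermutation(n)
    depth <- if (n <= 5L) 4L else 3L
    mine <- minInversionScenarios(p, maxDepth = depth)
    theirs <- oracleMinScenarios(p, maxDepth = depth)
    expect_identical(mine$dMin, theirs$dMin)
    expect_identical(scenarioSetKeys(mine$scenarios),
                     scenarioSetKeys(theirs$scenarios))
  }
})
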