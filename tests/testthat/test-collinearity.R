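test_that("a collinear chromosome yields the identity permutation", {
  ref <- tinyReference()
  man <- tinyManifest(ref)
  cm <- mapFromOrder("7H", probeOrder(ref), centromereSlot(ref))
  p <- buildPermutation(cm, ref, man)
  expect_equal(permSequence(p), 0:6)
  expect_equal(centromereSlot(p), 3L)
  expect_equal(nrow(foreignRuns(p)), 0L)
  expect_length(missingProbes(p), 0L)
  expect_equal(countBreakpoints(p), 0L)
})

test_that("a terminal foreign run is isolated with its source group/arm", {
  ## a 3H short arm carrying a distal segment from the 4H long arm
  ref3 <- ReferenceOrder(3L, sprintf("3H%02d", 1:6), 3L)
  ref4 <- ReferenceOrder(4L, sprintf("4H%02d", 1:6), 3L)
  man <- manifestFromReference(list(`3` = ref3, `4` = ref4))
  cm <- mapFromOrder("3H", c("4H05", "4H06", probeOrder(ref3)), 5L)
  p <- buildPermutation(cm, ref3, man)
  fr <- foreignRuns(p)
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$sourceGroup, 4L)
  expect_equal(fr$sourceArm, "L")
  expect_true(fr$terminal)
  expect_equal(fr$probes, "4H05,4H06")
  expect_equal(permSequence(p), 0:5)
})

test_that("missing probes shrink and densely re-rank the reference", {
  ref <- tinyReference()
  man <- tinyManifest(ref)
  probes <- probeOrder(ref)[-4]  # drop a mid-reference probe
  cm <- mapFromOrder("7H", probes, 3L)
  p <- buildPermutation(cm, ref, man)
  expect_equal(missingProbes(p), probeOrder(ref)[4])
  expect_equal(permSequence(p), 0:5)
  expect_equal(p@refSlots, c(0:2, 4:6))
})

test_that("second copies of a probe are routed to extras", {
  ref <- tinyReference()
  man <- tinyManifest(ref)
  probes <- c(probeOrder(ref), "7H02")
  cm <- mapFromOrder("7H", probes, 3L, copy = c(rep(1L, 7L), 2L))
  p <- buildPermutation(cm, ref, man)
  expect_equal(permSequence(p), 0:6)
  expect_equal(extraSites(p)$probe, "7H02")
})

test_that("unknown probes raise an error", {
  ref <- tinyReference()
  man <- tinyManifest(ref)
  cm <- mapFromOrder("7H", c(probeOrder(ref), "9X99"), 3L)
  expect_error(buildPermutation(cm, ref, man), "unknown probe")
})

test_that("breakpoint counts match direct enumeration on known cases", {
  expect_equal(countBreakpoints(0:6), 0L)
  expect_equal(countBreakpoints(c(0L, 2L, 1L, 3L)), 2L)
  ## full reversal: no internal breakpoints, both sentinels broken
  expect_equal(countBreakpoints(c(3L, 2L, 1L, 0L)), 2L)
  expect_error(countBreakpoints(integer()), "empty")
})

test_that("breakpoints are invariant under reversal + index complement", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:10, 1L)
    s <- sample(0:(n - 1L))
    mirrored <- rev((n - 1L) - s)
    expect_equal(countBreakpoints(s), countBreakpoints(mirrored))
  }
})

test_that("one good reversal adds exactly two breakpoints to identity", {
  set.seed(11)
  ref <- simReference(groups = 5L, markersPerGroup = 9L)[["5"]]
  for (rep in 1:40) {
    evs <- sampleDisjointInversions(ref, "5H", 1L)
    sim <- simulateKaryotype(stats::setNames(list(ref), "5"),
                             "H_bogdanii", "x", evs)
    p <- buildPermutation(getChromosome(sim$karyotype, "5H"), ref,
                          manifestFromReference(list(`5` = ref)))
    expect_equal(countBreakpoints(p), 2L)
  }
})

test_that("buildPermutation is idempotent and total on packaged demos", {
  ref <- crReference()
  man <- crProbeManifest()
  for (m in c("DY", "Hbog")) {
    k <- demoKaryotype(m)$karyotype
    for (cid in chromIds(k)) {
      cm <- getChromosome(k, cid)
      p1 <- buildPermutation(cm, ref[[as.character(cm@group)]], man)
      p2 <- buildPermutation(cm, ref[[as.character(cm@group)]], man)
      expect_identical(p1, p2)
    }
  }
})
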