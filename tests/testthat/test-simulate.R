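test_that("simulation is deterministic and zero events give identity", {
  ref <- simReference(groups = 1:3, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  s1 <- simulateKaryotype(ref, "E_sibiricus", "x", list())
  s2 <- simulateKaryotype(ref, "E_sibiricus", "x", list())
  expect_identical(s1, s2)
  expect_equal(length(chromIds(s1$karyotype)), 6L)  # St + H over 3 groups
  for (cid in chromIds(s1$karyotype)) {
    cm <- getChromosome(s1$karyotype, cid)
    p <- buildPermutation(cm, ref[[as.character(cm@group)]], man)
    expect_equal(permSequence(p), 0:7)
  }
})

test_that("an explicit pericentric inversion lands across the centromere", {
  ref <- simReference(groups = 2L, markersPerGroup = 8L)  # cen slot 3
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x", list(
    list(type = "PeI", chrom = "2H", start = 2L, end = 5L)))
  cm <- getChromosome(sim$karyotype, "2H")
  ## markers 2 and 3 swap across the centromere, in mirrored order
  expect_equal(markerSites(cm)$probe,
               c("g2m01", "g2m02", "g2m04", "g2m03", "g2m05", "g2m06",
                 "g2m07", "g2m08"))
  expect_equal(sum(markerSites(cm)$arm == "S"), 3L)
  inf <- inferEvents(sim$karyotype, ref, man)
  expect_length(inf$events, 1L)
  expect_equal(eventType(inf$events[[1]]), "PeI")
})

test_that("declared inversion class must match token containment", {
  ref <- simReference(groups = 2L, markersPerGroup = 8L)
  expect_error(simulateKaryotype(ref, "H_bogdanii", "x", list(
    list(type = "PaI", chrom = "2H", start = 2L, end = 5L))),
    "pericentric")
  expect_error(simulateKaryotype(ref, "H_bogdanii", "x", list(
    list(type = "PeI", chrom = "2H", start = 0L, end = 2L))),
    "paracentric")
  expect_error(simulateKaryotype(ref, "H_bogdanii", "x", list(
    list(type = "PeI", chrom = "2H", start = 5L, end = 20L))),
    "out of range")
})

test_that("breakpoint-disjoint replicates recover d_min = k exactly", {
  ref <- simReference(groups = 4L, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  set.seed(1234)
  for (rep in 1:30) {
    k <- sample(1:3, 1L)
    evs <- sampleDisjointInversions(ref[["4"]], "4H", k)
    if (is.null(evs)) next
    sim <- simulateKaryotype(ref, "H_bogdanii", "x", evs)
    p <- buildPermutation(getChromosome(sim$karyotype, "4H"),
                         ref[["4"]], man)
    expect_equal(countBreakpoints(p), 2L * k)
    res <- minInversionScenarios(p)
    expect_equal(res$dMin, k)
    truth <- data.frame(
      start = vapply(evs, function(e) e$start, 1L),
      end = vapply(evs, function(e) e$end, 1L),
      classification = vapply(evs, function(e) e$type, ""),
      stringsAsFactors = FALSE)
    keys <- scenarioSetKeys(res$scenarios)
    expect_true(scenarioKey(truth) %in% keys)
    for (sc in res$scenarios)
      expect_identical(applyScenario(p, sc), observedSeq(p))
  }
})

test_that("simulated pattern matrices are seed-reproducible", {
  a <- simulatePatternMatrix(7L, paste0("m", 1:4), c("1H", "2H", "3H"),
                             4L, 2L)
  b <- simulatePatternMatrix(7L, paste0("m", 1:4), c("1H", "2H", "3H"),
                             4L, 2L)
  expect_identical(a, b)
  expect_equal(sum(a$matrix@primed), 2L)
})

test_that("simulated karyotypes survive a TSV round trip", {
  ref <- simReference(groups = c(1L, 5L), markersPerGroup = 9L)
  sim <- simulateKaryotype(ref, "E_nutans", "n1", list(
    list(type = "PaI", chrom = "5Y", start = 5L, end = 8L),
    list(type = "De", chrom = "1St", probe = "g1m05")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeKaryotype(sim$karyotype, tmp)
  back <- readKaryotype(tmp)
  expect_equal(chromIds(back), chromIds(sim$karyotype))
  expect_equal(markerSites(getChromosome(back, "5Y")),
               markerSites(getChromosome(sim$karyotype, "5Y")))
})
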