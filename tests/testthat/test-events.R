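refPair <- function() simReference(groups = c(4L, 6L), markersPerGroup = 8L)

test_that("a reciprocal head swap is one RT event, never two T events", {
  ref <- refPair()
  man <- manifestFromReference(ref)
  for (lens in list(c(1L, 1L), c(2L, 1L), c(3L, 2L))) {
    sim <- simulateKaryotype(ref, "H_bogdanii", "x",
                             list(list(type = "RT",
                                       chroms = c("4H", "6H"),
                                       len = lens)))
    evs <- detectTranslocations(sim$karyotype, ref, man)
    expect_length(evs, 1L)
    expect_equal(eventType(evs[[1]]), "RT")
    expect_equal(eventChroms(evs[[1]]), c("4H", "6H"))
  }
})

test_that("an unreciprocated terminal run is a one-way translocation", {
  ref <- refPair()
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x",
                           list(list(type = "T", from = "4H", to = "6H",
                                     len = 1L, fromEnd = "tail")))
  evs <- detectTranslocations(sim$karyotype, ref, man)
  expect_length(evs, 1L)
  expect_equal(eventType(evs[[1]]), "T")
  expect_equal(eventChroms(evs[[1]]), c("4H", "6H"))
})

test_that("karyotypes without foreign runs yield no translocations", {
  ref <- refPair()
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x", list())
  expect_length(detectTranslocations(sim$karyotype, ref, man), 0L)
})

test_that("an interstitial extra copy on another chromosome is a Du", {
  ref <- simReference(groups = 1:2, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  ## a group-2 probe inserted interstitially on 1H while 2H keeps its own
  sim <- simulateKaryotype(ref, "H_bogdanii", "x",
                           list(list(type = "Du", probe = "g2m06",
                                     chrom = "1H", at = 6L)))
  evs <- detectCopyNumber(sim$karyotype, ref, man)
  expect_length(evs, 1L)
  expect_equal(eventType(evs[[1]]), "Du")
  expect_equal(eventChroms(evs[[1]]), "1H")
  expect_equal(evs[[1]]@probes, "g2m06")
  ## and it must not be mistaken for a translocation
  expect_length(detectTranslocations(sim$karyotype, ref, man), 0L)
})

test_that("a deleted probe with both neighbours present is a De", {
  ref <- simReference(groups = 1L, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x",
                           list(list(type = "De", chrom = "1H",
                                     probe = "g1m06")))
  evs <- detectCopyNumber(sim$karyotype, ref, man)
  expect_length(evs, 1L)
  expect_equal(eventType(evs[[1]]), "De")
  expect_equal(evs[[1]]@probes, "g1m06")
})

test_that("a truncated distal map is not called a deletion", {
  ref <- simReference(groups = 1L, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x",
                           list(list(type = "De", chrom = "1H",
                                     probe = "g1m08"),
                                list(type = "De", chrom = "1H",
                                     probe = "g1m07")))
  ## both distal long-arm probes gone: neither has an intact two-neighbour
  ## reference context, so the truncation produces no deletion calls
  evs <- detectCopyNumber(sim$karyotype, ref, man)
  expect_length(evs, 0L)
})

test_that("complete karyotypes yield no copy-number events", {
  ref <- refPair()
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x", list())
  expect_length(detectCopyNumber(sim$karyotype, ref, man), 0L)
})

test_that("inferEvents recovers a simulated PeI + RT ground truth", {
  ref <- refPair()
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "H_bogdanii", "x", list(
    list(type = "PeI", chrom = "4H", start = 2L, end = 5L),
    list(type = "RT", chroms = c("4H", "6H"), len = c(1L, 1L))))
  inf <- inferEvents(sim$karyotype, ref, man)
  types <- vapply(inf$events, eventType, "")
  expect_setequal(types, c("PeI", "RT"))
  pei <- inf$events[[which(types == "PeI")]]
  expect_equal(eventChroms(pei), "4H")
  ## markers 2 and 3 cross the centromere: reference slots [2, 4) after
  ## excising the translocated terminal marker shifts nothing interior
  expect_equal(refInterval(pei), c(2L, 4L))
})

test_that("a fully collinear karyotype yields no events at all", {
  ref <- simReference(groups = 1:7, markersPerGroup = 8L)
  man <- manifestFromReference(ref)
  sim <- simulateKaryotype(ref, "E_sibiricus", "x", list())
  inf <- inferEvents(sim$karyotype, ref, man)
  expect_length(inf$events, 0L)
  expect_true(all(vapply(inf$scenarios, function(s) s$dMin, 1) == 0))
})

test_that("prose-derived demos flag the narrated translocations", {
  ref <- crReference()
  man <- crProbeManifest()
  dy <- demoKaryotype("DY")
  infDY <- inferEvents(dy$karyotype, ref, man)
  labels <- vapply(infDY$events, eventLabel, "")
  expect_true("RT (4H/6H)" %in% labels)
  ## inversions recovered on each narrated chromosome
  invChrom <- vapply(infDY$events, function(e) e@chroms[1L], "")
  inv <- invChrom[vapply(infDY$events, eventType, "") %in% c("PeI", "PaI")]
  expect_setequal(unique(inv), c("1H", "2H", "3H", "4H", "6H",
                                 "2St", "4St", "5St"))

  hb <- demoKaryotype("Hbog")
  infHb <- inferEvents(hb$karyotype, ref, man)
  labels <- vapply(infHb$events, eventLabel, "")
  expect_true("T (4H->3H)" %in% labels)
  expect_true(any(grepl("^De ", labels)))
})

test_that("every returned scenario reproduces its observed chromosome", {
  ref <- crReference()
  man <- crProbeManifest()
  k <- demoKaryotype("DY")$karyotype
  for (cid in chromIds(k)) {
    cm <- getChromosome(k, cid)
    p <- buildPermutation(cm, ref[[as.character(cm@group)]], man)
    p@foreignRuns <- data.frame()
    res <- minInversionScenarios(p)
    expect_true(is.finite(res$dMin))
    for (sc in res$scenarios)
      expect_identical(applyScenario(p, sc), observedSeq(p))
  }
})
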