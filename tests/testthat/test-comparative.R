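toyMatrix <- function(events, materials, species, presence) {
  new("EventMatrix",
      events = events, materials = materials, species = species,
      presence = presence,
      annotation = matrix("", nrow(events), length(materials)))
}

test_that("inversion series collapse and RT partner rows merge", {
  em <- crEventSurvey()
  cx <- buildComplexes(em)
  ## a material with 1H PeI I and PeI II present -> one series, two members
  expect_true("1H:PeI I+PeI II" %in% cx$PJC$signature)
  expect_false(any(grepl("^1H:PeI I$", cx$PJC$signature)))
  ## RT (4H/6H) on both 4H and 6H rows -> a single complex in DY
  expect_equal(sum(cx$DY$signature == "RT (4H/6H)"), 1L)
  ## a material with no events has an empty complex set
  ev <- data.frame(chrom = "1H", label = "PeI I", type = "PeI",
                   stringsAsFactors = FALSE)
  toy <- toyMatrix(ev, c("a", "b"), c("E_sibiricus", "E_sibiricus"),
                   matrix(c(TRUE, FALSE), 1L))
  expect_equal(nrow(buildComplexes(toy)$b), 0L)
})

test_that("an RT label on a single chromosome row warns and is kept as T", {
  ev <- data.frame(chrom = "4H", label = "RT (4H/6H)", type = "RT",
                   stringsAsFactors = FALSE)
  toy <- toyMatrix(ev, "a", "E_sibiricus", matrix(TRUE, 1L, 1L))
  expect_warning(cx <- buildComplexes(toy), "treated as T")
  expect_equal(cx$a$kind, "translocation")
})

test_that("specificity calls reproduce the survey's headline examples", {
  em <- crEventSurvey()
  calls <- classifySpecificity(buildComplexes(em), speciesOf(em))
  rt46 <- calls[calls$signature == "RT (4H/6H)", ]
  expect_equal(rt46$call[rt46$species == "E_sibiricus"],
               "species_specific")
  expect_false("E_nutans" %in% rt46$species)  # absent from E. nutans
  du3 <- calls[calls$signature == "3St Du (3H448)" &
                 calls$species == "E_nutans", ]
  expect_equal(du3$call, "polymorphic")  # 3 of 4 materials
  ## non-uniform inversion series are excluded from species-specific sets
  expect_false(any(calls$call == "species_specific" &
                     grepl("^4H:", calls$signature)))
  expect_false(any(calls$call == "species_specific" &
                     grepl("^5Y:", calls$signature)))
})

test_that("uniform events in both species classify as uniform_shared", {
  ev <- data.frame(chrom = c("1H", "2H"), label = c("PeI I", "PeI I"),
                   type = c("PeI", "PeI"), stringsAsFactors = FALSE)
  toy <- toyMatrix(ev, c("s1", "s2", "n1", "n2"),
                   c("E_sibiricus", "E_sibiricus", "E_nutans", "E_nutans"),
                   matrix(c(TRUE, TRUE, TRUE, TRUE,
                            TRUE, TRUE, FALSE, FALSE), 2L, byrow = TRUE))
  calls <- classifySpecificity(buildComplexes(toy),
                               stats::setNames(c("E_sibiricus",
                                                 "E_sibiricus", "E_nutans",
                                                 "E_nutans"),
                                               c("s1", "s2", "n1", "n2")))
  expect_equal(calls$call[calls$signature == "1H:PeI I"],
               c("uniform_shared", "uniform_shared"))
  expect_equal(calls$call[calls$signature == "2H:PeI I" &
                            calls$species == "E_sibiricus"],
               "species_specific")
})

test_that("a single-species matrix makes every uniform event specific", {
  ev <- data.frame(chrom = c("1H", "3H"), label = c("PeI I", "PeI"),
                   type = c("PeI", "PeI"), stringsAsFactors = FALSE)
  toy <- toyMatrix(ev, "only", "E_sibiricus", matrix(TRUE, 2L, 1L))
  calls <- classifySpecificity(buildComplexes(toy),
                               c(only = "E_sibiricus"))
  expect_equal(countSpeciesSpecific(calls, "E_sibiricus"), 2L)
  expect_equal(countPolymorphicTypes(toy, "E_sibiricus"), 0L)
})

test_that("specificity calls are invariant to material and row order", {
  em <- crEventSurvey()
  base <- classifySpecificity(buildComplexes(em), speciesOf(em))
  set.seed(3)
  jm <- sample(length(em@materials))
  jr <- sample(nrow(em@events))
  shuffled <- new("EventMatrix", events = em@events[jr, ],
                  materials = em@materials[jm], species = em@species[jm],
                  presence = em@presence[jr, jm, drop = FALSE],
                  annotation = em@annotation[jr, jm, drop = FALSE])
  perm <- classifySpecificity(buildComplexes(shuffled),
                              speciesOf(shuffled))
  ord <- function(x) x[order(x$signature, x$species), ]
  expect_equal(ord(perm), ord(base), ignore_attr = TRUE)
})

test_that("breakpoint reuse tallies endpoints with complex dedup", {
  ref <- stats::setNames(list(ReferenceOrder(4L, paste0("p", 1:5), 2L)),
                         "4")
  ev <- data.frame(
    material = c("a", "b", "b"),
    species = c("E_sibiricus", "E_sibiricus", "E_nutans"),
    chrom = c("4H", "4H", "4St"),
    label = c("PeI I", "PeI I", "PaI I"),
    ref_start = c(1L, 1L, 1L), ref_end = c(3L, 3L, 4L),
    stringsAsFactors = FALSE)
  out <- breakpointReuse(ev, ref)
  ## rows 1-2 are the same shared sibiricus complex -> dedup to one;
  ## the nutans complex shares the p1|p2 endpoint -> that locus counts 2
  expect_equal(out$count[out$locus == "p1|p2"], 2L)
  expect_true(out$reused[out$locus == "p1|p2"])
  ## conservation: locus counts sum to 2 endpoints per distinct complex
  expect_equal(sum(out$count), 2L * 2L)
  ## all-distinct endpoints -> all counts 1
  ev2 <- ev[c(1, 3), ]
  ev2$ref_start <- c(0L, 1L)
  ev2$ref_end <- c(2L, 4L)
  out2 <- breakpointReuse(ev2, ref)
  expect_true(all(out2$count == 1L))
})

test_that("the group-4 demonstration names the narrated reused locus", {
  out <- breakpointReuse(crGroup4Demo(), crReference())
  top <- out[1L, ]
  expect_equal(top$locus, "4H138|4H289")
  expect_equal(top$count, 4L)
  expect_true(all(out$count[-1L] < 4L))
})

test_that("centromere-flank loci are distinguished by cut side", {
  ref <- stats::setNames(list(ReferenceOrder(1L, paste0("q", 1:4), 2L)),
                         "1")
  ev <- data.frame(material = c("a", "b"),
                   species = c("E_sibiricus", "E_nutans"),
                   chrom = c("1H", "1H"), label = c("PaI I", "PaI II"),
                   ref_start = c(2L, 0L), ref_end = c(4L, 2L),
                   stringsAsFactors = FALSE)
  out <- breakpointReuse(ev, ref)
  ## one interval starts at the centromere slot (cut on its long-arm side),
  ## the other ends there (cut on its short-arm side): different loci
  expect_true("CEN|q3" %in% out$locus)
  expect_true("q2|CEN" %in% out$locus)
  expect_true(all(out$count == 1L))
})
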