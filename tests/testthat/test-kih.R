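# Knobs-into-holes detection, classification, registers and symmetry.

test_that("the knob cutoff is inclusive at exactly 7.4 A", {
  atBoundary <- syntheticKnobModel(d4 = 7.4)
  k <- findKnobs(atBoundary$model, atBoundary$helices)
  k <- k[k$chain == "K", ]
  expect_equal(nrow(k), 1)
  expect_equal(k$resno, 4)
  expect_equal(sort(c(k$hole1, k$hole2, k$hole3, k$hole4)), c(1, 4, 5, 8))
  expect_equal(k$d4, 7.4, tolerance = 1e-12)
  beyond <- syntheticKnobModel(d4 = 7.41)
  k2 <- findKnobs(beyond$model, beyond$helices)
  expect_equal(nrow(k2[k2$chain == "K", ]), 0)
})

test_that("packing classification has inclusive 45/135 boundaries", {
  expect_equal(classifyPacking(90), "perpendicular")
  expect_equal(classifyPacking(10), "parallel")
  expect_equal(classifyPacking(45), "perpendicular")
  expect_equal(classifyPacking(135), "perpendicular")
  expect_equal(classifyPacking(44.9), "parallel")
  expect_equal(classifyPacking(135.1), "parallel")
  expect_error(classifyPacking(181))
})

test_that("packing angles are measured against the hole helix axis", {
  ca <- straightHelixCA(8)
  hole <- syntheticHelix("H", 1:8, ca, axisDir = c(0, 0, 1))
  mk <- function(cb) modelFromAtoms(
    atomRow("K", 1, "ALA", "CA", c(0, 0, 0)),
    atomRow("K", 1, "ALA", "CB", cb))
  expect_equal(packingAngle(mk(c(0, 0, 1.5)), "K", 1, hole, 4), 0,
               tolerance = 1e-9)
  expect_equal(packingAngle(mk(c(1.5, 0, 0)), "K", 1, hole, 4), 90,
               tolerance = 1e-9)
  cb30 <- 1.5 * c(sin(pi / 6), 0, cos(pi / 6))
  expect_equal(packingAngle(mk(cb30), "K", 1, hole, 4), 30, tolerance = 0.5)
  # Gly knobs have no angle
  mg <- modelFromAtoms(atomRow("K", 1, "GLY", "CA", c(0, 0, 0)))
  expect_true(is.na(packingAngle(mg, "K", 1, hole, 4)))
})

test_that("knob search matches a brute-force oracle on a pentamer barrel", {
  m <- fxBarrel(5)
  helices <- detectHelices(m)
  knobs <- findKnobs(m, helices)
  # independent brute force over all residue pairs via sideChainCenter
  at <- atomTable(m)
  bruteKnobs <- list()
  for (hi in seq_along(helices)) for (hj in seq_along(helices)) {
    if (hi == hj) next
    chI <- helices[[hi]]@chain; chJ <- helices[[hj]]@chain
    for (ri in helices[[hi]]@resno) {
      ci <- sideChainCenter(m, chI, ri, mode = "centroid")
      dists <- vapply(helices[[hj]]@resno, function(rj)
        sqrt(sum((sideChainCenter(m, chJ, rj, mode = "centroid") - ci)^2)),
        numeric(1))
      inc <- which(dists <= 7.4)
      if (length(inc) < 4) next
      hole <- sort(helices[[hj]]@resno[inc[order(dists[inc])][1:4]])
      if (identical(hole - hole[1], c(0L, 3L, 4L, 7L)))
        bruteKnobs[[length(bruteKnobs) + 1]] <-
          c(chI, ri, chJ, hole)
    }
  }
  got <- knobs[order(knobs$chain, knobs$resno, knobs$holeChain), ]
  brute <- do.call(rbind, bruteKnobs)
  brute <- brute[order(brute[, 1], as.integer(brute[, 2]), brute[, 3]), ]
  expect_equal(nrow(got), nrow(brute))
  expect_equal(got$chain, brute[, 1])
  expect_equal(got$resno, as.integer(brute[, 2]))
  expect_equal(got$holeChain, brute[, 3])
  expect_equal(got$hole1, as.integer(brute[, 4]))
  expect_equal(got$hole4, as.integer(brute[, 7]))
})

test_that("knob acceptance is monotone in the cutoff", {
  m <- fxBarrel(6)
  helices <- detectHelices(m)
  key <- function(k) paste(k$chain, k$resno, k$holeChain)
  prev <- character(0)
  for (cutoff in c(5.0, 6.5, 7.4, 8.0)) {
    cur <- key(findKnobs(m, helices, cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_length(key(findKnobs(m, helices, cutoff = 5.0)), 0)
})

test_that("graph assembly flags coiled coils and separates isolated bundles", {
  r <- fxKih(fxBarrel(6), "b6")
  expect_equal(nrow(r$assemblies), 1)
  expect_equal(r$assemblies$size, 6)
  expect_true(r$assemblies$coiledCoil)
  expect_true(all(r$knobs$reciprocal))
  # two isolated dimers -> two components of two
  d1 <- atomTable(fxBarrel(2))
  d2 <- d1
  d2$chain <- chartr("AB", "CD", d2$chain)
  d2$x <- d2$x + 100
  m2 <- new("StructureModel", atoms = rbind(d1, d2), source = "two-dimers",
            model = 1L)
  r2 <- analyzeKih(m2)
  expect_equal(r2$assemblies$size, c(2, 2))
  expect_true(all(r2$assemblies$coiledCoil))
  # the docked helix joins the arc's component
  r3 <- fxKih(fxDocked(), "docked")
  expect_equal(r3$assemblies$size, 6)
  expect_true(r3$assemblies$coiledCoil)
})

test_that("a mixed-orientation pentamer reports a mixed pattern", {
  m <- buildBarrel(crickParams(5, orientations = c(1, 1, 1, 1, -1)),
                   SEQ_ILE_CORE)
  h <- detectHelices(m)
  expect_equal(ccbarrel:::.orientationPattern(h), "mixed")
  signs <- outer(seq_along(h), seq_along(h), Vectorize(function(i, j)
    pairwiseOrientation(h[[i]], h[[j]]) == "parallel"))
  expect_equal(sum(!signs[upper.tri(signs)]), 4) # one inverted chain
})

test_that("register assignment follows the a/d-maximising rule with e/g tie-break", {
  ca <- straightHelixCA(28)
  h <- syntheticHelix("A", 1:28, ca)
  mkKnobs <- function(res) data.frame(chain = "A", resno = res,
                                      knobHelix = 1L, holeHelix = 2L)
  # canonical 3,4 spacing -> a, d, a, d
  reg <- assignRegister(h, mkKnobs(c(1, 4, 8, 11)))
  expect_equal(unname(reg[as.character(c(1, 4, 8, 11))]),
               c("a", "d", "a", "d"))
  # Type-2 offsets {0,3,4,6} -> letters a, d, e, g
  reg2 <- assignRegister(h, mkKnobs(c(1, 4, 5, 7)))
  expect_equal(unname(reg2[as.character(c(1, 4, 5, 7))]),
               c("a", "d", "e", "g"))
  # invariant under renumbering by a constant (and by +7 in particular)
  h2 <- syntheticHelix("A", 8:35, ca)
  reg3 <- assignRegister(h2, mkKnobs(c(1, 4, 8, 11) + 7))
  expect_equal(unname(reg3[as.character(c(8, 11, 15, 18))]),
               c("a", "d", "a", "d"))
  expect_null(assignRegister(h, mkKnobs(5)))
})

test_that("interface typing maps register sets to the published classes", {
  expect_equal(classifyInterface(c("a", "d")), "N")
  expect_equal(classifyInterface(c("a", "d", "e")), "1")
  expect_equal(classifyInterface(c("a", "d", "g")), "1")
  expect_equal(classifyInterface(c("a", "d", "e", "g")), "2")
  expect_equal(classifyInterface(c("a", "c", "d", "f")), "3")
  expect_equal(classifyInterface(c("a", "b", "d", "f")), "3")
  expect_equal(classifyInterface(c("b", "c")), "unclassified")
})

test_that("assembly symmetry distinguishes Cn, screw, C2 and E arrangements", {
  expect_equal(fxKih(fxBarrel(7), "b7")$symmetry@label, "Cn")
  expect_equal(fxKih(fxBarrel(7), "b7")$symmetry@rotationOrder, 7L)
  expect_equal(analyzeKih(fxSlippedHexamer())$symmetry@label, "screw")
  sheet <- fxKih(fxTwoSheet(), "twosheet")$symmetry
  expect_equal(sheet@label, "Cn")
  expect_equal(sheet@rotationOrder, 2L)
  expect_equal(sheet@orientationPattern, "mixed")
  expect_equal(fxKih(fxDocked(), "docked")$symmetry@label, "E")
})

test_that("Type-2 barrels are fully characterised across oligomer states", {
  for (n in c(5, 8)) {
    r <- fxKih(fxBarrel(n), paste0("b", n))
    expect_equal(r$knobRegisters, c("a", "d", "e", "g"))
    expect_equal(r$interfaceType, "2")
    expect_equal(r$orientationPattern, "all-parallel")
    expect_true(all(r$knobs$reciprocal))
    expect_equal(r$symmetry@rotationOrder, as.integer(n))
  }
})
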