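# Synthetic Crick-parameterised bundle generator.

test_that("heptad expansion substitutes the variable position per heptad", {
  expect_equal(buildSequence("LKEIAfA", 4, fills = c("Q", "K", "W", "Q")),
               "LKEIAQALKEIAKALKEIAWALKEIAQA")
  expect_equal(buildSequence("AAAAAAA", 1), "AAAAAAA")
  s <- buildSequence("IKEIAfA", 4, fills = c("Q", "K", "W", "Q"))
  expect_equal(nchar(s), 28)
  chars <- strsplit(s, "")[[1]]
  expect_true(all(chars[c(1, 8, 15, 22)] == "I"))  # a positions
  expect_true(all(chars[c(4, 11, 18, 25)] == "I")) # d positions
  expect_error(buildSequence("LKEIAfA", 4, fills = c("Q", "K")), "one entry per heptad")
  expect_error(buildSequence("LKEIAZA", 4), "unknown")
})

test_that("barrels have ideal consecutive CA distances and exact Cn symmetry", {
  for (n in c(5, 7)) {
    m <- fxBarrel(n)
    at <- atomTable(m)
    for (ch in chainIDs(m)) {
      ca <- as.matrix(at[at$chain == ch & at$elety == "CA", c("x", "y", "z")])
      d <- sqrt(rowSums(diff(ca)^2))
      expect_true(all(abs(d - 3.8) < 0.1))
    }
    # rotating by 360/n superposes chain k onto k+1
    R <- rotationAboutAxis(c(0, 0, 1), 360 / n)
    a1 <- as.matrix(at[at$chain == "A" & at$elety != "SCC", c("x", "y", "z")])
    a2 <- as.matrix(at[at$chain == "B" & at$elety != "SCC", c("x", "y", "z")])
    expect_lt(sqrt(mean(rowSums((a1 %*% t(R) - a2)^2))), 1e-6)
  }
  expect_error(buildBarrel(crickParams(6, r0 = 2.0), SEQ_ILE_CORE), "r0 > r1")
})

test_that("helix count equals the construction for 4-heptad bundles", {
  for (n in c(2, 6, 8))
    expect_length(detectHelices(fxBarrel(n)), n)
})

test_that("chain orientations control parallel/antiparallel geometry", {
  m <- fxBarrel(2)
  h <- detectHelices(m)
  expect_equal(pairwiseOrientation(h[[1]], h[[2]]), "parallel")
  ma <- buildBarrel(crickParams(2, orientations = c(1, -1)), SEQ_ILE_CORE)
  ha <- detectHelices(ma)
  expect_equal(pairwiseOrientation(ha[[1]], ha[[2]]), "antiparallel")
})

test_that("SCC pseudoatoms follow the centroid-distance table", {
  tab <- sccDistanceTable()
  expect_equal(unname(tab[["GLY"]]), 0)
  expect_gt(tab[["ILE"]], tab[["VAL"]])
  expect_gt(tab[["VAL"]], tab[["ALA"]])
  # Ala SCC coincides with CB, Gly SCC with CA
  m <- buildBarrel(crickParams(2), buildSequence("GAAAAAA", 2))
  at <- atomTable(m)
  r1 <- at[at$chain == "A" & at$resno == 1, ]   # Gly
  expect_equal(as.numeric(r1[r1$elety == "SCC", c("x", "y", "z")]),
               as.numeric(r1[r1$elety == "CA", c("x", "y", "z")]))
  r2 <- at[at$chain == "A" & at$resno == 2, ]   # Ala
  expect_equal(as.numeric(r2[r2$elety == "SCC", c("x", "y", "z")]),
               as.numeric(r2[r2$elety == "CB", c("x", "y", "z")]),
               tolerance = 1e-9)
  # missing CB for non-Gly is an error
  broken <- m
  broken@atoms <- at[!(at$elety %in% c("SCC", "CB")), ]
  expect_error(placeCentroids(broken), "CB")
})

test_that("uniform per-chain slips produce a screw assembly detectable by superposition", {
  m <- fxSlippedHexamer()
  at <- atomTable(m)
  a1 <- as.matrix(at[at$chain == "A" & at$elety == "CA", c("x", "y", "z")])
  a2 <- as.matrix(at[at$chain == "B" & at$elety == "CA", c("x", "y", "z")])
  sp <- superpose(a1, a2)
  expect_lt(sp$rmsd, 0.01)
  expect_equal(abs(sp$transform@screwTranslation), 1.2, tolerance = 0.01)
  expect_equal(analyzeKih(m)$symmetry@label, "screw")
})

test_that("default barrels satisfy the Cn symmetry invariant", {
  for (n in c(5, 6)) {
    sym <- fxKih(fxBarrel(n), paste0("b", n))$symmetry
    expect_equal(sym@label, "Cn")
    expect_equal(sym@rotationOrder, n)
    expect_lt(abs(sym@meanRotation - 360 / n), 0.5)
    expect_lt(abs(sym@meanScrew), 0.1)
  }
})

test_that("collapsed arrangements have the designed symmetry and closed lumens", {
  r2 <- fxKih(fxTwoSheet(), "twosheet")
  expect_equal(r2$symmetry@label, "Cn")
  expect_equal(r2$symmetry@rotationOrder, 2L)
  r3 <- fxKih(fxDocked(), "docked")
  expect_equal(r3$symmetry@label, "E")
  for (m in list(fxTwoSheet(), fxDocked())) {
    h <- detectHelices(m)
    ps <- poreSummary(poreProfile(m, barrelAxis(m, h)))
    expect_false(ps$open)
  }
  expect_error(buildCollapsed(crickParams(4), SEQ_LEU_CORE, "docked"), "5-8")
  expect_error(buildCollapsed(crickParams(6), SEQ_LEU_CORE, "sideways"))
})

test_that("register offset shifts the geometric seam by the stated amount", {
  # rotating the heptad left by 3 and starting the register at position 3
  # describes the same physical seam, so the knob positions must shift by
  # exactly three places around the heptad wheel
  rot3 <- paste(rep(paste0(substr("IAAIAAA", 4, 7), substr("IAAIAAA", 1, 3)),
                    4), collapse = "")
  m3 <- buildBarrel(crickParams(6), rot3, registerOffset = 3)
  k0 <- fxKih(fxBarrel(6), "b6")
  k3 <- analyzeKih(m3)
  expect_equal(k0$knobRegisters, c("a", "d", "e", "g"))
  off0 <- unique((k0$knobs$resno - 1) %% 7)
  off3 <- unique((k3$knobs$resno - 1 + 3) %% 7)
  expect_setequal(off3, off0)
})
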