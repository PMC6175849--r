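# Structure I/O, helix detection, axes, superposition, side-chain centers.

miniAlaPdb <- paste(
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.673   6.622  -4.105  1.00  0.00           C",
  "ATOM      4  O   ALA A   1      10.810   6.351  -2.915  1.00  0.00           O",
  "ATOM      5  CB  ALA A   1      12.008   4.626  -4.793  1.00  0.00           C",
  "END", sep = "\n")

test_that("a minimal single-residue PDB parses to 1 chain, 1 residue, 5 atoms", {
  m <- readStructure(miniAlaPdb)
  expect_s4_class(m, "StructureModel")
  expect_equal(chainIDs(m), "A")
  expect_equal(residueCount(m), 1)
  expect_equal(nrow(atomTable(m)), 5)
  expect_equal(atomTable(m)$x[2], 11.639)
})

test_that("malformed records fail naming the line; waters and hetero atoms drop", {
  bad <- sub("11.639", "xx.yyy", miniAlaPdb)
  expect_error(readStructure(bad), "line 2")
  withWater <- paste(miniAlaPdb,
    "HETATM    6  O   HOH A 101      0.000   0.000   0.000  1.00  0.00           O",
    sep = "\n")
  m <- readStructure(withWater)
  expect_equal(nrow(atomTable(m)), 5)
  expect_error(readStructure("REMARK nothing here\nEND"), "ATOM|protein")
})

test_that("alternate locations other than blank or A are discarded", {
  altB <- sub("ATOM      5  CB  ALA A", "ATOM      5  CB BALA A", miniAlaPdb)
  m <- readStructure(altB)
  expect_false("CB" %in% atomTable(m)$elety)
})

test_that("write/read round-trip preserves topology and coordinates to 1e-3 A", {
  m <- fxBarrel(6)
  lines <- writeStructure(m)
  m2 <- readStructure(lines)
  expect_equal(chainIDs(m2), chainIDs(m))
  expect_equal(residueCount(m2, perChain = TRUE), residueCount(m, perChain = TRUE))
  expect_lt(max(abs(as.matrix(atomTable(m2)[, c("x", "y", "z")]) -
                      as.matrix(atomTable(m)[, c("x", "y", "z")]))), 1e-3)
  # SCC pseudoatoms written as plain ATOM records of element C
  sccLines <- grep(" SCC ", lines, value = TRUE)
  expect_true(length(sccLines) == residueCount(m))
  expect_true(all(grepl("^ATOM", sccLines)))
  expect_true(all(atomTable(m2)$elesy[atomTable(m2)$elety == "SCC"] == "C"))
  # fixed-width column oracle: coordinates live in columns 31-54
  expect_equal(as.numeric(substr(lines[grepl("^ATOM", lines)][1], 31, 38)),
               atomTable(m)$x[1], tolerance = 1e-3)
})

test_that("writing rejects empty models and over-long atom names", {
  empty <- new("StructureModel", atoms = atomTable(fxBarrel(6))[0, ])
  expect_error(writeStructure(empty), "empty")
  m <- readStructure(miniAlaPdb)
  m@atoms$elety[5] <- "CBXYZ"
  expect_error(writeStructure(m), "4 characters")
})

test_that("helix detection flags ideal helices and rejects extended strands", {
  m <- fxBarrel(6)
  segs <- detectHelices(m)
  expect_length(segs, 6)
  expect_true(all(vapply(segs, function(s) length(s@resno), integer(1)) >= 24))
  # extended strand: CA spaced 3.8 A along a line
  ca <- cbind(3.8 * (0:19), 0, 0)
  strand <- do.call(rbind, lapply(1:20, function(i)
    atomRow("A", i, "ALA", "CA", ca[i, ])))
  expect_length(detectHelices(modelFromAtoms(strand)), 0)
})

test_that("two helices joined by a loop give two segments with criterion-true boundaries", {
  h1 <- straightHelixCA(28)
  h2 <- sweep(straightHelixCA(28), 2, c(25, 0, 0), "+")
  gapStart <- h1[28, ]
  gapEnd <- h2[1, ]
  loop <- t(sapply(1:5, function(k)
    gapStart + (gapEnd - gapStart) * k / 6))
  ca <- rbind(h1, loop, h2)
  rows <- do.call(rbind, lapply(seq_len(nrow(ca)), function(i)
    atomRow("A", i, "ALA", "CA", ca[i, ])))
  m <- modelFromAtoms(rows)
  segs <- detectHelices(m)
  expect_length(segs, 2)
  # oracle: recompute the helical flags directly from the distance criteria
  flag <- vapply(seq_len(nrow(ca) - 4), function(i) {
    d3 <- sqrt(sum((ca[i + 3, ] - ca[i, ])^2))
    d4 <- sqrt(sum((ca[i + 4, ] - ca[i, ])^2))
    d3 >= 4.5 && d3 <= 5.6 && d4 >= 5.7 && d4 <= 6.7
  }, logical(1))
  runs <- rle(flag)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- which(runs$values & runs$lengths >= 7)
  expect_equal(vapply(segs, function(s) s@resno[1], integer(1)),
               as.integer(starts[keep]))
  expect_equal(vapply(segs, function(s) s@resno[length(s@resno)], integer(1)),
               as.integer(ends[keep]))
})

test_that("local helix axis reproduces the ideal geometry and is equivariant", {
  ca <- straightHelixCA(28)
  ax <- localHelixAxis(ca)
  expect_lt(acos(min(1, abs(sum(ax$axisDir * c(0, 0, 1))))) * 180 / pi, 1)
  # all CA at the ideal helical radius from the fitted axis line
  p0 <- colMeans(ax$axisPoints)
  rel <- sweep(ca, 2, p0)
  proj <- rel - outer(as.numeric(rel %*% ax$axisDir), ax$axisDir)
  expect_true(all(abs(sqrt(rowSums(proj^2)) - 2.26) < 0.05))
  # equivariance under a known rotation
  R <- rotationAboutAxis(c(1, 2, 2), 73)
  ax2 <- localHelixAxis(ca %*% t(R))
  expect_lt(acos(min(1, sum(ax2$axisDir * as.numeric(R %*% ax$axisDir)))) *
              180 / pi, 1)
  expect_error(localHelixAxis(ca[1:5, ]), "at least")
})

test_that("superposition recovers exact transforms and their screw decomposition", {
  set.seed(11)
  P <- matrix(rnorm(45), 15, 3)
  sp <- superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$transform@rotationAngle, 0, tolerance = 1e-6)

  R <- rotationAboutAxis(c(0, 0, 1), 60)
  sp <- superpose(P, P %*% t(R))
  expect_equal(sp$transform@rotationAngle, 60, tolerance = 1e-6)
  expect_lt(abs(sp$transform@screwTranslation), 1e-6)

  # rotation by 360/7 plus 1.5 A along the axis
  ax <- c(0, 0, 1)
  Q <- sweep(P %*% t(rotationAboutAxis(ax, 360 / 7)), 2, 1.5 * ax, "+")
  sp <- superpose(P, Q)
  expect_equal(sp$transform@rotationAngle, 360 / 7, tolerance = 1e-6)
  expect_equal(abs(sp$transform@screwTranslation), 1.5, tolerance = 1e-6)

  # the reported rmsd equals the rmsd of the applied transform
  fit <- applyTransform(sp$transform, P)
  expect_equal(sqrt(mean(rowSums((fit - Q)^2))), sp$rmsd, tolerance = 1e-9)

  collinear <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(superpose(collinear, collinear), "degenerate|collinear")
})

test_that("side-chain centers follow the stated conventions", {
  m <- readStructure(miniAlaPdb)
  cb <- as.numeric(atomTable(m)[5, c("x", "y", "z")])
  expect_equal(sideChainCenter(m, "A", 1, mode = "atoms"), cb)
  # Gly reports CA
  g <- atomTable(m)[1:4, ]
  g$resname <- "GLY"
  mg <- new("StructureModel", atoms = g)
  expect_equal(sideChainCenter(mg, "A", 1, mode = "atoms"),
               as.numeric(g[g$elety == "CA", c("x", "y", "z")]))
  # Leu: unweighted mean of CB, CG, CD1, CD2 (hand-averaged oracle)
  leu <- mutateOntoBackbone(m, "L")
  at <- atomTable(leu)
  sc <- at[at$elety %in% c("CB", "CG", "CD1", "CD2"), c("x", "y", "z")]
  expect_equal(nrow(sc), 4)
  expect_equal(sideChainCenter(leu, "A", 1, mode = "atoms"),
               unname(colMeans(as.matrix(sc))))
  # centroid mode requires an SCC pseudoatom
  expect_error(sideChainCenter(m, "A", 1, mode = "centroid"), "SCC")
  mscc <- placeCentroids(readStructure(miniAlaPdb))
  expect_equal(sideChainCenter(mscc, "A", 1, mode = "centroid"), cb,
               tolerance = 0.01)
})
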