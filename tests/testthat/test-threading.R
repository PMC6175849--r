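# Threading, repacking and soft-steric scoring.

test_that("identity threading keeps residue types and backbone coordinates", {
  m <- fxBarrel(6)
  thr <- mutateOntoBackbone(m, SEQ_ILE_CORE)
  a0 <- atomTable(m); a1 <- atomTable(thr)
  bb0 <- a0[a0$elety %in% c("N", "CA", "C", "O"), ]
  bb1 <- a1[a1$elety %in% c("N", "CA", "C", "O"), ]
  expect_equal(bb1$resname, bb0$resname)
  expect_equal(as.matrix(bb1[, c("x", "y", "z")]),
               as.matrix(bb0[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("an all-Ala thread leaves exactly CB beyond the backbone", {
  thr <- mutateOntoBackbone(fxBarrel(6), SEQ_ALA)
  a <- atomTable(thr)
  expect_true(all(a$resname == "ALA"))
  perRes <- table(paste(a$chain, a$resno))
  expect_true(all(perRes == 5))  # N, CA, C, O, CB
  expect_false("SCC" %in% a$elety)
})

test_that("threading changes atom sets according to the residue topology table", {
  m <- fxBarrel(2)
  ile <- atomTable(mutateOntoBackbone(m, strrep("I", 28)))
  leu <- atomTable(mutateOntoBackbone(m, strrep("L", 28)))
  ileNames <- sort(ile$elety[ile$chain == "A" & ile$resno == 5])
  leuNames <- sort(leu$elety[leu$chain == "A" & leu$resno == 5])
  expect_equal(ileNames, sort(c("N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1")))
  expect_equal(leuNames, sort(c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2")))
  expect_length(ileNames, 8)
  expect_length(leuNames, 8)
})

test_that("length-incompatible sequences raise the declared condition", {
  expect_error(mutateOntoBackbone(fxBarrel(6), strrep("A", 21)),
               class = "ccbarrelLengthMismatch")
})

test_that("repacking is idempotent and leaves clash-free models alone", {
  thr <- mutateOntoBackbone(fxBarrel(6, r0 = 10.5), SEQ_ALA)  # wide, no clashes
  rp <- repack(thr)
  expect_equal(atomTable(rp)[, c("x", "y", "z")],
               atomTable(thr)[, c("x", "y", "z")])
  thr2 <- mutateOntoBackbone(fxNarrowCollapsed(), SEQ_ILE_CORE)
  rp1 <- repack(thr2)
  rp2 <- repack(rp1)
  expect_equal(atomTable(rp2)[, c("x", "y", "z")],
               atomTable(rp1)[, c("x", "y", "z")])
  expect_lte(sum(stericScore(rp1)), sum(stericScore(thr2)))
})

test_that("after repacking every residue is at a local rotamer optimum", {
  # independent check: enumerate the library around the final state
  params <- stericParams()
  rp <- repack(mutateOntoBackbone(fxNarrowCollapsed(), SEQ_ILE_CORE),
               params = params)
  a <- atomTable(rp)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- ccbarrel:::vdwRadius(a$elesy)
  for (res in list(c("A", 4), c("B", 11), c("D", 18))) {
    rows <- which(a$chain == res[1] & a$resno == as.integer(res[2]))
    mv <- rows[!(a$elety[rows] %in% c("N", "CA", "C", "O", "CB"))]
    pos <- function(nm) xyz[rows[a$elety[rows] == nm][1], ]
    ctx <- setdiff(seq_len(nrow(a)), rows)
    eOf <- function(coords) ccbarrel:::.softPenalty(
      coords, radii[mv], xyz[ctx, ], radii[ctx], params)
    eCur <- eOf(xyz[mv, , drop = FALSE])
    lib <- rotamerLibrary("ILE")
    eAll <- apply(lib, 1, function(chis) {
      sc <- ccbarrel:::buildSideChain("ILE", pos("N"), pos("CA"), pos("CB"),
                                      chis)
      eOf(sc[a$elety[mv], , drop = FALSE])
    })
    expect_lte(eCur, min(eAll) + 1e-6)
  }
})

test_that("the steric pair penalty matches its closed form and splits evenly", {
  params <- stericParams(s = 0.9, k = 100)
  contact <- params$s * (1.70 + 1.70)
  mk <- function(d) modelFromAtoms(
    atomRow("A", 1, "ALA", "CB", c(0, 0, 0)),
    atomRow("B", 1, "ALA", "CB", c(d, 0, 0)))
  # at or beyond the softened contact distance: zero
  expect_equal(unname(stericScore(mk(contact), params)), c(0, 0))
  expect_equal(unname(stericScore(mk(4.0), params)), c(0, 0))
  # at half the softened contact: penalty k * 0.25, half per chain
  sc <- stericScore(mk(contact / 2), params)
  expect_equal(unname(sc), c(12.5, 12.5))
  expect_equal(sum(sc), params$k * 0.25)
})

test_that("scores are invariant under a global rigid motion", {
  thr <- repack(mutateOntoBackbone(fxBarrel(6), SEQ_ILE_CORE))
  s0 <- stericScore(thr)
  t0 <- totalScore(thr)
  R <- rotationAboutAxis(c(1, 1, 0), 37)
  a <- atomTable(thr)
  moved <- applyRigid(as.matrix(a[, c("x", "y", "z")]), R, c(5, -3, 11))
  a$x <- moved[, 1]; a$y <- moved[, 2]; a$z <- moved[, 3]
  mt <- new("StructureModel", atoms = a, source = "moved", model = 1L)
  expect_equal(unname(stericScore(mt)), unname(s0), tolerance = 1e-9)
  expect_equal(unname(totalScore(mt)), unname(t0), tolerance = 1e-9)
})

test_that("shrinking the superhelical radius never relieves steric strain", {
  r0s <- c(8.6, 8.9, 9.2, 9.5, 9.8)
  scores <- vapply(r0s, function(r0) {
    m <- mutateOntoBackbone(buildBarrel(crickParams(6, r0 = r0),
                                        SEQ_ILE_CORE), SEQ_ILE_CORE)
    mean(stericScore(repack(m)))
  }, numeric(1))
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("the total score rewards apolar contact and reduces to steric at c = 0", {
  params <- stericParams()
  contact <- params$s * (1.70 + 1.70)
  touching <- modelFromAtoms(
    atomRow("A", 1, "LEU", "CD1", c(0, 0, 0)),
    atomRow("B", 1, "LEU", "CD1", c(contact + 0.3, 0, 0)))
  expect_equal(unname(stericScore(touching, params)), c(0, 0))
  tot <- totalScore(touching, params)
  expect_equal(sum(tot), -params$c)
  expect_true(all(tot < 0))
  apart <- modelFromAtoms(
    atomRow("A", 1, "LEU", "CD1", c(0, 0, 0)),
    atomRow("B", 1, "LEU", "CD1", c(30, 0, 0)))
  expect_equal(sum(totalScore(apart, params)), 0)
  p0 <- stericParams(c = 0)
  m <- repack(mutateOntoBackbone(fxBarrel(5), SEQ_ILE_CORE))
  expect_equal(totalScore(m, p0), stericScore(m, p0))
})

test_that("specificity matrices have an exactly zero cognate diagonal", {
  seqs <- c(ii = SEQ_ILE_CORE, aa = SEQ_ALA)
  structs <- list(barrel = fxBarrel(6), narrow = fxNarrowCollapsed())
  cognate <- c(ii = "barrel", aa = "narrow")
  for (sc in c("steric", "total")) {
    sm <- specificityMatrix(seqs, structs, cognate, score = sc)
    expect_identical(unname(diag(scoreMatrix(sm)[names(seqs),
                                                 cognate[names(seqs)]])),
                     c(0, 0))
  }
  # degenerate 1x1 case
  sm1 <- specificityMatrix(seqs["ii"], structs["barrel"],
                           cognate[1])
  expect_identical(unname(scoreMatrix(sm1)[1, 1]), 0)
})

test_that("per-chain score spread vanishes on exactly Cn-symmetric backbones", {
  sm <- specificityMatrix(c(ii = SEQ_ILE_CORE), list(barrel = fxBarrel(6)),
                          c(ii = "barrel"))
  expect_lt(sm@sd[1, 1], 1e-9)
})

test_that("beta-branched cores clash in the narrow collapsed fixture, Ala fits anywhere", {
  sm <- fxCached("sm2x2", function() specificityMatrix(
    c(ii = SEQ_ILE_CORE, aa = SEQ_ALA),
    list(barrel = fxBarrel(6), narrow = fxNarrowCollapsed()),
    c(ii = "barrel", aa = "narrow")))
  v <- scoreMatrix(sm)
  expect_gt(v["ii", "narrow"], 0)
  expect_lte(v["aa", "barrel"], 0)
  expect_lte(v["aa", "narrow"], 0)
})

test_that("length-incompatible pairs become missing cells, not failures", {
  seqs <- c(ii = SEQ_ILE_CORE, short = strrep("A", 21))
  structs <- list(barrel = fxBarrel(6),
                  short = buildBarrel(crickParams(6), strrep("A", 21)))
  sm <- specificityMatrix(seqs, structs,
                          c(ii = "barrel", short = "short"))
  expect_true(is.na(scoreMatrix(sm)["ii", "short"]))
  expect_true(is.na(scoreMatrix(sm)["short", "barrel"]))
  expect_identical(unname(scoreMatrix(sm)["short", "short"]), 0)
})
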