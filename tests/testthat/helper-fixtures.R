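# Shared fixtures, all generated in code and cached for the test run.

.fx <- new.env(parent = emptyenv())

fxCached <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

# Type-2 heptad with beta-branched a/d core and Ala at b, c, e, f, g.
SEQ_ILE_CORE <- buildSequence("IAAIAAA", 4)
SEQ_LEU_CORE <- buildSequence("LAALAAA", 4)
SEQ_ALA <- strrep("A", 28)

fxBarrel <- function(n, ...) {
  args <- list(...)
  key <- paste0("barrel", n, paste(names(args), unlist(args), collapse = "_"))
  fxCached(key, function()
    buildBarrel(do.call(crickParams, c(list(n), args)), SEQ_ILE_CORE))
}

fxSlippedHexamer <- function() fxCached("slipped6", function()
  buildBarrel(crickParams(6, zSlips = (0:5) * 1.2), SEQ_ILE_CORE))

fxTwoSheet <- function() fxCached("twosheet", function()
  buildCollapsed(crickParams(6), SEQ_LEU_CORE, "two_sheet"))

# Narrow two-sheet bundle used for steric discrimination: inter-sheet gap
# tight enough that beta-branched cores cannot be accommodated.
fxNarrowCollapsed <- function() fxCached("narrow", function()
  buildCollapsed(crickParams(6), SEQ_LEU_CORE, "two_sheet", gap = 8.6))

fxDocked <- function() fxCached("docked", function()
  buildCollapsed(crickParams(6), SEQ_LEU_CORE, "docked"))

fxKih <- function(model, key, ...) {
  fxCached(paste0("kih_", key), function() analyzeKih(model, ...))
}

# Straight ideal alpha-helix C-alpha trace (radius 2.26 A, rise 1.51 A,
# 100 deg/residue) used as an analytic oracle fixture.
straightHelixCA <- function(L, r1 = 2.26, rise = 1.51, twist = 100,
                            psi0 = 0) {
  t <- seq_len(L) - 1
  psi <- (psi0 + twist * t) * pi / 180
  cbind(r1 * cos(psi), r1 * sin(psi), rise * t)
}

# Minimal atoms table row constructor for hand-built fixtures.
atomRow <- function(chain, resno, resname, elety, pos, elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(sub("^[0-9]*", "", elety), 1, 1)
  data.frame(chain = chain, resno = resno, resname = resname,
             elety = elety, elesy = elesy,
             x = pos[1], y = pos[2], z = pos[3], o = 1,
             stringsAsFactors = FALSE)
}

modelFromAtoms <- function(..., source = "hand-built") {
  new("StructureModel", atoms = do.call(rbind, list(...)), source = source,
      model = 1L)
}

# Synthetic knob/hole system with exactly controllable center distances:
# the hole helix carries SCC pseudoatoms at chosen positions, the knob
# helix sits far away except for its knob residue.
syntheticKnobModel <- function(d4 = 7.4) {
  rows <- list()
  # knob chain K: 7 residues along z at x = -30, knob residue 4 at origin
  for (i in 1:7) {
    p <- if (i == 4) c(0, 0, 0) else c(-30, 0, 1.5 * i)
    rows[[length(rows) + 1]] <- atomRow("K", i, "ALA", "CA", p + c(0, 0, 0.1))
    rows[[length(rows) + 1]] <- atomRow("K", i, "ALA", "CB", p + c(0, 1, 0.1))
    rows[[length(rows) + 1]] <- atomRow("K", i, "ALA", "SCC", p, "C")
  }
  # hole chain H: residues 1..8; diamond members 1, 4, 5, 8
  holePos <- list(`1` = c(d4, 0, 0), `4` = c(5.0, 0.5, 0),
                  `5` = c(5.2, -0.5, 0), `8` = c(6.0, 0, 1))
  for (i in 1:8) {
    p <- if (as.character(i) %in% names(holePos)) holePos[[as.character(i)]]
         else c(30, 30, 2 * i)
    rows[[length(rows) + 1]] <- atomRow("H", i, "ALA", "CA", p + c(0, 0, 0.1))
    rows[[length(rows) + 1]] <- atomRow("H", i, "ALA", "CB", p + c(0, 1, 0.1))
    rows[[length(rows) + 1]] <- atomRow("H", i, "ALA", "SCC", p, "C")
  }
  m <- do.call(modelFromAtoms, rows)
  hK <- syntheticHelix("K", 1:7, as.matrix(atomTable(m)[
    atomTable(m)$chain == "K" & atomTable(m)$elety == "CA", c("x", "y", "z")]))
  hH <- syntheticHelix("H", 1:8, as.matrix(atomTable(m)[
    atomTable(m)$chain == "H" & atomTable(m)$elety == "CA", c("x", "y", "z")]))
  list(model = m, helices = list(hK, hH))
}

# Hand-built HelixSegment with a straight axis, for synthetic knob tests.
syntheticHelix <- function(chain, resno, ca, axisDir = c(0, 0, 1)) {
  n <- length(resno)
  pts <- matrix(rep(colMeans(ca), 2), 2, 3, byrow = TRUE)
  pts[2, ] <- pts[2, ] + axisDir
  new("HelixSegment", chain = chain, resno = as.integer(resno), ca = ca,
      axisPoints = pts, axisDir = axisDir / sqrt(sum(axisDir^2)))
}
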