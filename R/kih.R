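# Knobs-into-holes detection and coiled-coil classification: KIH contact
# search with the canonical diamond-hole pattern, packing-angle classes,
# the helix interaction graph, heptad-register and interface-type
# assignment, and assembly-symmetry classification.

.emptyKnobs <- function() {
  data.frame(knobHelix = integer(), holeHelix = integer(),
             chain = character(), resno = integer(), resname = character(),
             holeChain = character(),
             hole1 = integer(), hole2 = integer(), hole3 = integer(),
             hole4 = integer(),
             d1 = numeric(), d2 = numeric(), d3 = numeric(), d4 = numeric(),
             packingAngle = numeric(), packingClass = character(),
             reciprocal = logical(), stringsAsFactors = FALSE)
}

#' Find knobs-into-holes contacts
#'
#' For every residue on every helix, residues of each other helix whose
#' side-chain centers lie within \code{cutoff} (inclusive) are collected;
#' when at least four are in range, the four nearest form the candidate
#' hole, accepted as a knob when the hole residue numbers fit the canonical
#' diamond pattern \{j, j+3, j+4, j+7\} (or, with \code{relaxedHoles}, any
#' four residues spanning at most 7 positions). Each knob carries its
#' packing angle against the hole helix's local axis and the
#' parallel/perpendicular class.
#'
#' @param model a \linkS4class{StructureModel}
#' @param helices list of \linkS4class{HelixSegment} (from
#'   \code{\link{detectHelices}})
#' @param cutoff maximum knob-to-hole center distance in Angstroms
#'   (default 7.4, inclusive)
#' @param mode side-chain center definition: \code{"centroid"} uses SCC
#'   pseudoatoms, \code{"atoms"} averages side-chain heavy atoms
#' @param relaxedHoles accept any 4-residue hole of span <= 7 (off by
#'   default)
#' @return data.frame with one row per knob: knob helix/chain/residue, the
#'   four hole residues and center distances (nearest first), packing angle
#'   and class, and a pair-level reciprocity flag
#' @export
findKnobs <- function(model, helices, cutoff = 7.4,
                      mode = c("centroid", "atoms"), relaxedHoles = FALSE) {
  mode <- match.arg(mode)
  if (length(helices) < 2) stop("need at least 2 helices")
  scc <- .sccMatrix(model, mode)
  key <- paste(scc$info$chain, scc$info$resno, sep = ":")
  hRows <- lapply(helices, function(h)
    match(paste(h@chain, h@resno, sep = ":"), key))
  if (any(is.na(unlist(hRows)))) stop("helix residues missing from model")
  out <- list()
  for (hi in seq_along(helices)) {
    rowsI <- hRows[[hi]]
    cenI <- scc$centers[rowsI, , drop = FALSE]
    for (hj in seq_along(helices)) {
      if (hj == hi || helices[[hj]]@chain == helices[[hi]]@chain &&
            hj == hi) next
      if (hj == hi) next
      rowsJ <- hRows[[hj]]
      if (helices[[hj]]@chain == helices[[hi]]@chain &&
          length(intersect(rowsI, rowsJ)) > 0) next
      cenJ <- scc$centers[rowsJ, , drop = FALSE]
      resJ <- helices[[hj]]@resno
      d2 <- crossDist2(cenI, cenJ)
      for (ii in seq_along(rowsI)) {
        d <- sqrt(d2[ii, ])
        inc <- which(d <= cutoff)
        if (length(inc) < 4) next
        ord <- inc[order(d[inc], resJ[inc])]
        hole <- ord[1:4]
        hres <- sort(resJ[hole])
        pat <- hres - hres[1]
        ok <- if (relaxedHoles) pat[4] <= 7 else
          identical(pat, c(0L, 3L, 4L, 7L))
        if (!ok) next
        ang <- .knobPackingAngle(model, helices[[hi]]@chain,
                                 helices[[hi]]@resno[ii],
                                 helices[[hj]], mean(hres))
        out[[length(out) + 1]] <- data.frame(
          knobHelix = hi, holeHelix = hj,
          chain = helices[[hi]]@chain, resno = helices[[hi]]@resno[ii],
          resname = scc$info$resname[rowsI[ii]],
          holeChain = helices[[hj]]@chain,
          hole1 = hres[1], hole2 = hres[2], hole3 = hres[3], hole4 = hres[4],
          d1 = d[ord[1]], d2 = d[ord[2]], d3 = d[ord[3]], d4 = d[ord[4]],
          packingAngle = ang,
          packingClass = if (is.na(ang)) "unclassified" else
            classifyPacking(ang),
          reciprocal = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(.emptyKnobs())
  knobs <- do.call(rbind, out)
  pairKey <- paste(knobs$knobHelix, knobs$holeHelix)
  revKey <- paste(knobs$holeHelix, knobs$knobHelix)
  knobs$reciprocal <- revKey %in% pairKey
  rownames(knobs) <- NULL
  knobs
}

# Packing angle of one knob: angle between the knob's CA->CB vector and
# the hole helix's local axis at the hole midpoint. NA for Gly knobs.
.knobPackingAngle <- function(model, chain, resno, holeHelix, holeMidRes) {
  a <- model@atoms
  sel <- a$chain == chain & a$resno == resno
  ca <- which(sel & a$elety == "CA")
  cb <- which(sel & a$elety == "CB")
  if (length(ca) != 1 || length(cb) != 1) return(NA_real_)
  v <- as.numeric(a[cb, c("x", "y", "z")]) - as.numeric(a[ca, c("x", "y", "z")])
  ax <- .axisDirAt(holeHelix, holeMidRes)
  vecAngle(v, ax)
}

#' Packing angle of a knob residue against a hole helix
#'
#' Angle (degrees, in [0, 180]) between the knob's CA-to-CB bond vector
#' and the hole helix's local axis direction at the hole midpoint. Glycine
#' knobs have no CB and return NA.
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain,resno the knob residue
#' @param holeHelix the \linkS4class{HelixSegment} hosting the hole
#' @param holeMidRes residue number at the middle of the hole
#' @return angle in degrees or NA
#' @export
packingAngle <- function(model, chain, resno, holeHelix, holeMidRes) {
  .knobPackingAngle(model, chain, resno, holeHelix, holeMidRes)
}

#' Classify a knob packing angle
#'
#' Perpendicular-like for core angles between 45 and 135 degrees
#' (inclusive bounds), parallel otherwise.
#'
#' @param angle packing angle in degrees, in [0, 180]
#' @return \code{"perpendicular"} or \code{"parallel"}
#' @export
classifyPacking <- function(angle) {
  stopifnot(all(angle >= 0 & angle <= 180))
  ifelse(angle >= 45 & angle <= 135, "perpendicular", "parallel")
}

#' Build the helix interaction graph from knobs
#'
#' Directed graph with one node per helix and an edge from each knob's
#' helix to its hole helix.
#'
#' @param knobs data.frame from \code{\link{findKnobs}}
#' @param nHelices total number of helices (nodes), defaulting to the
#'   largest helix index seen
#' @return an \code{igraph} directed graph
#' @export
buildKihGraph <- function(knobs, nHelices = NULL) {
  if (is.null(nHelices))
    nHelices <- max(c(1L, knobs$knobHelix, knobs$holeHelix))
  g <- igraph::make_empty_graph(n = nHelices, directed = TRUE)
  if (nrow(knobs) > 0)
    g <- igraph::add_edges(g, rbind(knobs$knobHelix, knobs$holeHelix))
  g
}

#' Coiled-coil assemblies in a KIH graph
#'
#' Weakly connected components of the helix interaction graph; a component
#' is flagged as a coiled coil when every member helix both donates at
#' least one knob and hosts at least one hole.
#'
#' @param graph igraph from \code{\link{buildKihGraph}}
#' @return data.frame with one row per component: \code{component},
#'   \code{size}, \code{members} (comma-separated helix ids) and
#'   \code{coiledCoil}
#' @export
assemblies <- function(graph) {
  comp <- igraph::components(graph, mode = "weak")
  outdeg <- igraph::degree(graph, mode = "out")
  indeg <- igraph::degree(graph, mode = "in")
  res <- lapply(seq_len(comp$no), function(k) {
    members <- which(comp$membership == k)
    data.frame(component = k, size = length(members),
               members = paste(members, collapse = ","),
               coiledCoil = all(outdeg[members] >= 1) &&
                 all(indeg[members] >= 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Relative orientation of two helices
#'
#' @param h1,h2 \linkS4class{HelixSegment} objects
#' @return \code{"parallel"} or \code{"antiparallel"} (axis dot product
#'   below zero)
#' @export
pairwiseOrientation <- function(h1, h2) {
  if (sum(h1@axisDir * h2@axisDir) < 0) "antiparallel" else "parallel"
}

# "all-parallel" or "mixed" over a helix list.
.orientationPattern <- function(helices) {
  if (length(helices) < 2) return("all-parallel")
  ref <- helices[[1]]
  mixed <- any(vapply(helices[-1], function(h)
    pairwiseOrientation(ref, h) == "antiparallel", logical(1)))
  if (mixed) "mixed" else "all-parallel"
}

#' Assign heptad register letters to a helix from its knobs
#'
#' Chooses the cyclic offset (0-6) that maximises the number of knob
#' residues at \{a, d\}, breaking ties by \{e, g\} membership and then by
#' the smallest offset; letters propagate mod 7 across the whole helix.
#'
#' @param helix a \linkS4class{HelixSegment}
#' @param knobs data.frame from \code{\link{findKnobs}}; only rows whose
#'   knob residue lies on \code{helix} are used
#' @return named character vector mapping residue number to letter a-g, or
#'   NULL when the helix carries fewer than 2 knobs
#' @export
assignRegister <- function(helix, knobs) {
  kres <- unique(knobs$resno[knobs$chain == helix@chain &
                               knobs$resno %in% helix@resno])
  if (length(kres) < 2) return(NULL)
  r0 <- helix@resno[1]
  best <- NULL
  for (off in 0:6) {
    letters7 <- .HEPTAD_LETTERS[(kres - r0 + off) %% 7 + 1]
    nAD <- sum(letters7 %in% c("a", "d"))
    nEG <- sum(letters7 %in% c("e", "g"))
    score <- c(nAD, nEG, -off)
    if (is.null(best) || .lexGreater(score, best$score))
      best <- list(score = score, off = off)
  }
  reg <- .HEPTAD_LETTERS[(helix@resno - r0 + best$off) %% 7 + 1]
  names(reg) <- helix@resno
  reg
}

.lexGreater <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] > b[i]) return(TRUE)
    if (a[i] < b[i]) return(FALSE)
  }
  FALSE
}

#' Classify a coiled-coil interface from its knob registers
#'
#' \{a,d\} is the classical Type-N interface; \{a,d,e\} or \{a,d,g\} Type
#' 1; \{a,d,e,g\} Type 2; the two-offset-seam patterns \{a,c,d,f\} or
#' \{a,b,d,f\} Type 3; anything else is unclassified.
#'
#' @param knobRegisters character vector (or set) of register letters that
#'   carry knobs
#' @return one of \code{"N"}, \code{"1"}, \code{"2"}, \code{"3"},
#'   \code{"unclassified"}
#' @export
classifyInterface <- function(knobRegisters) {
  s <- paste(sort(unique(knobRegisters)), collapse = "")
  switch(s,
         "ad" = "N",
         "ade" = "1", "adg" = "1",
         "adeg" = "2",
         "acdf" = "3", "abdf" = "3",
         "unclassified")
}

# --- assembly symmetry -------------------------------------------------------

# Trimmed C-alpha matrix of a helix, reversed when orientation is flipped.
.helixCA <- function(h, L, reverse = FALSE) {
  n <- length(h@resno)
  start <- floor((n - L) / 2)
  m <- h@ca[(start + 1):(start + L), , drop = FALSE]
  if (reverse) m[L:1, , drop = FALSE] else m
}

#' Classify the internal symmetry of a helix assembly
#'
#' Superposes every ordered pair of helices (reversing the residue order
#' of antiparallel partners), keeps pair maps with rmsd below
#' \code{rmsdTol}, and classifies: maps that carry the whole assembly onto
#' itself form the point group (cyclic \code{Cn}, or \code{Dn} when
#' perpendicular 2-folds accompany a principal cyclic axis); a single map
#' that relays every helix onto the next along an open chain with a
#' consistent axial translation of at least \code{slipTol} is a
#' \code{screw} (slipped/spiral) arrangement; with no acceptable
#' non-identity map the assembly only has the identity element \code{E}.
#'
#' @param model a \linkS4class{StructureModel} (unused beyond provenance;
#'   the helices carry the coordinates)
#' @param helices list of \linkS4class{HelixSegment} forming one assembly
#' @param rmsdTol pair-map acceptance rmsd in Angstroms (default 1.0)
#' @param slipTol screw translation below which a map counts as a pure
#'   rotation (default 1.0 A)
#' @return a \linkS4class{SymmetryReport}
#' @export
assemblySymmetry <- function(model, helices, rmsdTol = 1.0, slipTol = 1.0) {
  n <- length(helices)
  if (n < 2) stop("need at least 2 helices")
  lens <- vapply(helices, function(h) length(h@resno), integer(1))
  L <- min(lens)
  if (max(lens) - L > 7)
    stop("helix lengths too different to trim to a common range")
  cas <- lapply(seq_len(n), function(k) .helixCA(helices[[k]], L))
  orientation <- .orientationPattern(helices)

  # candidate pair maps; residue correspondence is always i -> i (genuine
  # symmetry operations of a homomer preserve sequence register)
  cand <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sp <- superpose(cas[[i]], cas[[j]])
    if (sp$rmsd >= rmsdTol) next
    tr <- sp$transform
    # where does the transform send every helix?
    dest <- integer(n)
    derr <- numeric(n)
    for (k in seq_len(n)) {
      moved <- applyTransform(tr, cas[[k]])
      errs <- vapply(seq_len(n), function(l)
        sqrt(mean(rowSums((moved - cas[[l]])^2))), numeric(1))
      dest[k] <- which.min(errs)
      derr[k] <- min(errs)
    }
    mapped <- derr < rmsdTol
    cand[[length(cand) + 1]] <- list(
      i = i, j = j, rmsd = sp$rmsd, angle = tr@rotationAngle,
      screw = tr@screwTranslation, axis = tr@axis, dest = dest,
      mapped = mapped,
      assemblyValid = all(mapped) && !anyDuplicated(dest[mapped]))
  }
  opsDf <- if (length(cand) == 0) data.frame() else do.call(rbind, lapply(cand,
    function(cc) data.frame(from = cc$i, to = cc$j, rmsd = cc$rmsd,
                            angle = cc$angle, screw = cc$screw,
                            assemblyValid = cc$assemblyValid)))

  valid <- Filter(function(cc) cc$assemblyValid && cc$angle > 1, cand)
  if (length(valid) > 0) {
    angles <- vapply(valid, `[[`, numeric(1), "angle")
    screws <- vapply(valid, `[[`, numeric(1), "screw")
    axes <- t(vapply(valid, `[[`, numeric(3), "axis"))
    thetaMin <- min(angles)
    order <- as.integer(round(360 / thetaMin))
    gen <- abs(angles - thetaMin) < 2
    # principal axis = axis of the smallest-angle ops
    mainAxis <- unitVec(colSums(axes[gen, , drop = FALSE] *
                                  sign(axes[gen, , drop = FALSE] %*%
                                         axes[which(gen)[1], ])[, 1]))
    perp <- vapply(seq_len(nrow(axes)), function(k)
      abs(sum(axes[k, ] * mainAxis)) < 0.2, logical(1))
    label <- if (any(perp) && any(!perp)) "Dn" else "Cn"
    if (label == "Dn") {
      mainAngles <- angles[!perp]
      thetaMin <- min(mainAngles)
      order <- as.integer(round(360 / thetaMin))
      gen <- !perp & abs(angles - thetaMin) < 2
    }
    return(new("SymmetryReport", label = label, rotationOrder = order,
               meanRotation = mean(angles[gen]),
               meanScrew = mean(abs(screws[gen])),
               orientationPattern = orientation, ops = opsDf))
  }

  # spiral (screw) search: one map relaying all helices along an open chain
  spirals <- Filter(function(cc) {
    nm <- sum(cc$mapped)
    if (nm != n - 1) return(FALSE)
    # mapped destinations must be distinct and leave exactly one head/tail
    dests <- cc$dest[cc$mapped]
    if (anyDuplicated(dests)) return(FALSE)
    heads <- setdiff(seq_len(n), dests)
    length(heads) == 1
  }, cand)
  if (length(spirals) > 0) {
    rmsds <- vapply(spirals, `[[`, numeric(1), "rmsd")
    best <- spirals[[which.min(rmsds)]]
    lab <- if (abs(best$screw) >= slipTol) "screw" else "Cn"
    ord <- if (best$angle > 1) as.integer(round(360 / best$angle)) else NA_integer_
    return(new("SymmetryReport", label = lab,
               rotationOrder = if (lab == "Cn") ord else NA_integer_,
               meanRotation = best$angle, meanScrew = best$screw,
               orientationPattern = orientation, ops = opsDf))
  }

  new("SymmetryReport", label = "E", rotationOrder = NA_integer_,
      meanRotation = 0, meanScrew = 0,
      orientationPattern = orientation, ops = opsDf)
}

#' Full KIH characterisation of a model
#'
#' Convenience wrapper running helix detection, knob search, graph
#' assembly, register and interface assignment, orientation and symmetry
#' classification in one call.
#'
#' @param model a \linkS4class{StructureModel}
#' @param cutoff knob acceptance cutoff (A)
#' @param mode side-chain center mode (see \code{\link{findKnobs}})
#' @param relaxedHoles see \code{\link{findKnobs}}
#' @param rmsdTol,slipTol symmetry tolerances (A)
#' @return list with \code{helices}, \code{knobs}, \code{assemblies},
#'   \code{registers} (per helix), \code{knobRegisters},
#'   \code{interfaceType}, \code{orientationPattern} and \code{symmetry}
#' @export
analyzeKih <- function(model, cutoff = 7.4, mode = c("centroid", "atoms"),
                       relaxedHoles = FALSE, rmsdTol = 1.0, slipTol = 1.0) {
  mode <- match.arg(mode)
  helices <- detectHelices(model)
  knobs <- findKnobs(model, helices, cutoff = cutoff, mode = mode,
                     relaxedHoles = relaxedHoles)
  graph <- buildKihGraph(knobs, nHelices = length(helices))
  comps <- assemblies(graph)
  registers <- lapply(helices, assignRegister, knobs = knobs)
  knobReg <- character(0)
  for (hi in seq_along(helices)) {
    reg <- registers[[hi]]
    if (is.null(reg)) next
    kres <- knobs$resno[knobs$knobHelix == hi]
    knobReg <- c(knobReg, reg[as.character(kres)])
  }
  knobReg <- sort(unique(unname(knobReg)))
  sym <- if (length(helices) >= 2)
    assemblySymmetry(model, helices, rmsdTol = rmsdTol, slipTol = slipTol)
  else NULL
  list(helices = helices, knobs = knobs, assemblies = comps,
       registers = registers, knobRegisters = knobReg,
       interfaceType = classifyInterface(knobReg),
       orientationPattern = .orientationPattern(helices),
       symmetry = sym)
}
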