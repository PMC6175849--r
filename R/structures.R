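# Structure I/O and basic geometry: parsing/writing PDB (and mmCIF) through
# bio3d, alpha-helix detection from C-alpha distances, local helix axes, and
# rigid-body superposition with screw decomposition.

#' Read a protein structure
#'
#' Parses a PDB (or mmCIF) file, or raw PDB text, into a
#' \linkS4class{StructureModel}. Only the first coordinate model is kept;
#' HETATM records, waters and non-standard residues (other than a small
#' alias table of modified amino acids mapped to standard parents) are
#' discarded; alternate locations other than blank or \code{"A"} are dropped.
#'
#' @param source path to a \code{.pdb}/\code{.cif} file, or a character
#'   scalar/vector of raw PDB text.
#' @param format \code{"auto"}, \code{"pdb"} or \code{"cif"}.
#' @return a \linkS4class{StructureModel}
#' @examples
#' pdb <- writeStructure(buildBarrel(crickParams(n = 2), strrep("A", 14)))
#' readStructure(pdb)
#' @export
readStructure <- function(source, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  isText <- length(source) > 1 || grepl("\n", source) ||
    grepl("^(ATOM|HETATM|HEADER|REMARK|CRYST)", source[1])
  path <- source
  if (isText) {
    lines <- if (length(source) > 1) source else strsplit(source, "\n")[[1]]
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
    if (format == "auto") format <- "pdb"
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "auto")
      format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") .checkPdbRecords(readLines(path, warn = FALSE))
  parsed <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE))
  }
  a <- parsed$atom
  keep <- a$type == "ATOM" &
    (is.na(a$alt) | a$alt %in% c("", "A")) &
    (a$resid %in% names(.AA1) | a$resid %in% names(.RES_ALIAS))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("no protein atoms found in ", if (isText) "input text" else path)
  resname <- a$resid
  ali <- resname %in% names(.RES_ALIAS)
  resname[ali] <- .RES_ALIAS[resname[ali]]
  elesy <- a$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[bad] <- atomElement(a$elety[bad])
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resname = resname, elety = trimws(a$elety), elesy = trimws(elesy),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o), stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- "A"
  new("StructureModel", atoms = atoms,
      source = if (isText) "pdb-text" else basename(path), model = 1L)
}

# Fail with the offending line number on malformed fixed-width records.
.checkPdbRecords <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(rec)
  if (length(idx) == 0)
    stop("no ATOM records found: zero protein atoms")
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) stop("malformed PDB record at line ", i, ": too short")
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("malformed PDB record at line ", i, ": unparseable coordinates")
  }
  invisible(TRUE)
}

#' Write a structure as PDB
#'
#' Emits fixed-width PDB ATOM records (coordinates to 3 decimals) in chain
#' order. Side-chain-centroid pseudoatoms (\code{"SCC"}) are written as
#' ordinary ATOM records of element C so files round-trip through
#' \code{\link{readStructure}}.
#'
#' @param model a \linkS4class{StructureModel}
#' @param file optional output path; when \code{NULL} the PDB text is
#'   returned as a character vector of lines.
#' @return \code{file} (invisibly) or the PDB text lines.
#' @export
writeStructure <- function(model, file = NULL) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  if (nrow(a) == 0) stop("refusing to write an empty structure")
  if (any(nchar(a$elety) > 4)) stop("atom names longer than 4 characters")
  toFile <- !is.null(file)
  if (!toFile) file <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  if (toFile) return(invisible(file))
  out <- readLines(file, warn = FALSE)
  unlink(file)
  out
}

# C-alpha coordinates of one chain as a matrix with resno rownames.
.caMatrix <- function(model, chain) {
  a <- model@atoms
  sel <- a$chain == chain & a$elety == "CA"
  m <- as.matrix(a[sel, c("x", "y", "z")])
  rownames(m) <- a$resno[sel]
  m
}

#' Detect alpha-helical segments
#'
#' Flags residue i as helical when d(CAi, CAi+3) lies in [4.5, 5.6] A and
#' d(CAi, CAi+4) in [5.7, 6.7] A, then returns maximal runs of at least
#' \code{minLen} flagged residues per chain, each with a fitted local axis.
#' The C-alpha-only criterion is robust to missing side chains (e.g.
#' poly-Ala models). Residues without a C-alpha are skipped with a warning.
#'
#' @param model a \linkS4class{StructureModel}
#' @param minLen minimum run length in residues (default 7)
#' @param window axis-fitting window in residues (default 7)
#' @return list of \linkS4class{HelixSegment}
#' @export
detectHelices <- function(model, minLen = 7, window = 7) {
  stopifnot(is(model, "StructureModel"))
  a <- model@atoms
  out <- list()
  for (ch in chainIDs(model)) {
    resnos <- unique(a$resno[a$chain == ch])
    ca <- .caMatrix(model, ch)
    if (length(resnos) > nrow(ca))
      warning("chain ", ch, ": ", length(resnos) - nrow(ca),
              " residue(s) without CA skipped")
    n <- nrow(ca)
    if (n < minLen) next
    res <- as.integer(rownames(ca))
    flagged <- logical(n)
    for (i in seq_len(n - 4)) {
      # only use windows of consecutive author numbering
      if (res[i + 4] - res[i] != 4) next
      d3 <- vecNorm(ca[i + 3, ] - ca[i, ])
      d4 <- vecNorm(ca[i + 4, ] - ca[i, ])
      flagged[i] <- d3 >= 4.5 && d3 <= 5.6 && d4 >= 5.7 && d4 <= 6.7
    }
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < minLen) next
      idx <- starts[k]:ends[k]
      seg <- localHelixAxis(ca[idx, , drop = FALSE], window = window)
      out[[length(out) + 1]] <- new("HelixSegment", chain = ch,
                                    resno = res[idx], ca = ca[idx, , drop = FALSE],
                                    axisPoints = seg$axisPoints,
                                    axisDir = seg$axisDir)
    }
  }
  out
}

#' Local helix axis from C-alpha coordinates
#'
#' Sliding-window centroid estimate of the local helix axis: each axis
#' point is the centroid of \code{window} consecutive C-alpha positions
#' (exact for an ideal helix when the window covers a whole number of
#' turns, and a close approximation otherwise); the overall direction runs
#' from the first to the last axis point (N to C).
#'
#' @param ca n x 3 matrix of C-alpha coordinates, ordered N to C
#' @param window window length in residues (default 7, about two turns)
#' @return list with \code{axisPoints} ((n-window+1) x 3) and unit
#'   \code{axisDir}
#' @export
localHelixAxis <- function(ca, window = 7) {
  n <- nrow(ca)
  if (n < window) stop("need at least ", window, " residues to fit an axis")
  m <- n - window + 1
  pts <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) pts[i, ] <- colMeans(ca[i:(i + window - 1), , drop = FALSE])
  dir <- unitVec(pts[m, ] - pts[1, ])
  list(axisPoints = pts, axisDir = dir)
}

# Local axis direction of a helix segment near a given residue number.
.axisDirAt <- function(segment, resno) {
  pts <- segment@axisPoints
  m <- nrow(pts)
  if (m < 2) return(segment@axisDir)
  # axis point i corresponds to residue window starting at segment residue i
  half <- (length(segment@resno) - m) / 2
  i <- which.min(abs(segment@resno + half - resno))
  i <- min(max(i, 1), m)
  lo <- max(1, i - 1)
  hi <- min(m, i + 1)
  unitVec(pts[hi, ] - pts[lo, ])
}

#' Least-squares rigid superposition
#'
#' Kabsch superposition of point set P onto Q (proper rotation enforced),
#' with the transform's axis-angle and screw decomposition.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3, equal n)
#' @return list with \code{transform} (a \linkS4class{RigidTransform}) and
#'   \code{rmsd} (Angstroms, after transformation)
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' Q <- applyRigid(P, rotationAboutAxis(c(0, 0, 1), 60))
#' superpose(P, Q)$transform
#' @export
superpose <- function(P, Q) {
  fit <- kabsch(P, Q)
  sc <- screwDecompose(fit$rotation, fit$translation)
  tr <- new("RigidTransform", rotation = fit$rotation,
            translation = fit$translation, rotationAngle = sc$angle,
            screwTranslation = sc$screw, axis = sc$axis)
  list(transform = tr, rmsd = fit$rmsd)
}

#' Apply a RigidTransform to coordinates
#' @param transform a \linkS4class{RigidTransform}
#' @param xyz n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(transform, xyz) {
  applyRigid(xyz, transform@rotation, transform@translation)
}

#' Side-chain center of a residue
#'
#' In \code{"atoms"} mode, the unweighted mean of all side-chain heavy
#' atoms (everything beyond C-alpha, excluding backbone N, C, O); glycine
#' reports its C-alpha position. In \code{"centroid"} mode, the position of
#' the residue's \code{"SCC"} pseudoatom (see \code{\link{placeCentroids}}).
#'
#' @param model a \linkS4class{StructureModel}
#' @param chain chain id
#' @param resno author residue number
#' @param mode \code{"atoms"} or \code{"centroid"}
#' @return 3-vector (Angstroms)
#' @export
sideChainCenter <- function(model, chain, resno, mode = c("atoms", "centroid")) {
  mode <- match.arg(mode)
  a <- model@atoms
  sel <- a$chain == chain & a$resno == resno
  if (!any(sel)) stop("no residue ", chain, ":", resno)
  res <- a[sel, , drop = FALSE]
  if (mode == "centroid") {
    i <- which(res$elety == "SCC")
    if (length(i) != 1) stop("residue ", chain, ":", resno, " has no SCC pseudoatom")
    return(as.numeric(res[i, c("x", "y", "z")]))
  }
  if (res$resname[1] == "GLY") {
    i <- which(res$elety == "CA")
    if (length(i) != 1) stop("Gly ", chain, ":", resno, " missing CA")
    return(as.numeric(res[i, c("x", "y", "z")]))
  }
  sc <- !(res$elety %in% c(.BACKBONE_ATOMS, "SCC"))
  if (!any(sc)) stop("residue ", chain, ":", resno,
                     " has no side-chain heavy atoms (atoms mode)")
  unname(colMeans(as.matrix(res[sc, c("x", "y", "z")])))
}

# Matrix of side-chain centers for all residues of a model (rows keyed by
# chain:resno), used by the KIH search. Gly falls back to CA in both modes
# only when no SCC atom exists.
.sccMatrix <- function(model, mode = c("atoms", "centroid")) {
  mode <- match.arg(mode)
  a <- model@atoms
  key <- paste(a$chain, a$resno, sep = ":")
  ukey <- unique(key)
  first <- match(ukey, key)
  info <- data.frame(key = ukey, chain = a$chain[first], resno = a$resno[first],
                     resname = a$resname[first], stringsAsFactors = FALSE)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  centers <- matrix(NA_real_, length(ukey), 3)
  for (i in seq_along(ukey)) {
    rows <- which(key == ukey[i])
    res <- a[rows, , drop = FALSE]
    if (mode == "centroid") {
      j <- which(res$elety == "SCC")
      if (length(j) == 1) { centers[i, ] <- xyz[rows[j], ]; next }
      stop("residue ", ukey[i], " has no SCC pseudoatom (centroid mode)")
    }
    if (res$resname[1] == "GLY") {
      j <- which(res$elety == "CA")
      centers[i, ] <- xyz[rows[j[1]], ]
      next
    }
    sc <- which(!(res$elety %in% c(.BACKBONE_ATOMS, "SCC")))
    if (length(sc) == 0) stop("residue ", ukey[i], " has no side-chain atoms")
    centers[i, ] <- colMeans(xyz[rows[sc], , drop = FALSE])
  }
  list(info = info, centers = centers)
}
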