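# Deterministic generator of idealized coiled-coil models: C-alpha traces on
# the Crick minor-helix-on-superhelix curve, backbone completion from ideal
# internal coordinates, side-chain-centroid pseudoatoms, and collapsed
# (two-sheet / docked) arrangements emulating low-symmetry bundles.

.HEPTAD_LETTERS <- c("a", "b", "c", "d", "e", "f", "g")

# Default superhelical radius: places adjacent helix axes ~9.2 A apart,
# a typical helix-helix packing distance in coiled coils.
.defaultR0 <- function(n) if (n == 2) 4.9 else 4.6 / sin(pi / n)

#' Crick parameter set for the bundle generator
#'
#' Collects the geometric parameters of an idealized n-helix coiled coil.
#' The minor helix advances 2/7 turn per residue in the frame that rotates
#' with the supercoil (the heptad register lock), and the superhelical
#' frequency is derived from the laboratory-frame helical periodicity
#' \code{resPerTurn} unless an explicit \code{pitch} is supplied. Negative
#' pitch = left-handed supercoil (the default for heptad repeats).
#'
#' @param nHelices number of helices (>= 2)
#' @param r0 superhelical radius in Angstroms (default: oligomer-dependent,
#'   giving ~9.6 A axial separation of neighbouring helices)
#' @param pitch superhelical pitch in Angstroms, sign = handedness;
#'   \code{NULL} (default) derives it from \code{resPerTurn}
#' @param r1 minor (alpha-helix) radius, default 2.26 A
#' @param rise rise per residue along the minor helix, default 1.51 A
#' @param resPerTurn laboratory-frame residues per turn, default 3.55
#'   (supercoil pitch angle near 12 degrees for barrel-sized radii)
#' @param phi1 interface angle in degrees: azimuth of the heptad a position
#'   measured from the outward radial direction (default 185, centring the
#'   a/d/e/g seams on the bundle lumen)
#' @param phases per-chain azimuthal offsets in degrees (default 360k/n)
#' @param zSlips per-chain axial offsets in Angstroms (default 0)
#' @param orientations per-chain +1 (up) / -1 (down) flags (default all +1)
#' @return a validated list of class \code{"CrickParams"}
#' @export
crickParams <- function(nHelices, r0 = NULL, pitch = NULL, r1 = 2.26,
                        rise = 1.51, resPerTurn = 3.55,
                        phi1 = 185, phases = NULL, zSlips = 0,
                        orientations = 1L) {
  n <- as.integer(nHelices)
  if (n < 2) stop("nHelices must be >= 2")
  if (is.null(r0)) r0 <- .defaultR0(n)
  if (r0 <= r1 || r1 <= 0) stop("need r0 > r1 > 0")
  if (is.null(phases)) phases <- 360 * (seq_len(n) - 1) / n
  zSlips <- rep_len(zSlips, n)
  orientations <- rep_len(as.integer(orientations), n)
  if (length(phases) != n) stop("phases must have one entry per helix")
  if (!all(orientations %in% c(-1L, 1L))) stop("orientations must be +1/-1")
  p <- list(nHelices = n, r0 = r0, pitch = pitch, r1 = r1, rise = rise,
            resPerTurn = resPerTurn, phi1 = phi1, phases = phases,
            zSlips = zSlips, orientations = orientations)
  class(p) <- "CrickParams"
  p
}

# Angular frequencies (rad/residue) and axial rise per residue.
.crickFrequencies <- function(p) {
  if (is.null(p$pitch)) {
    w0 <- 2 * pi / p$resPerTurn - 2 * pi / 3.5   # register-locked supercoil
    arg <- p$rise^2 - (p$r0 * w0)^2
    if (arg <= 0) stop("superhelical frequency too high for the given rise")
    dz <- sqrt(arg)
    w1 <- 2 * pi / 3.5
  } else {
    dz <- p$rise / sqrt(1 + (2 * pi * p$r0 / p$pitch)^2)
    w0 <- 2 * pi * dz / p$pitch
    w1 <- 2 * pi / p$resPerTurn - w0
  }
  list(w0 = w0, w1 = w1, dz = dz)
}

#' Expand a heptad-repeat specification into a sequence
#'
#' Concatenates \code{nHeptads} copies of a 7-letter repeat. A single
#' lower-case letter in the repeat marks a variable position that is
#' substituted per heptad from \code{fills} (N- to C-terminal order), e.g.
#' repeat \code{"LKEIAfA"} with fills Q, K, W, Q.
#'
#' @param heptad 7-character repeat, positions a-g
#' @param nHeptads number of heptad copies (>= 1)
#' @param fills character vector of per-heptad substitutions for the
#'   variable position (length \code{nHeptads}), or NULL
#' @return amino-acid string of length 7 * nHeptads
#' @examples
#' buildSequence("LKEIAfA", 4, fills = c("Q", "K", "W", "Q"))
#' @export
buildSequence <- function(heptad, nHeptads, fills = NULL) {
  if (nchar(heptad) != 7) stop("heptad repeat must have 7 characters")
  if (nHeptads < 1) stop("nHeptads must be >= 1")
  chars <- strsplit(heptad, "")[[1]]
  lower <- which(chars %in% letters)
  if (length(lower) > 1) stop("at most one variable (lower-case) position allowed")
  if (length(lower) == 1) {
    if (is.null(fills) || length(fills) != nHeptads)
      stop("fills must have one entry per heptad (", nHeptads, ")")
    if (any(nchar(fills) != 1)) stop("fills must be single letters")
  }
  up <- toupper(chars)
  if (!all(up %in% names(.AA3))) stop("unknown amino-acid code in repeat")
  out <- character(nHeptads)
  for (h in seq_len(nHeptads)) {
    cc <- up
    if (length(lower) == 1) cc[lower] <- toupper(fills[h])
    out[h] <- paste(cc, collapse = "")
  }
  paste(out, collapse = "")
}

# --- ideal-helix template offsets -------------------------------------------

# Local orthonormal frame at CA_i from the flanking C-alphas: e1 points from
# CA toward the helix axis (bisector), e2 along the chain, e3 = e1 x e2.
.caFrame <- function(caPrev, ca, caNext) {
  e2 <- unitVec(caNext - caPrev)
  b <- (caPrev + caNext) / 2 - ca
  b <- b - sum(b * e2) * e2
  e1 <- unitVec(b)
  e3 <- crossProd3(e1, e2)
  rbind(e1, e2, e3)
}

.templateCache <- new.env(parent = emptyenv())

# Mean offsets of backbone N, C, O from CA expressed in the local CA frame,
# measured on a NeRF-built ideal alpha-helix (phi -57.8, psi -47.0).
.helixFrameOffsets <- function() {
  if (!is.null(.templateCache$offsets)) return(.templateCache$offsets)
  L <- 13
  phi <- -57.8; psi <- -47.0
  N <- matrix(NA_real_, L, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- nerfPlace(c(0, 1, 0), N[1, ], CA[1, ], 1.525, 111.2, 60)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
    CA[i + 1, ] <- nerfPlace(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- nerfPlace(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2, phi)
    O[i, ] <- nerfPlace(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
  }
  O[L, ] <- nerfPlace(N[L, ], CA[L, ], C[L, ], 1.231, 120.5, psi + 180)
  idx <- 4:(L - 3)
  acc <- list(N = 0, C = 0, O = 0)
  for (i in idx) {
    F <- .caFrame(CA[i - 1, ], CA[i, ], CA[i + 1, ])
    acc$N <- acc$N + as.numeric(F %*% (N[i, ] - CA[i, ]))
    acc$C <- acc$C + as.numeric(F %*% (C[i, ] - CA[i, ]))
    acc$O <- acc$O + as.numeric(F %*% (O[i, ] - CA[i, ]))
  }
  off <- lapply(acc, function(v) v / length(idx))
  .templateCache$offsets <- off
  off
}

# Complete backbone (N, C, O, CB) around a C-alpha trace. Terminal residues
# borrow the frame of their nearest interior neighbour.
.completeBackbone <- function(ca, resnames) {
  n <- nrow(ca)
  off <- .helixFrameOffsets()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ip <- min(max(i, 2), n - 1)
    F <- .caFrame(ca[ip - 1, ], ca[ip, ], ca[ip + 1, ])
    Ni <- ca[i, ] + as.numeric(t(F) %*% off$N)
    Ci <- ca[i, ] + as.numeric(t(F) %*% off$C)
    Oi <- ca[i, ] + as.numeric(t(F) %*% off$O)
    ats <- rbind(N = Ni, CA = ca[i, ], C = Ci, O = Oi)
    if (resnames[i] != "GLY") ats <- rbind(ats, CB = placeCB(Ni, ca[i, ], Ci))
    rows[[i]] <- ats
  }
  rows
}

# Assemble an atoms data.frame from a list of chains, each a list of
# per-residue coordinate matrices with rownames = atom names.
.atomsFromChains <- function(chains, sequences) {
  out <- list()
  for (ci in seq_along(chains)) {
    ch <- names(chains)[ci]
    seq1 <- strsplit(sequences[[ci]], "")[[1]]
    for (ri in seq_along(chains[[ci]])) {
      m <- chains[[ci]][[ri]]
      out[[length(out) + 1]] <- data.frame(
        chain = ch, resno = ri, resname = .AA3[[seq1[ri]]],
        elety = rownames(m), elesy = atomElement(rownames(m)),
        x = m[, 1], y = m[, 2], z = m[, 3], o = 1,
        stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, out)
  rownames(atoms) <- NULL
  atoms
}

#' Build an idealized coiled-coil barrel
#'
#' Traces each chain's C-alpha positions on the Crick
#' minor-helix-on-superhelix curve, completes the backbone (N, C, O, CB)
#' from ideal internal coordinates, and adds side-chain-centroid (SCC)
#' pseudoatoms. With default phases and zero slips the model is exactly
#' Cn-symmetric under rotation by 360/n about the z axis.
#'
#' @param params a \code{\link{crickParams}} object
#' @param sequence amino-acid string (length >= 7) used for every chain
#' @param registerOffset 0-6; which heptad position residue 1 occupies
#'   (0 = a)
#' @return a \linkS4class{StructureModel}
#' @examples
#' m <- buildBarrel(crickParams(6), buildSequence("IAAIAAA", 4))
#' residueCount(m, perChain = TRUE)
#' @export
buildBarrel <- function(params, sequence, registerOffset = 0) {
  stopifnot(inherits(params, "CrickParams"))
  L <- nchar(sequence)
  if (L < 7) stop("sequence must have at least 7 residues")
  fr <- .crickFrequencies(params)
  t <- seq_len(L) - 1
  chains <- list()
  zmid <- fr$dz * (L - 1) / 2
  for (k in seq_len(params$nHelices)) {
    theta <- deg2rad(params$phases[k]) + fr$w0 * t
    z <- fr$dz * t + params$zSlips[k]
    u <- cbind(cos(theta), sin(theta), 0)
    tangent <- cbind(-params$r0 * fr$w0 * sin(theta),
                     params$r0 * fr$w0 * cos(theta),
                     fr$dz)
    tangent <- tangent / sqrt(rowSums(tangent^2))
    v <- cbind(tangent[, 2] * u[, 3] - tangent[, 3] * u[, 2],
               tangent[, 3] * u[, 1] - tangent[, 1] * u[, 3],
               tangent[, 1] * u[, 2] - tangent[, 2] * u[, 1])
    psi <- deg2rad(params$phi1) + fr$w1 * (t + registerOffset)
    ca <- cbind(params$r0 * cos(theta), params$r0 * sin(theta), z) +
      params$r1 * (cos(psi) * u + sin(psi) * v)
    if (params$orientations[k] == -1L) {
      phiMid <- deg2rad(params$phases[k]) + fr$w0 * (L - 1) / 2
      ax <- c(cos(phiMid), sin(phiMid), 0)
      R <- rotationAboutAxis(ax, 180)
      cz <- c(0, 0, zmid + params$zSlips[k])
      ca <- sweep(sweep(ca, 2, cz) %*% t(R), 2, -cz)
    }
    resnames <- .AA3[strsplit(sequence, "")[[1]]]
    chains[[LETTERS[k]]] <- .completeBackbone(ca, resnames)
  }
  atoms <- .atomsFromChains(chains, rep(list(sequence), params$nHelices))
  model <- new("StructureModel", atoms = atoms,
               source = sprintf("crick-barrel-n%d-r0%.2f", params$nHelices,
                                params$r0), model = 1L)
  placeCentroids(model)
}

# A single straight ideal alpha-helix along +z, length L residues, with its
# axis through the origin; psi0 orients residue 1.
.straightHelixCA <- function(L, r1 = 2.26, rise = 1.51, psi0 = 0,
                             twist = 360 / 3.6) {
  t <- seq_len(L) - 1
  psi <- deg2rad(psi0 + twist * t)
  cbind(r1 * cos(psi), r1 * sin(psi), rise * t - rise * (L - 1) / 2)
}

#' Build a collapsed (non-barrel) bundle fixture
#'
#' Two deterministic low-symmetry arrangements used to emulate collapsed
#' coiled-coil folds: \code{"two_sheet"} places two linear 3-helix sheets
#' related by an exact 180-degree rotation about an axis perpendicular to
#' the helices (C2, antiparallel sheets); \code{"docked"} places n-1
#' helices on a circular arc with incremental axial slips plus one helix
#' translated into the concave face, so that only the identity symmetry
#' remains and the lumen is fully occluded.
#'
#' @param params a \code{\link{crickParams}} object (nHelices in 5..8)
#' @param sequence amino-acid string used for every chain
#' @param arrangement \code{"two_sheet"} or \code{"docked"}
#' @param spacing helix-helix axial separation within a sheet/arc (A)
#' @param gap inter-sheet spacing for \code{"two_sheet"} (A)
#' @return a \linkS4class{StructureModel}
#' @export
buildCollapsed <- function(params, sequence,
                           arrangement = c("two_sheet", "docked"),
                           spacing = 9.6, gap = 9.0) {
  arrangement <- match.arg(arrangement)
  n <- params$nHelices
  if (!n %in% 5:8) stop("collapsed fixtures support 5-8 helices")
  L <- nchar(sequence)
  if (L < 7) stop("sequence must have at least 7 residues")
  resnames <- .AA3[strsplit(sequence, "")[[1]]]
  chains <- list()
  if (arrangement == "two_sheet") {
    if (n %% 2 != 0) stop("two_sheet needs an even helix count")
    half <- n / 2
    xs <- (seq_len(half) - (half + 1) / 2) * spacing
    R2 <- rotationAboutAxis(c(1, 0, 0), 180)
    for (k in seq_len(half)) {
      ca <- .straightHelixCA(L, r1 = params$r1, rise = params$rise,
                             psi0 = 60 * k)
      ca[, 1] <- ca[, 1] + xs[k]
      ca[, 2] <- ca[, 2] + gap / 2
      chains[[LETTERS[k]]] <- .completeBackbone(ca, resnames)
      chains[[LETTERS[half + k]]] <- .completeBackbone(ca %*% t(R2), resnames)
    }
  } else {
    r0 <- params$r0
    for (k in seq_len(n - 1)) {
      ang <- 2 * pi * (k - 1) / n
      ca <- .straightHelixCA(L, r1 = params$r1, rise = params$rise,
                             psi0 = rad2deg(ang) + 180)
      ca[, 1] <- ca[, 1] + r0 * cos(ang)
      ca[, 2] <- ca[, 2] + r0 * sin(ang)
      ca[, 3] <- ca[, 3] + 0.8 * (k - 1)
      chains[[LETTERS[k]]] <- .completeBackbone(ca, resnames)
    }
    ca <- .straightHelixCA(L, r1 = params$r1, rise = params$rise, psi0 = 90)
    ca[, 3] <- ca[, 3] + 0.8 * (n - 2) / 2
    chains[[LETTERS[n]]] <- .completeBackbone(ca, resnames)
  }
  atoms <- .atomsFromChains(chains, rep(list(sequence), n))
  model <- new("StructureModel", atoms = atoms,
               source = sprintf("collapsed-%s-n%d", arrangement, n),
               model = 1L)
  placeCentroids(model)
}

#' Place side-chain-centroid pseudoatoms
#'
#' Adds (or replaces) one \code{"SCC"} pseudoatom per residue, positioned
#' along the CA-to-CB direction at a residue-type-specific distance taken
#' from a table derived once from idealized extended side chains (see
#' \code{\link{sccDistanceTable}}). Glycine's SCC coincides with its CA.
#' These pseudoatoms let the knobs-into-holes search run on models that
#' carry no explicit side chains.
#'
#' @param model a \linkS4class{StructureModel} with CA and CB present
#'   (CA only for Gly)
#' @return the model with SCC pseudoatoms appended per residue
#' @export
placeCentroids <- function(model) {
  stopifnot(is(model, "StructureModel"))
  tab <- sccDistanceTable()
  a <- model@atoms[model@atoms$elety != "SCC", , drop = FALSE]
  key <- paste(a$chain, a$resno, sep = ":")
  pieces <- lapply(split(seq_len(nrow(a)), factor(key, levels = unique(key))),
                   function(rows) {
    res <- a[rows, , drop = FALSE]
    iCA <- which(res$elety == "CA")
    if (length(iCA) != 1) stop("residue ", res$chain[1], ":", res$resno[1],
                               " missing CA")
    caPos <- as.numeric(res[iCA, c("x", "y", "z")])
    rn <- res$resname[1]
    if (rn == "GLY") {
      p <- caPos
    } else {
      iCB <- which(res$elety == "CB")
      if (length(iCB) != 1) stop("residue ", res$chain[1], ":", res$resno[1],
                                 " missing CB (needed for SCC placement)")
      cbPos <- as.numeric(res[iCB, c("x", "y", "z")])
      p <- caPos + tab[[rn]] * unitVec(cbPos - caPos)
    }
    scc <- res[iCA, , drop = FALSE]
    scc$elety <- "SCC"; scc$elesy <- "C"
    scc$x <- p[1]; scc$y <- p[2]; scc$z <- p[3]
    rbind(res, scc)
  })
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  initialize(model, atoms = atoms)
}
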