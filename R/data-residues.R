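# Residue-level chemical reference data: amino-acid code maps, side-chain
# internal-coordinate topologies used for idealized side-chain building, the
# derived side-chain-centroid distance table, and van der Waals radii.

#' @keywords internal
.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA1 <- structure(names(.AA3), names = .AA3)

# Non-standard residues mapped onto a standard parent for geometric analyses
# (e.g. selenomethionine, and dehydro-leucine variants used in synthetic
# peptides). Anything not in .AA3 or this table is dropped at parse time.
.RES_ALIAS <- c(MSE = "MET", SEC = "CYS", HYP = "PRO", DLE = "LEU",
                "2LU" = "LEU", MLE = "LEU")

# Backbone heavy atoms; everything else on a residue is side chain.
.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# van der Waals radii by element (Angstroms).
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Side-chain topology beyond CB: one row per heavy atom in build order.
# Atom D is placed by NeRF from reference atoms (a, b, c) with the given
# bond length |c-D|, bond angle b-c-D and torsion a-b-c-D. chi > 0 means the
# torsion is chi_(chi) + offset, chi = 0 means the torsion is fixed at offset.
.scRow <- function(atom, a, b, c, bond, angle, chi, offset) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = chi, offset = offset, stringsAsFactors = FALSE)
}

.SIDECHAIN_TOPOLOGY <- list(
  GLY = NULL,
  ALA = NULL,
  SER = .scRow("OG", "N", "CA", "CB", 1.417, 110.8, 1, 0),
  CYS = .scRow("SG", "N", "CA", "CB", 1.808, 113.8, 1, 0),
  THR = rbind(.scRow("OG1", "N", "CA", "CB", 1.433, 109.6, 1, 0),
              .scRow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120)),
  VAL = rbind(.scRow("CG1", "N", "CA", "CB", 1.527, 110.5, 1, 0),
              .scRow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, 120)),
  ILE = rbind(.scRow("CG1", "N", "CA", "CB", 1.530, 110.4, 1, 0),
              .scRow("CG2", "N", "CA", "CB", 1.521, 110.5, 1, -120),
              .scRow("CD1", "CA", "CB", "CG1", 1.513, 113.8, 2, 0)),
  LEU = rbind(.scRow("CG", "N", "CA", "CB", 1.530, 116.3, 1, 0),
              .scRow("CD1", "CA", "CB", "CG", 1.521, 110.5, 2, 0),
              .scRow("CD2", "CA", "CB", "CG", 1.521, 110.5, 2, 120)),
  MET = rbind(.scRow("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              .scRow("SD", "CA", "CB", "CG", 1.803, 112.7, 2, 0),
              .scRow("CE", "CB", "CG", "SD", 1.791, 100.9, 3, 0)),
  ASP = rbind(.scRow("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              .scRow("OD1", "CA", "CB", "CG", 1.249, 118.4, 2, 0),
              .scRow("OD2", "CA", "CB", "CG", 1.249, 118.4, 2, 180)),
  ASN = rbind(.scRow("CG", "N", "CA", "CB", 1.516, 112.6, 1, 0),
              .scRow("OD1", "CA", "CB", "CG", 1.231, 120.8, 2, 0),
              .scRow("ND2", "CA", "CB", "CG", 1.328, 116.4, 2, 180)),
  GLU = rbind(.scRow("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              .scRow("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              .scRow("OE1", "CB", "CG", "CD", 1.249, 118.4, 3, 0),
              .scRow("OE2", "CB", "CG", "CD", 1.249, 118.4, 3, 180)),
  GLN = rbind(.scRow("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              .scRow("CD", "CA", "CB", "CG", 1.516, 112.6, 2, 0),
              .scRow("OE1", "CB", "CG", "CD", 1.231, 120.8, 3, 0),
              .scRow("NE2", "CB", "CG", "CD", 1.328, 116.4, 3, 180)),
  LYS = rbind(.scRow("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              .scRow("CD", "CA", "CB", "CG", 1.520, 111.3, 2, 0),
              .scRow("CE", "CB", "CG", "CD", 1.520, 111.3, 3, 0),
              .scRow("NZ", "CG", "CD", "CE", 1.489, 111.9, 4, 0)),
  ARG = rbind(.scRow("CG", "N", "CA", "CB", 1.520, 114.1, 1, 0),
              .scRow("CD", "CA", "CB", "CG", 1.520, 111.3, 2, 0),
              .scRow("NE", "CB", "CG", "CD", 1.461, 112.0, 3, 0),
              .scRow("CZ", "CG", "CD", "NE", 1.329, 124.2, 4, 0),
              .scRow("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0, 0),
              .scRow("NH2", "CD", "NE", "CZ", 1.326, 120.0, 0, 180)),
  HIS = rbind(.scRow("CG", "N", "CA", "CB", 1.497, 113.8, 1, 0),
              .scRow("ND1", "CA", "CB", "CG", 1.371, 122.7, 2, 0),
              .scRow("CD2", "CA", "CB", "CG", 1.356, 129.1, 2, 180),
              .scRow("CE1", "CB", "CG", "ND1", 1.319, 109.3, 0, 180),
              .scRow("NE2", "CB", "CG", "CD2", 1.374, 107.2, 0, 180)),
  PHE = rbind(.scRow("CG", "N", "CA", "CB", 1.502, 113.8, 1, 0),
              .scRow("CD1", "CA", "CB", "CG", 1.384, 120.8, 2, 0),
              .scRow("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, 180),
              .scRow("CE1", "CB", "CG", "CD1", 1.382, 120.8, 0, 180),
              .scRow("CE2", "CB", "CG", "CD2", 1.382, 120.8, 0, 180),
              .scRow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0, 0)),
  TYR = rbind(.scRow("CG", "N", "CA", "CB", 1.502, 113.8, 1, 0),
              .scRow("CD1", "CA", "CB", "CG", 1.384, 120.8, 2, 0),
              .scRow("CD2", "CA", "CB", "CG", 1.384, 120.8, 2, 180),
              .scRow("CE1", "CB", "CG", "CD1", 1.382, 120.8, 0, 180),
              .scRow("CE2", "CB", "CG", "CD2", 1.382, 120.8, 0, 180),
              .scRow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0, 0),
              .scRow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 0, 180)),
  TRP = rbind(.scRow("CG", "N", "CA", "CB", 1.498, 113.6, 1, 0),
              .scRow("CD1", "CA", "CB", "CG", 1.365, 126.9, 2, 0),
              .scRow("CD2", "CA", "CB", "CG", 1.433, 126.6, 2, 180),
              .scRow("NE1", "CB", "CG", "CD1", 1.374, 110.2, 0, 180),
              .scRow("CE2", "CB", "CG", "CD2", 1.409, 107.2, 0, 180),
              .scRow("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0, 0),
              .scRow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 0, 180),
              .scRow("CZ3", "CG", "CD2", "CE3", 1.382, 118.7, 0, 180),
              .scRow("CH2", "CD2", "CE3", "CZ3", 1.368, 121.2, 0, 0)),
  PRO = rbind(.scRow("CG", "N", "CA", "CB", 1.495, 104.5, 0, 30),
              .scRow("CD", "CA", "CB", "CG", 1.507, 106.1, 0, -35))
)

# Number of variable chi torsions per residue type.
.N_CHI <- vapply(.SIDECHAIN_TOPOLOGY, function(t) {
  if (is.null(t)) 0L else as.integer(max(c(0L, t$chi)))
}, integer(1))

# Element symbol from an atom name (leading digits stripped, first letter).
atomElement <- function(elety) {
  e <- sub("^[0-9]*", "", elety)
  substr(e, 1, 1)
}

# CB placement constants for L-amino acids: NeRF along the N -> C -> CA path.
.CB_BOND <- 1.530
.CB_ANGLE <- 110.5   # C-CA-CB
.CB_TORSION <- 122.5 # N-C-CA-CB improper, positive for L-chirality

placeCB <- function(N, CA, C) nerfPlace(N, C, CA, .CB_BOND, .CB_ANGLE, .CB_TORSION)

# Build the side-chain heavy atoms of one residue type at given chi angles.
# Returns a matrix with rownames = atom names (beyond CB), or NULL.
buildSideChain <- function(resname, N, CA, CB, chis = NULL) {
  topo <- .SIDECHAIN_TOPOLOGY[[resname]]
  if (is.null(topo)) return(NULL)
  nchi <- .N_CHI[[resname]]
  if (is.null(chis)) chis <- rep(180, nchi)
  if (length(chis) < nchi) stop("residue ", resname, " needs ", nchi, " chi angles")
  pos <- list(N = N, CA = CA, CB = CB)
  out <- matrix(NA_real_, nrow(topo), 3, dimnames = list(topo$atom, NULL))
  for (i in seq_len(nrow(topo))) {
    r <- topo[i, ]
    tor <- if (r$chi > 0) chis[r$chi] + r$offset else r$offset
    p <- nerfPlace(pos[[r$a]], pos[[r$b]], pos[[r$c]], r$bond, r$angle, tor)
    pos[[r$atom]] <- p
    out[i, ] <- p
  }
  out
}

# Distance from CA to the side-chain heavy-atom centroid for each residue
# type, computed once from idealized extended side chains (all chi = 180)
# built on a reference backbone triad. Gly is 0 by the Gly -> CA convention.
.sccCache <- new.env(parent = emptyenv())

sccDistanceTable <- function() {
  if (!is.null(.sccCache$table)) return(.sccCache$table)
  # reference backbone triad with ideal internal geometry
  N <- c(0, 0, 0)
  CA <- c(1.458, 0, 0)
  C <- nerfPlace(c(0, -1, 0), N, CA, 1.525, 111.2, -120)
  CB <- placeCB(N, CA, C)
  tab <- vapply(names(.SIDECHAIN_TOPOLOGY), function(rn) {
    if (rn == "GLY") return(0)
    sc <- buildSideChain(rn, N, CA, CB)
    atoms <- rbind(CB, sc)
    vecNorm(colMeans(atoms) - CA)
  }, numeric(1))
  .sccCache$table <- tab
  tab
}
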