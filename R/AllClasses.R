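#' @import methods
NULL

#' StructureModel: a single-model protein structure
#'
#' Container for one coordinate model of a (typically homomeric) protein
#' assembly. Atoms are held in a flat table with one row per heavy atom;
#' waters, ions and other heteroatoms are excluded at parse time, and only
#' the 20 standard amino acids (plus a small alias table of modified
#' residues mapped to standard parents) are retained.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno} (author
#'   numbering), \code{resname} (3-letter code), \code{elety} (atom name),
#'   \code{elesy} (element), \code{x}, \code{y}, \code{z} (Angstroms) and
#'   \code{o} (occupancy).
#' @slot source character identifier of the model's origin (file name,
#'   accession, or generator description).
#' @slot model integer model number retained from the source (always a
#'   single model).
#'
#' @export
setClass("StructureModel",
  representation(atoms = "data.frame", source = "character",
                 model = "integer"),
  prototype(atoms = data.frame(), source = "unknown", model = 1L)
)

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "elety", "elesy", "x", "y", "z", "o")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) > 0 && any(!is.finite(c(a$x, a$y, a$z))))
    return("atom coordinates must be finite")
  if (nrow(a) > 0 && any(!nzchar(a$elesy)))
    return("every atom needs a non-empty element symbol")
  TRUE
})

#' HelixSegment: a detected alpha-helical run with a fitted local axis
#'
#' @slot chain chain identifier the segment belongs to.
#' @slot resno integer vector of author residue numbers, ordered N to C.
#' @slot ca numeric matrix (n x 3) of C-alpha coordinates.
#' @slot axisPoints numeric matrix of local axis points (one per interior
#'   residue of the fitting window), ordered N to C.
#' @slot axisDir unit 3-vector pointing N to C along the mean axis.
#'
#' @export
setClass("HelixSegment",
  representation(chain = "character", resno = "integer", ca = "matrix",
                 axisPoints = "matrix", axisDir = "numeric")
)

setValidity("HelixSegment", function(object) {
  if (length(object@resno) < 7)
    return("a helix segment must span at least 7 residues")
  if (length(object@axisDir) != 3)
    return("axisDir must be a 3-vector")
  if (abs(vecNorm(object@axisDir) - 1) > 1e-9)
    return("axisDir must be a unit vector")
  TRUE
})

#' RigidTransform: a proper rigid-body map with screw decomposition
#'
#' @slot rotation 3x3 proper orthonormal matrix.
#' @slot translation length-3 numeric vector (Angstroms).
#' @slot rotationAngle rotation angle in degrees, in [0, 180].
#' @slot screwTranslation translation component along the rotation axis
#'   (Angstroms, signed).
#' @slot axis unit rotation axis.
#'
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 rotationAngle = "numeric", screwTranslation = "numeric",
                 axis = "numeric")
)

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
  if (abs(det(R) - 1) > 1e-6) return("rotation must be proper (det = +1)")
  if (max(abs(t(R) %*% R - diag(3))) > 1e-6) return("rotation must be orthonormal")
  if (object@rotationAngle < -1e-9 || object@rotationAngle > 180 + 1e-9)
    return("rotationAngle must lie in [0, 180]")
  TRUE
})

#' SymmetryReport: internal symmetry classification of a helix assembly
#'
#' @slot label one of \code{"Cn"}, \code{"Dn"}, \code{"screw"}, \code{"E"}.
#' @slot rotationOrder integer rotational order (NA for screw/E).
#' @slot meanRotation mean rotation angle of the generating maps (degrees).
#' @slot meanScrew mean axial translation of the generating maps (Angstroms).
#' @slot orientationPattern \code{"all-parallel"} or \code{"mixed"}.
#' @slot ops data.frame of the accepted chain-to-chain maps.
#'
#' @export
setClass("SymmetryReport",
  representation(label = "character", rotationOrder = "integer",
                 meanRotation = "numeric", meanScrew = "numeric",
                 orientationPattern = "character", ops = "data.frame")
)

setValidity("SymmetryReport", function(object) {
  if (!object@label %in% c("Cn", "Dn", "screw", "E"))
    return("label must be one of Cn, Dn, screw, E")
  TRUE
})

#' SpecificityMatrix: sequences x structures normalized threading scores
#'
#' Each cell holds the mean per-chain score of a sequence threaded onto a
#' structure, normalised row-wise by subtracting the score of the sequence
#' on its cognate structure, so every cognate cell is exactly zero and
#' positive values mean a worse-than-cognate fit.
#'
#' @slot values normalized score matrix (rows = sequences, cols = structures).
#' @slot raw raw mean per-chain scores on the same layout.
#' @slot sd per-cell standard deviation of per-chain scores.
#' @slot cognate named character vector mapping sequence id to structure id.
#' @slot score score type used, \code{"steric"} or \code{"total"}.
#'
#' @export
setClass("SpecificityMatrix",
  representation(values = "matrix", raw = "matrix", sd = "matrix",
                 cognate = "character", score = "character")
)

setValidity("SpecificityMatrix", function(object) {
  v <- object@values
  if (!all(dim(v) == dim(object@raw))) return("values and raw must share shape")
  if (!all(names(object@cognate) %in% rownames(v)))
    return("cognate names must be row names")
  diagOK <- vapply(rownames(v), function(s) {
    cg <- object@cognate[[s]]
    is.na(v[s, cg]) || identical(v[s, cg], 0)
  }, logical(1))
  if (!all(diagOK)) return("cognate cells must be exactly zero")
  TRUE
})

#' PoreProfile: lumen radius along a bundle axis
#'
#' @slot stations numeric vector of axial coordinates (Angstroms), increasing.
#' @slot radius numeric vector of pore radii at each station; values <= 0
#'   mean the station is occluded.
#' @slot axisOrigin point on the channel axis.
#' @slot axisDir unit direction of the channel axis.
#' @slot convention \code{"vdw"} (radius measured to atom surfaces) or
#'   \code{"center"} (to atom centers).
#'
#' @export
setClass("PoreProfile",
  representation(stations = "numeric", radius = "numeric",
                 axisOrigin = "numeric", axisDir = "numeric",
                 convention = "character")
)

setValidity("PoreProfile", function(object) {
  if (length(object@stations) != length(object@radius))
    return("stations and radius must have equal length")
  if (is.unsorted(object@stations, strictly = TRUE))
    return("stations must be strictly increasing")
  if (any(!is.finite(object@radius))) return("radius values must be finite")
  TRUE
})

#' PolyproticModel: macroscopic stepwise description of an x-site cluster
#'
#' A cluster of x interacting titratable sites treated as a single
#' polyprotic acid with ordered macroscopic stepwise pKa values and
#' optional per-transition Hill coefficients.
#'
#' @slot pka numeric vector of x non-decreasing stepwise pKa values.
#' @slot hill numeric vector of x positive Hill coefficients (default 1).
#'
#' @export
setClass("PolyproticModel",
  representation(pka = "numeric", hill = "numeric")
)

setValidity("PolyproticModel", function(object) {
  if (length(object@pka) < 1) return("at least one site required")
  if (is.unsorted(object@pka)) return("pKa values must be non-decreasing")
  if (length(object@hill) != length(object@pka))
    return("hill must match pka in length")
  if (any(object@hill <= 0)) return("hill coefficients must be positive")
  TRUE
})

#' ChargeStateSeries: per-pH charge-state sample counts
#'
#' Tabulated charge-state statistics of a titratable cluster, one row per
#' pH value and one column per number of deprotonated sites (0..x), as
#' produced by constant-pH simulation post-processing or by
#' \code{\link{simulateChargeSeries}}.
#'
#' @slot pH numeric grid of pH values.
#' @slot counts integer matrix (length(pH) x (x+1)) of observed samples.
#' @slot meta list of provenance metadata (seed, correlation, ...).
#'
#' @export
setClass("ChargeStateSeries",
  representation(pH = "numeric", counts = "matrix", meta = "list"),
  prototype(meta = list())
)

setValidity("ChargeStateSeries", function(object) {
  if (nrow(object@counts) != length(object@pH))
    return("counts must have one row per pH")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' TitrationFit: fitted macroscopic stepwise pKa values
#'
#' @slot pka fitted non-decreasing stepwise pKa values.
#' @slot hill fitted (or fixed) Hill coefficients.
#' @slot ci matrix of bootstrap intervals (2 x length(pka)) or 0-row matrix.
#' @slot rss residual sum of squares of the fit.
#' @slot converged logical convergence flag.
#' @slot identifiable logical; FALSE when the data carry no information on
#'   one or more transitions (midpoints outside the pH grid).
#'
#' @export
setClass("TitrationFit",
  representation(pka = "numeric", hill = "numeric", ci = "matrix",
                 rss = "numeric", converged = "logical",
                 identifiable = "logical")
)

setValidity("TitrationFit", function(object) {
  if (is.unsorted(object@pka + 1e-9)) return("fitted pKa must be non-decreasing")
  TRUE
})
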