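#' @include AllClasses.R
NULL

#' Chain identifiers of a structure
#' @param x a \linkS4class{StructureModel}
#' @return character vector of chain ids in file order
#' @export
setGeneric("chainIDs", function(x) standardGeneric("chainIDs"))

#' Atom table of a structure
#' @param x a \linkS4class{StructureModel}
#' @return the flat atom data.frame
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Number of residues (per chain or total)
#' @param x a \linkS4class{StructureModel}
#' @param perChain logical; return a per-chain table?
#' @export
setGeneric("residueCount", function(x, perChain = FALSE) standardGeneric("residueCount"))

#' @rdname chainIDs
#' @export
setMethod("chainIDs", "StructureModel", function(x) unique(x@atoms$chain))

#' @rdname atomTable
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

#' @rdname residueCount
#' @export
setMethod("residueCount", "StructureModel", function(x, perChain = FALSE) {
  key <- paste(x@atoms$chain, x@atoms$resno)
  if (!perChain) return(length(unique(key)))
  vapply(split(x@atoms$resno, x@atoms$chain), function(r) length(unique(r)),
         integer(1))
})

setMethod("show", "StructureModel", function(object) {
  rc <- residueCount(object, perChain = TRUE)
  cat("StructureModel:", object@source, "\n")
  cat(" ", length(rc), "chain(s) [", paste(names(rc), collapse = " "), "],",
      sum(rc), "residues,", nrow(object@atoms), "atoms\n")
})

setMethod("show", "HelixSegment", function(object) {
  cat(sprintf("HelixSegment %s:%d-%d (%d residues), axis [% .3f % .3f % .3f]\n",
              object@chain, object@resno[1], object@resno[length(object@resno)],
              length(object@resno), object@axisDir[1], object@axisDir[2],
              object@axisDir[3]))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rotation %.2f deg, screw %.3f A\n",
              object@rotationAngle, object@screwTranslation))
})

setMethod("show", "SymmetryReport", function(object) {
  lab <- object@label
  if (lab %in% c("Cn", "Dn") && !is.na(object@rotationOrder))
    lab <- sub("n", object@rotationOrder, lab)
  cat(sprintf("SymmetryReport: %s (rotation %.2f deg, screw %.3f A, %s)\n",
              lab, object@meanRotation, object@meanScrew,
              object@orientationPattern))
})

setMethod("show", "SpecificityMatrix", function(object) {
  cat(sprintf("SpecificityMatrix (%s score): %d sequences x %d structures\n",
              object@score, nrow(object@values), ncol(object@values)))
  print(round(object@values, 2))
})

setMethod("show", "PoreProfile", function(object) {
  r <- object@radius
  cat(sprintf("PoreProfile (%s): %d stations, radius %.2f to %.2f A\n",
              object@convention, length(r), min(r), max(r)))
})

setMethod("show", "PolyproticModel", function(object) {
  cat("PolyproticModel with", length(object@pka), "sites\n")
  cat("  pKa:", paste(sprintf("%.2f", object@pka), collapse = ", "), "\n")
  if (any(object@hill != 1))
    cat("  hill:", paste(sprintf("%.2f", object@hill), collapse = ", "), "\n")
})

setMethod("show", "ChargeStateSeries", function(object) {
  cat(sprintf("ChargeStateSeries: %d pH values (%.1f-%.1f), %d charge states, n=%d samples/pH\n",
              length(object@pH), min(object@pH), max(object@pH),
              ncol(object@counts), sum(object@counts[1, ])))
})

setMethod("show", "TitrationFit", function(object) {
  cat("TitrationFit:", if (object@converged) "converged" else "NOT converged",
      if (!object@identifiable) "(unidentifiable transitions present)" else "", "\n")
  cat("  pKa:", paste(sprintf("%.3f", object@pka), collapse = ", "), "\n")
  if (nrow(object@ci) == 2)
    cat("  95% CI half-widths:",
        paste(sprintf("%.3f", (object@ci[2, ] - object@ci[1, ]) / 2),
              collapse = ", "), "\n")
  cat("  RSS:", format(object@rss, digits = 4), "\n")
})

#' Fitted macroscopic pKa values
#' @param object a \linkS4class{TitrationFit} or \linkS4class{PolyproticModel}
#' @export
setGeneric("pkaValues", function(object) standardGeneric("pkaValues"))

#' @rdname pkaValues
#' @export
setMethod("pkaValues", "TitrationFit", function(object) object@pka)

#' @rdname pkaValues
#' @export
setMethod("pkaValues", "PolyproticModel", function(object) object@pka)

#' Normalized values of a specificity matrix
#' @param object a \linkS4class{SpecificityMatrix}
#' @param raw logical; return raw (un-normalized) mean per-chain scores?
#' @export
setGeneric("scoreMatrix", function(object, raw = FALSE) standardGeneric("scoreMatrix"))

#' @rdname scoreMatrix
#' @export
setMethod("scoreMatrix", "SpecificityMatrix", function(object, raw = FALSE) {
  if (raw) object@raw else object@values
})
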