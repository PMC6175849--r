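# Pore/channel geometry of alpha-helical barrels: bundle axis estimation,
# slab-minimum radius profile along the axis, and open/closed summaries.

#' Principal axis of a helix bundle
#'
#' Largest-variance direction of the pooled helix axis points (each
#' helix's points centred on its own centroid first, so that the radial
#' arrangement of the helices around the bundle cannot outweigh the axial
#' spread), anchored at the overall centroid; the direction sign follows
#' the majority helix direction.
#'
#' @param model a \linkS4class{StructureModel} (provenance only)
#' @param helices list of >= 3 \linkS4class{HelixSegment}
#' @return list with \code{origin} and unit \code{direction}
#' @export
barrelAxis <- function(model, helices) {
  if (length(helices) < 3)
    stop("need at least 3 helices for a bundle axis; use the helix axis directly")
  pts <- do.call(rbind, lapply(helices, function(h) h@axisPoints))
  ctr <- colMeans(pts)
  centred <- do.call(rbind, lapply(helices, function(h)
    sweep(h@axisPoints, 2, colMeans(h@axisPoints))))
  sv <- svd(centred)
  dir <- sv$v[, 1]
  majority <- colSums(t(vapply(helices, function(h) h@axisDir, numeric(3))))
  if (sum(dir * majority) < 0) dir <- -dir
  list(origin = ctr, direction = unitVec(dir))
}

#' Pore radius profile along an axis
#'
#' At stations spaced \code{step} apart along the axial extent of the
#' model, the pore radius is the minimum over heavy atoms within
#' \code{slab} of the station of (radial distance to the axis minus the
#' atom's van der Waals radius); stations with no atoms in the slab are
#' skipped. Radii of zero or below mean the axis is occluded. With
#' \code{convention = "center"} the vdW subtraction is omitted
#' (atom-center radius).
#'
#' @param model a \linkS4class{StructureModel}
#' @param axis list with \code{origin} and \code{direction} (from
#'   \code{\link{barrelAxis}})
#' @param step station spacing in Angstroms (default 0.5)
#' @param slab half-thickness of the axial slab in Angstroms (default 1.0)
#' @param convention \code{"vdw"} (default) or \code{"center"}
#' @param excludePseudo drop SCC pseudoatoms (default TRUE)
#' @return a \linkS4class{PoreProfile}
#' @export
poreProfile <- function(model, axis, step = 0.5, slab = 1.0,
                        convention = c("vdw", "center"),
                        excludePseudo = TRUE) {
  convention <- match.arg(convention)
  a <- model@atoms
  if (excludePseudo) a <- a[a$elety != "SCC", , drop = FALSE]
  if (nrow(a) == 0) stop("empty model")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rel <- sweep(xyz, 2, axis$origin)
  zc <- as.numeric(rel %*% axis$direction)
  radial <- sqrt(pmax(rowSums(rel^2) - zc^2, 0))
  rv <- if (convention == "vdw") vdwRadius(a$elesy) else 0
  eff <- radial - rv
  stations <- seq(min(zc), max(zc), by = step)
  keep <- logical(length(stations))
  radius <- numeric(length(stations))
  for (i in seq_along(stations)) {
    inSlab <- abs(zc - stations[i]) <= slab
    if (!any(inSlab)) next
    keep[i] <- TRUE
    radius[i] <- min(eff[inSlab])
  }
  new("PoreProfile", stations = stations[keep], radius = radius[keep],
      axisOrigin = axis$origin, axisDir = axis$direction,
      convention = convention)
}

#' Summarise a pore profile
#'
#' Minimum and maximum pore diameter (2 x radius) over the central window
#' of the axial span, and an open/closed call: the channel is open when
#' the minimum radius in the window exceeds \code{openThreshold}.
#'
#' @param profile a \linkS4class{PoreProfile}
#' @param centralWindow fraction of the axial span summarised (default
#'   0.7, centred)
#' @param openThreshold minimum radius (A) for an open call (default 0.5)
#' @return list with \code{minDiameter}, \code{maxDiameter} (A) and
#'   \code{open}
#' @export
poreSummary <- function(profile, centralWindow = 0.7, openThreshold = 0.5) {
  z <- profile@stations
  zmid <- (min(z) + max(z)) / 2
  half <- (max(z) - min(z)) * centralWindow / 2
  inWin <- abs(z - zmid) <= half
  if (sum(inWin) < 3) stop("fewer than 3 stations in the central window")
  r <- profile@radius[inWin]
  list(minDiameter = 2 * min(r), maxDiameter = 2 * max(r),
       open = min(r) > openThreshold)
}
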