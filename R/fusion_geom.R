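# Fusion-enzyme geometric descriptors.
#
# For an artificial two-enzyme fusion, two descriptors summarise the
# relative placement of the active sites on a predicted structure: the
# inter-tunnel centroid distance D_IC and the inter-segment angle O_IC.
# Tunnels and segments are defined by user-supplied anchor atoms; the
# package computes geometry only and does not detect tunnels.

#' Define an anchor set
#'
#' A labelled group of selectors that together resolve to >= 1 atom; the
#' anchor point is the unweighted centroid of the resolved atoms.
#'
#' @param label anchor label
#' @param selectors a [Selector-class] or list of selectors
#' @return an \code{anchorSet} list
#' @export
anchorSet <- function(label, selectors) {
  if (is(selectors, "Selector")) selectors <- list(selectors)
  stopifnot(length(selectors) >= 1,
            all(vapply(selectors, is, logical(1), class2 = "Selector")))
  structure(list(label = label, selectors = selectors), class = "anchorSet")
}

#' Define a line segment between two anchor centroids
#'
#' @param label segment label
#' @param startAnchor,endAnchor [anchorSet()] objects with distinct
#'   centroids
#' @return a \code{segmentSpec} list
#' @export
segmentSpec <- function(label, startAnchor, endAnchor) {
  stopifnot(inherits(startAnchor, "anchorSet"), inherits(endAnchor, "anchorSet"))
  structure(list(label = label, start = startAnchor, end = endAnchor),
            class = "segmentSpec")
}

#' Centroid of an anchor set
#'
#' @param ens an [Ensemble-class]
#' @param anchors an [anchorSet()]
#' @param frame frame position (default 1)
#' @return length-3 numeric vector (Angstrom)
#' @export
centroid <- function(ens, anchors, frame = 1L) {
  idx <- unique(unlist(lapply(anchors$selectors, function(s)
    selectAtoms(ens, s))))
  if (length(idx) == 0L)
    stop(sprintf("anchor '%s' resolved to no atoms", anchors$label),
         call. = FALSE)
  xyz <- ens@coords[idx, , frame, drop = FALSE]
  colMeans(matrix(xyz, ncol = 3))
}

#' Inter-tunnel centroid distance D_IC
#'
#' Euclidean distance (Angstrom) between the centroids of the two tunnel
#' anchor sets. Symmetric in its anchors and invariant under rigid motions
#' of the frame.
#'
#' @param ens an [Ensemble-class]
#' @param tunnelA,tunnelB [anchorSet()] objects
#' @param frame frame position (default 1)
#' @return distance in Angstrom
#' @export
dIC <- function(ens, tunnelA, tunnelB, frame = 1L) {
  ca <- centroid(ens, tunnelA, frame)
  cb <- centroid(ens, tunnelB, frame)
  sqrt(sum((ca - cb)^2))
}

#' Inter-segment angle O_IC
#'
#' Orientation-sensitive angle in [0, 180] degrees between the direction
#' vectors (end - start) of two segments; antiparallel segments give 180,
#' not 0, so near-straight tandem arrangements are representable.
#'
#' @param ens an [Ensemble-class]
#' @param segX,segY [segmentSpec()] objects
#' @param frame frame position (default 1)
#' @return angle in degrees
#' @export
oIC <- function(ens, segX, segY, frame = 1L) {
  dir_of <- function(seg) {
    v <- centroid(ens, seg$end, frame) - centroid(ens, seg$start, frame)
    if (sqrt(sum(v^2)) < 1e-9)
      stop(sprintf("degenerate segment '%s': endpoint centroids coincide",
                   seg$label), call. = FALSE)
    v
  }
  vx <- dir_of(segX)
  vy <- dir_of(segY)
  angleDeg(vx, c(0, 0, 0), vy)
}
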