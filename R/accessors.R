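# Constructors and accessors for the core S4 objects.

#' Construct an Ensemble
#'
#' Low-level constructor; most users obtain ensembles from [parsePDB()] or
#' [generateEnsemble()].
#'
#' @param atoms data.frame with columns serial, name, resname, chain,
#'   resseq, element
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (Angstrom)
#' @param frameIndex integer model numbers (default \code{1:n_frames})
#' @return an [Ensemble-class]
#' @export
Ensemble <- function(atoms, coords, frameIndex = NULL) {
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(dim(coords), 1L))
  if (is.null(frameIndex)) frameIndex <- seq_len(dim(coords)[3])
  new("Ensemble", atoms = atoms, coords = coords,
      frameIndex = as.integer(frameIndex))
}

#' Construct an atom Selector
#'
#' @param chain chain identifier (optional)
#' @param resseq residue sequence number (optional)
#' @param resname residue name (optional)
#' @param atomNames character vector of atom names (optional)
#' @return a [Selector-class]
#' @examples
#' selector(resseq = 259, atomNames = c("ND1", "NE2"))
#' @export
selector <- function(chain = NA, resseq = NA, resname = NA,
                     atomNames = character(0)) {
  new("Selector",
      chain = as.character(chain),
      resseq = as.integer(resseq),
      resname = as.character(resname),
      atomNames = as.character(atomNames))
}

#' Construct a methylation-site specification
#'
#' @param label site label (e.g. "3'-OH")
#' @param oSel selector for the nucleophile oxygen
#' @param nSels a [Selector-class] or list of selectors for the catalytic
#'   histidine acceptor nitrogen(s)
#' @param c1Sel selector for the SAM methyl carbon C1
#' @param sSel selector for the SAM sulfur S
#' @return a [SiteSpec-class]
#' @export
siteSpec <- function(label, oSel, nSels, c1Sel, sSel) {
  if (is(nSels, "Selector")) nSels <- list(nSels)
  new("SiteSpec", label = label, oSel = oSel, nSels = nSels,
      c1Sel = c1Sel, sSel = sSel)
}

#' Construct a methylation-reactive region
#'
#' @param dMax maximum O-to-N distance in Angstrom (strict bound)
#' @param thetaMin,thetaMax inclusive attack-angle window in degrees
#' @return a [ReactiveRegion-class]
#' @export
reactiveRegion <- function(dMax = 3.5, thetaMin = 125, thetaMax = 170) {
  new("ReactiveRegion", dMax = dMax, thetaMin = thetaMin, thetaMax = thetaMax)
}

#' @rdname ensembleAccessors
#' @name ensembleAccessors
#' @title Ensemble accessors
#' @description Accessor functions for [Ensemble-class] objects: number of
#'   frames and atoms, the atom topology table, the coordinate array, the
#'   frame (model) numbers, a topology fingerprint, and single-frame
#'   extraction.
#' @param ens an [Ensemble-class]
#' @param i frame position (1-based, in storage order)
#' @return \code{nFrames}/\code{nAtoms}: integer; \code{atomData}: the atom
#'   data.frame; \code{coords}: the coordinate array (or an
#'   \code{n_atoms x 3} matrix when \code{i} is given); \code{getFrame}: a
#'   one-frame [Ensemble-class]; \code{topologyKey}: a character scalar that
#'   is equal for ensembles with identical atom topology.
NULL

#' @rdname ensembleAccessors
#' @export
nFrames <- function(ens) dim(ens@coords)[3]

#' @rdname ensembleAccessors
#' @export
nAtoms <- function(ens) nrow(ens@atoms)

#' @rdname ensembleAccessors
#' @export
atomData <- function(ens) ens@atoms

#' @rdname ensembleAccessors
#' @export
coords <- function(ens, i = NULL) {
  if (is.null(i)) ens@coords else ens@coords[, , i, drop = TRUE]
}

#' @rdname ensembleAccessors
#' @export
frameIndices <- function(ens) ens@frameIndex

#' @rdname ensembleAccessors
#' @export
topologyKey <- function(ens) {
  a <- ens@atoms
  paste(a$name, a$resname, a$chain, a$resseq, sep = "|", collapse = ";")
}

#' @rdname ensembleAccessors
#' @export
getFrame <- function(ens, i) {
  stopifnot(i >= 1, i <= nFrames(ens))
  Ensemble(ens@atoms, ens@coords[, , i, drop = FALSE], ens@frameIndex[i])
}
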