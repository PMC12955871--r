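#' @import methods
#' @importFrom stats dnorm pnorm qnorm runif rnorm sd setNames coef approx optim
#' @importFrom utils write.csv read.csv packageVersion
NULL

#' Conformational ensemble with shared atom topology
#'
#' An \code{Ensemble} holds an ordered set of structural frames (e.g. MD
#' snapshots written as a multi-model PDB) that share one atom topology.
#' The topology lives in the \code{atoms} data frame (one row per atom);
#' Cartesian coordinates live in a dense \code{n_atoms x 3 x n_frames}
#' array so that per-frame geometry can be computed vectorised across the
#' whole ensemble.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{resname}, \code{chain}, \code{resseq}, \code{element}; one row
#'   per atom, order is significant and identical in every frame.
#' @slot coords numeric array of dimension \code{c(nrow(atoms), 3, n_frames)},
#'   coordinates in Angstrom.
#' @slot frameIndex integer vector of model numbers, one per frame, unique.
#'
#' @seealso [parsePDB()], [writePDB()], [selectAtoms()], [siteStats()]
#' @export
setClass("Ensemble",
  representation(
    atoms = "data.frame",
    coords = "array",
    frameIndex = "integer"
  )
)

setValidity("Ensemble", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "chain", "resseq", "element")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(a))
    return("coords first dimension must match nrow(atoms)")
  if (d[3] < 1L)
    return("ensemble must contain at least one frame")
  if (length(object@frameIndex) != d[3])
    return("frameIndex length must equal the number of frames")
  if (anyDuplicated(object@frameIndex))
    return("frame indices must be unique")
  if (!all(is.finite(object@coords)))
    return("all coordinates must be finite")
  if (any(!nzchar(a$name)))
    return("atom names must be non-empty")
  if (any(a$serial < 1))
    return("atom serial numbers must be >= 1")
  TRUE
})

#' Atom selector
#'
#' Declarative selection of atoms by chain, residue number, residue name
#' and/or atom name(s). Unset criteria (NA / empty) match everything; at
#' least one criterion must be set. Selection is order-preserving and
#' idempotent.
#'
#' @slot chain single chain identifier or NA
#' @slot resseq residue sequence number or NA
#' @slot resname residue name or NA
#' @slot atomNames character vector of atom names (empty = any)
#' @export
setClass("Selector",
  representation(
    chain = "character",
    resseq = "integer",
    resname = "character",
    atomNames = "character"
  ),
  prototype(chain = NA_character_, resseq = NA_integer_,
            resname = NA_character_, atomNames = character(0))
)

setValidity("Selector", function(object) {
  if (is.na(object@chain) && is.na(object@resseq) &&
      is.na(object@resname) && length(object@atomNames) == 0L)
    return("at least one selection criterion must be set")
  TRUE
})

#' Methylation-site specification
#'
#' Names the four atoms defining the reaction coordinates of one candidate
#' methyl-acceptor site: the nucleophile hydroxyl oxygen, the catalytic
#' histidine acceptor nitrogen(s) (N-delta-1 and/or N-epsilon-2), the SAM
#' methyl carbon C1, and the SAM sulfonium sulfur S. Each selector must
#' resolve to exactly one atom per frame.
#'
#' @slot label site label, e.g. \code{"3'-OH"}
#' @slot oSel [Selector-class] for the nucleophile oxygen
#' @slot nSels list of [Selector-class], one per candidate acceptor nitrogen
#' @slot c1Sel [Selector-class] for the SAM methyl carbon C1
#' @slot sSel [Selector-class] for the SAM sulfur S
#' @export
setClass("SiteSpec",
  representation(
    label = "character",
    oSel = "Selector",
    nSels = "list",
    c1Sel = "Selector",
    sSel = "Selector"
  )
)

setValidity("SiteSpec", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single non-empty string")
  if (length(object@nSels) < 1L)
    return("at least one acceptor-nitrogen selector is required")
  if (!all(vapply(object@nSels, is, logical(1), class2 = "Selector")))
    return("nSels must be a list of Selector objects")
  TRUE
})

#' Methylation-reactive region in the (d, theta) plane
#'
#' The near-attack-conformation criterion: a conformation is
#' methylation-competent when the nucleophile-to-histidine distance d is
#' strictly below \code{dMax} and the attack angle theta at the SAM methyl
#' carbon lies inclusively within \code{[thetaMin, thetaMax]}. Defaults:
#' d < 3.5 Angstrom, 125 <= theta <= 170 degrees.
#'
#' @slot dMax maximum distance in Angstrom (strict)
#' @slot thetaMin lower angle bound in degrees (inclusive)
#' @slot thetaMax upper angle bound in degrees (inclusive)
#' @export
setClass("ReactiveRegion",
  representation(dMax = "numeric", thetaMin = "numeric", thetaMax = "numeric"),
  prototype(dMax = 3.5, thetaMin = 125, thetaMax = 170)
)

setValidity("ReactiveRegion", function(object) {
  if (object@dMax <= 0) return("dMax must be positive")
  if (!(0 <= object@thetaMin && object@thetaMin < object@thetaMax &&
        object@thetaMax <= 180))
    return("need 0 <= thetaMin < thetaMax <= 180")
  TRUE
})

#' Per-site regioselectivity statistics
#'
#' Result of [siteStats()]: per-frame reaction-coordinate records, the
#' reactive (near-attack) fraction, and a kernel density estimate over the
#' (d, theta) plane.
#'
#' @slot siteLabel site label
#' @slot nFrames number of frames analysed
#' @slot nReactive number of frames classified reactive
#' @slot fraction nReactive / nFrames
#' @slot records data.frame with columns \code{frame}, \code{site},
#'   \code{d_angstrom}, \code{theta_deg}, \code{reactive}
#' @slot kde list with components \code{d} (grid axis, Angstrom),
#'   \code{theta} (grid axis, degrees) and \code{z} (density matrix,
#'   rows index d, columns index theta)
#' @slot region the [ReactiveRegion-class] used for classification
#' @export
setClass("SiteStats",
  representation(
    siteLabel = "character",
    nFrames = "integer",
    nReactive = "integer",
    fraction = "numeric",
    records = "data.frame",
    kde = "list",
    region = "ReactiveRegion"
  )
)

setValidity("SiteStats", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@nReactive < 0L || object@nReactive > object@nFrames)
    return("nReactive must lie in [0, nFrames]")
  if (abs(object@fraction - object@nReactive / object@nFrames) > 1e-12)
    return("fraction must equal nReactive / nFrames")
  if (length(object@kde)) {
    if (!all(c("d", "theta", "z") %in% names(object@kde)))
      return("kde must have components d, theta, z")
    if (any(object@kde$z < 0)) return("kde density must be non-negative")
  }
  TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "Ensemble", function(object) {
  cat("Ensemble:", dim(object@coords)[3], "frame(s),",
      nrow(object@atoms), "atoms/frame\n")
  ch <- unique(object@atoms$chain)
  cat("  chains:", paste(ch, collapse = " "), "\n")
  cat("  topology key:", substr(topologyKey(object), 1, 16), "...\n")
})

setMethod("show", "Selector", function(object) {
  crit <- c(
    if (!is.na(object@chain)) paste0("chain=", object@chain),
    if (!is.na(object@resseq)) paste0("resseq=", object@resseq),
    if (!is.na(object@resname)) paste0("resname=", object@resname),
    if (length(object@atomNames))
      paste0("name=[", paste(object@atomNames, collapse = ","), "]")
  )
  cat("Selector(", paste(crit, collapse = ", "), ")\n", sep = "")
})

setMethod("show", "SiteSpec", function(object) {
  cat("SiteSpec:", object@label, "(",
      length(object@nSels), "acceptor N selector(s) )\n")
})

setMethod("show", "ReactiveRegion", function(object) {
  cat(sprintf("ReactiveRegion: d < %.2f A, %.1f <= theta <= %.1f deg\n",
              object@dMax, object@thetaMin, object@thetaMax))
})

setMethod("show", "SiteStats", function(object) {
  cat(sprintf("SiteStats[%s]: %d/%d frames reactive (%.1f%%)\n",
              object@siteLabel, object@nReactive, object@nFrames,
              100 * object@fraction))
})
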