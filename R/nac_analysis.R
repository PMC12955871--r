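# Near-attack-conformation (NAC) analysis.
#
# The S_N2 methyl transfer requires (i) the substrate hydroxyl oxygen close
# enough to the catalytic histidine to be deprotonated, and (ii) an
# approximately in-line O...C1-S arrangement at the SAM methyl carbon.
# These two reaction coordinates -- d(O...H-N), measured heavy-atom O->N on
# hydrogen-free models, and the angle at C1 between the attacking oxygen
# and the sulfonium sulfur -- are extracted per frame, classified against a
# rectangular reactive region, and summarised per candidate site.

#' Angle at a vertex, in degrees
#'
#' Angle between the arms \code{a - vertex} and \code{b - vertex}, computed
#' as the arccosine of the normalised dot product and clamped to [0, 180]
#' against floating-point rounding.
#'
#' @param a,vertex,b numeric 3-vectors (or \code{n x 3} matrices for
#'   vectorised evaluation)
#' @return angle(s) in degrees in [0, 180]
#' @examples
#' angleDeg(c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0)) # 180
#' angleDeg(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))  # 90
#' @export
angleDeg <- function(a, vertex, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(vertex))) vertex <- matrix(vertex, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  u <- a - vertex
  v <- b - vertex
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu == 0 | nv == 0))
    stop("degenerate geometry: zero-length arm at the angle vertex",
         call. = FALSE)
  cosang <- rowSums(u * v) / (nu * nv)
  cosang <- pmin(1, pmax(-1, cosang))
  out <- acos(cosang) * 180 / pi
  if (length(out) == 1L) out[[1]] else out
}

.site_indices <- function(ens, site) {
  lab <- site@label
  list(
    o = .resolve_one(ens, site@oSel, sprintf("site '%s' nucleophile O", lab)),
    n = vapply(seq_along(site@nSels), function(j)
      .resolve_one(ens, site@nSels[[j]],
                   sprintf("site '%s' acceptor N #%d", lab, j)), integer(1)),
    c1 = .resolve_one(ens, site@c1Sel, sprintf("site '%s' SAM C1", lab)),
    s = .resolve_one(ens, site@sSel, sprintf("site '%s' SAM S", lab))
  )
}

#' Measure the reaction coordinates of a site across an ensemble
#'
#' For every frame: \code{d} is the minimum Euclidean distance from the
#' nucleophile oxygen to the resolved acceptor nitrogen atoms (heavy-atom
#' convention -- the imidazole N-H hydrogen is not required), and
#' \code{theta} is the angle at the SAM methyl carbon C1 between the oxygen
#' and the sulfur.
#'
#' @param ens an [Ensemble-class]
#' @param site a [SiteSpec-class]; every selector must resolve to exactly
#'   one atom
#' @return data.frame with columns \code{frame} (model number),
#'   \code{site}, \code{d_angstrom}, \code{theta_deg}
#' @export
measureSite <- function(ens, site) {
  idx <- .site_indices(ens, site)
  xyz <- ens@coords
  o <- t(xyz[idx$o, , ])    # n_frames x 3
  c1 <- t(xyz[idx$c1, , ])
  s <- t(xyz[idx$s, , ])
  if (nFrames(ens) == 1L) { # t() of a length-3 vector is 1 x 3 already
    o <- matrix(xyz[idx$o, , 1], ncol = 3)
    c1 <- matrix(xyz[idx$c1, , 1], ncol = 3)
    s <- matrix(xyz[idx$s, , 1], ncol = 3)
  }
  dmat <- vapply(idx$n, function(j) {
    nn <- if (nFrames(ens) == 1L) matrix(xyz[j, , 1], ncol = 3) else t(xyz[j, , ])
    sqrt(rowSums((o - nn)^2))
  }, numeric(nFrames(ens)))
  d <- if (is.null(dim(dmat))) min(dmat) else apply(dmat, 1, min)
  theta <- angleDeg(o, c1, s)
  data.frame(frame = frameIndices(ens), site = site@label,
             d_angstrom = as.numeric(d), theta_deg = as.numeric(theta),
             stringsAsFactors = FALSE)
}

#' Classify conformations as methylation-competent
#'
#' A conformation is reactive iff \code{d < dMax} (strict) and
#' \code{thetaMin <= theta <= thetaMax} (inclusive).
#'
#' @param d distance(s), Angstrom
#' @param theta angle(s), degrees
#' @param region a [ReactiveRegion-class]
#' @return logical vector
#' @examples
#' classifyReactive(3.3, 155) # TRUE  (competent)
#' classifyReactive(5.8, 110) # FALSE (both criteria fail)
#' classifyReactive(3.5, 150) # FALSE (strict distance bound)
#' @export
classifyReactive <- function(d, theta, region = reactiveRegion()) {
  d < region@dMax & theta >= region@thetaMin & theta <= region@thetaMax
}

#' Product-Gaussian kernel density estimate on a grid
#'
#' 2-D KDE with a product Gaussian kernel and Scott's rule per axis
#' (\code{h_j = sd_j * n^(-1/6)}), evaluated on the outer product of the
#' two axis vectors. Density integrates to ~1 over a grid covering the
#' data.
#'
#' @param x,y data vectors (equal length)
#' @param gx,gy grid axis vectors
#' @param hx,hy optional bandwidth overrides (Angstrom / degrees)
#' @return list with \code{x = gx}, \code{y = gy}, \code{z} (matrix,
#'   \code{length(gx) x length(gy)}), and bandwidths \code{hx}, \code{hy}
#' @export
kdeGrid <- function(x, y, gx, gy, hx = NULL, hy = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 1)
  if (is.null(hx)) hx <- stats::sd(x) * n^(-1 / 6)
  if (is.null(hy)) hy <- stats::sd(y) * n^(-1 / 6)
  if (!isTRUE(hx > 0)) hx <- max(1e-3, abs(mean(x)) * 1e-3, na.rm = TRUE)
  if (!isTRUE(hy > 0)) hy <- max(1e-3, abs(mean(y)) * 1e-3, na.rm = TRUE)
  ax <- dnorm(outer(gx, x, "-") / hx) / hx   # |gx| x n
  ay <- dnorm(outer(gy, y, "-") / hy) / hy   # |gy| x n
  z <- (ax %*% t(ay)) / n
  list(x = gx, y = gy, z = z, hx = hx, hy = hy)
}

#' Per-site regioselectivity statistics
#'
#' Measures the reaction coordinates for every frame, classifies frames
#' against the reactive region, and estimates a KDE over the (d, theta)
#' plane. The reactive fraction is the exact integer count ratio.
#'
#' @param ens an [Ensemble-class]
#' @param site a [SiteSpec-class]
#' @param region a [ReactiveRegion-class]
#' @param gridD,gridTheta KDE grid axes (defaults: 100 points over
#'   [0, 8] Angstrom and [0, 180] degrees)
#' @param hx,hy optional KDE bandwidth overrides
#' @return a [SiteStats-class]
#' @export
siteStats <- function(ens, site, region = reactiveRegion(),
                      gridD = seq(0, 8, length.out = 100),
                      gridTheta = seq(0, 180, length.out = 100),
                      hx = NULL, hy = NULL) {
  rec <- measureSite(ens, site)
  rec$reactive <- classifyReactive(rec$d_angstrom, rec$theta_deg, region)
  n <- nrow(rec)
  nr <- sum(rec$reactive)
  kde <- kdeGrid(rec$d_angstrom, rec$theta_deg, gridD, gridTheta, hx, hy)
  new("SiteStats",
      siteLabel = site@label, nFrames = as.integer(n),
      nReactive = as.integer(nr), fraction = nr / n,
      records = rec,
      kde = list(d = kde$x, theta = kde$y, z = kde$z,
                 hd = kde$hx, htheta = kde$hy),
      region = region)
}

#' Rank candidate sites by reactive fraction
#'
#' Sites are ordered by competent-conformation fraction, descending; exact
#' ties are broken alphabetically by label and flagged as ambiguous.
#'
#' @param stats list of [SiteStats-class] objects (or a single one)
#' @return data.frame with columns \code{site}, \code{fraction},
#'   \code{n_reactive}, \code{n_frames}, \code{rank}, \code{tie}
#' @export
rankSites <- function(stats) {
  if (is(stats, "SiteStats")) stats <- list(stats)
  stopifnot(length(stats) >= 1)
  df <- data.frame(
    site = vapply(stats, function(s) s@siteLabel, character(1)),
    fraction = vapply(stats, function(s) s@fraction, numeric(1)),
    n_reactive = vapply(stats, function(s) s@nReactive, integer(1)),
    n_frames = vapply(stats, function(s) s@nFrames, integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-df$fraction, df$site)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df$tie <- duplicated(df$fraction) | duplicated(df$fraction, fromLast = TRUE)
  rownames(df) <- NULL
  df
}

# ---- superposition ---------------------------------------------------------

.kabsch <- function(mob, ref) {
  # mob, ref: n x 3 matrices, paired rows; returns R (3x3, proper), t
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  A <- sweep(mob, 2, cm)
  B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, dsign))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cr - as.numeric(R %*% cm)
  list(R = R, t = tvec)
}

#' Rigid-body superposition (Kabsch)
#'
#' Least-squares fit of a mobile frame onto a reference frame over a
#' selection of paired atoms, with a proper rotation enforced (no
#' reflection). Atoms are paired by selection order; the selection must
#' resolve to the same count (>= 3) in both frames.
#'
#' @param mobile,reference single-frame [Ensemble-class] objects (or
#'   multi-frame; see \code{mobileFrame}, \code{refFrame})
#' @param sel optional [Selector-class]; default uses all atoms
#' @param mobileFrame,refFrame frame positions to use (default 1)
#' @return list with \code{rotation} (3x3), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom, after fit), and \code{coords}
#'   (the fitted mobile selection, n x 3)
#' @export
superpose <- function(mobile, reference, sel = NULL,
                      mobileFrame = 1L, refFrame = 1L) {
  im <- if (is.null(sel)) seq_len(nAtoms(mobile)) else selectAtoms(mobile, sel)
  ir <- if (is.null(sel)) seq_len(nAtoms(reference)) else selectAtoms(reference, sel)
  if (length(im) != length(ir))
    stop(sprintf("selection pairing error: %d mobile vs %d reference atoms",
                 length(im), length(ir)), call. = FALSE)
  if (length(im) < 3L)
    stop("superposition is underdetermined with fewer than 3 atoms",
         call. = FALSE)
  mob <- mobile@coords[im, , mobileFrame]
  ref <- reference@coords[ir, , refFrame]
  fit <- .kabsch(mob, ref)
  moved <- sweep(mob %*% t(fit$R), 2, fit$t, "+")
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  list(rotation = fit$R, translation = fit$t, rmsd = rmsd, coords = moved)
}

#' Apply a rigid motion to an ensemble
#'
#' @param ens an [Ensemble-class]
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector
#' @return the transformed [Ensemble-class]
#' @export
transformEnsemble <- function(ens, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  xyz <- ens@coords
  for (k in seq_len(dim(xyz)[3]))
    xyz[, , k] <- sweep(xyz[, , k] %*% t(rotation), 2, translation, "+")
  Ensemble(ens@atoms, xyz, ens@frameIndex)
}

#' Per-residue root-mean-square fluctuation
#'
#' Each frame is superposed onto the ensemble mean structure with a
#' two-pass refit (mean, refit all frames, recompute the mean once, refit
#' again); the RMSF of atom i is the root mean squared displacement from
#' its mean position over the fitted frames, and atom values are averaged
#' per residue. No mass weighting.
#'
#' @param ens an [Ensemble-class] with >= 2 frames
#' @param sel a [Selector-class]; default selects backbone-named atoms
#'   (N, CA, C, O)
#' @param refit logical; \code{FALSE} skips the superposition passes and
#'   measures fluctuations about the raw ensemble mean (useful for
#'   pre-aligned ensembles)
#' @return data.frame with columns \code{chain}, \code{resseq},
#'   \code{rmsf} (Angstrom)
#' @export
rmsf <- function(ens, sel = selector(atomNames = c("N", "CA", "C", "O")),
                 refit = TRUE) {
  if (nFrames(ens) < 2L)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  idx <- if (is.null(sel)) seq_len(nAtoms(ens)) else selectAtoms(ens, sel)
  if (length(idx) == 0L)
    stop("RMSF selection resolved to no atoms", call. = FALSE)
  nf <- nFrames(ens)
  frames <- lapply(seq_len(nf), function(k) ens@coords[idx, , k, drop = FALSE][, , 1])
  if (length(idx) == 1L)
    frames <- lapply(frames, function(f) matrix(f, ncol = 3))
  fit_all <- function(target) lapply(frames, function(f) {
    if (nrow(f) < 3L) return(f)  # too few atoms to fit; use as-is
    k <- .kabsch(f, target)
    sweep(f %*% t(k$R), 2, k$t, "+")
  })
  mean_of <- function(fs) Reduce(`+`, fs) / length(fs)
  if (refit) {
    m0 <- mean_of(frames)
    f1 <- fit_all(m0)
    m1 <- mean_of(f1)
    f2 <- fit_all(m1)
  } else {
    f2 <- frames
  }
  m2 <- mean_of(f2)
  sqd <- Reduce(`+`, lapply(f2, function(f) rowSums((f - m2)^2))) / nf
  atom_rmsf <- sqrt(sqd)
  a <- ens@atoms[idx, , drop = FALSE]
  key <- paste(a$chain, a$resseq, sep = "\r")
  agg <- tapply(atom_rmsf, key, mean)
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resseq = a$resseq[first],
                    rmsf = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chain, out$resseq), , drop = FALSE]
}
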