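# Synthetic conformational ensembles with known internal-coordinate truth.
#
# The generator stands in for MD trajectory sampling: per site it draws
# (d, theta) pairs from truncated normal distributions and embeds each pair
# as a minimal Cartesian scaffold (S, C1, O, N) so that measureSite()
# recovers the sampled internal coordinates exactly. Scaffold constants:
# r_SC = 1.80 A (S-CH3 bond-like), r_OC = 3.0 A (van der Waals approach);
# both are irrelevant to (d, theta) recovery by construction.

.R_SC <- 1.80
.R_OC <- 3.00

#' Describe the (d, theta) distribution of one synthetic site
#'
#' d is drawn from Normal(dMean, dSd) truncated below at 0.5 Angstrom;
#' theta from Normal(thetaMean, thetaSd) truncated to [0, 180] degrees.
#' A Gaussian-copula correlation \code{rho} between the two coordinates is
#' accepted for stress tests (default 0 = independent).
#'
#' @param label site label (unique within a generation call)
#' @param dMean,dSd distance mean and sd, Angstrom
#' @param thetaMean,thetaSd angle mean and sd, degrees
#' @param rho latent-normal correlation between d and theta in (-1, 1)
#' @return a \code{siteDistribution} list
#' @export
siteDistribution <- function(label, dMean, dSd, thetaMean, thetaSd, rho = 0) {
  stopifnot(dSd > 0, thetaSd > 0, dMean > 0.5,
            thetaMean >= 0, thetaMean <= 180, abs(rho) < 1)
  structure(list(label = label, dMean = dMean, dSd = dSd,
                 thetaMean = thetaMean, thetaSd = thetaSd, rho = rho),
            class = "siteDistribution")
}

.site_seed <- function(masterSeed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% 99991L
  (as.integer(masterSeed) %% 20000000L) * 100L + h %% 100L + h
}

.qtrunc_norm <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Sample internal coordinates for one site
#'
#' Deterministic for a fixed seed. Draws are truncated-normal via the
#' inverse-CDF transform; with \code{rho != 0} the two coordinates share a
#' Gaussian copula.
#'
#' @param dist a [siteDistribution()]
#' @param n number of draws
#' @param seed integer seed
#' @return data.frame with columns \code{d}, \code{theta}
#' @export
sampleInternal <- function(dist, n, seed) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  z1 <- rnorm(n)
  z2 <- dist$rho * z1 + sqrt(1 - dist$rho^2) * rnorm(n)
  u1 <- pnorm(z1)
  u2 <- pnorm(z2)
  data.frame(
    d = .qtrunc_norm(u1, dist$dMean, dist$dSd, 0.5, Inf),
    theta = .qtrunc_norm(u2, dist$thetaMean, dist$thetaSd, 0, 180)
  )
}

#' Embed (d, theta) pairs as Cartesian scaffold coordinates
#'
#' Places, per pair: S at the origin; C1 at (1.80, 0, 0); O in the
#' xy-plane at 3.0 Angstrom from C1 so that the angle at C1 between
#' (S - C1) and (O - C1) equals theta; and a single acceptor N at distance
#' d from O along +z (a fixed unit vector perpendicular to the O-C1
#' direction). [measureSite()] on the resulting frame returns (d, theta)
#' to 1e-6.
#'
#' @param d distance(s), Angstrom, > 0
#' @param theta angle(s), degrees, strictly inside (0, 180)
#' @return array \code{4 x 3 x length(d)} of coordinates in atom order
#'   S, C1, O, N
#' @export
embedGeometry <- function(d, theta) {
  stopifnot(length(d) == length(theta))
  if (any(d <= 0)) stop("d must be positive", call. = FALSE)
  if (any(theta <= 0 | theta >= 180))
    stop("degenerate embedding: theta must be strictly inside (0, 180)",
         call. = FALSE)
  n <- length(d)
  th <- theta * pi / 180
  out <- array(0, dim = c(4, 3, n))
  out[2, 1, ] <- .R_SC
  ox <- .R_SC - .R_OC * cos(th)
  oy <- .R_OC * sin(th)
  out[3, 1, ] <- ox
  out[3, 2, ] <- oy
  out[4, 1, ] <- ox
  out[4, 2, ] <- oy
  out[4, 3, ] <- d
  out
}

.scaffold_atoms <- function(chain) {
  data.frame(
    serial = 1:4,
    name = c("S", "C1", "O", "NE2"),
    resname = c("SAM", "SAM", "LIG", "HIS"),
    chain = chain,
    resseq = c(1L, 1L, 2L, 3L),
    element = c("S", "C", "O", "N"),
    stringsAsFactors = FALSE
  )
}

.scaffold_site_spec <- function(label, chain) {
  siteSpec(
    label = label,
    oSel = selector(chain = chain, resname = "LIG", atomNames = "O"),
    nSels = selector(chain = chain, resname = "HIS", atomNames = "NE2"),
    c1Sel = selector(chain = chain, resname = "SAM", atomNames = "C1"),
    sSel = selector(chain = chain, resname = "SAM", atomNames = "S")
  )
}

#' Generate a synthetic ensemble with ground truth
#'
#' Each frame contains one embedded scaffold per site, on a distinct chain
#' (A, B, C, ...). Per-site random streams are derived from the master
#' seed and the site label, so adding a site never perturbs another site's
#' draws. The truth table records the sampled internal coordinates and the
#' reactive flag under the supplied region.
#'
#' @param dists a [siteDistribution()] or list of them (unique labels)
#' @param n number of frames
#' @param seed master integer seed
#' @param region [ReactiveRegion-class] used for the truth flags
#' @return list with \code{ensemble} ([Ensemble-class]), \code{truth}
#'   (data.frame: frame, site, d, theta, reactive), and \code{sites}
#'   (named list of [SiteSpec-class], one per site)
#' @examples
#' gen <- generateEnsemble(
#'   siteDistribution("3'-OH", 3.3, 0.3, 155, 10), n = 50, seed = 1)
#' mean(gen$truth$reactive)
#' @export
generateEnsemble <- function(dists, n, seed, region = reactiveRegion()) {
  if (inherits(dists, "siteDistribution")) dists <- list(dists)
  labels <- vapply(dists, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("site labels must be unique", call. = FALSE)
  if (length(dists) > 26L) stop("at most 26 sites (one chain each)", call. = FALSE)
  chains <- LETTERS[seq_along(dists)]
  per_site <- lapply(seq_along(dists), function(j) {
    draws <- sampleInternal(dists[[j]], n, .site_seed(seed, labels[j]))
    list(draws = draws, coords = embedGeometry(draws$d, draws$theta))
  })
  natom <- 4L * length(dists)
  xyz <- array(0, dim = c(natom, 3, n))
  atoms <- do.call(rbind, lapply(chains, .scaffold_atoms))
  atoms$serial <- seq_len(natom)
  for (j in seq_along(dists)) {
    rows <- (j - 1L) * 4L + 1:4
    # offset scaffolds along x so sites do not overlap spatially
    off <- (j - 1L) * 50
    xyz[rows, , ] <- per_site[[j]]$coords
    xyz[rows, 1, ] <- xyz[rows, 1, ] + off
  }
  ens <- Ensemble(atoms, xyz)
  truth <- do.call(rbind, lapply(seq_along(dists), function(j) {
    dr <- per_site[[j]]$draws
    data.frame(frame = seq_len(n), site = labels[j], d = dr$d,
               theta = dr$theta,
               reactive = classifyReactive(dr$d, dr$theta, region),
               stringsAsFactors = FALSE)
  }))
  sites <- setNames(lapply(seq_along(dists), function(j)
    .scaffold_site_spec(labels[j], chains[j])), labels)
  list(ensemble = ens, truth = truth, sites = sites)
}
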