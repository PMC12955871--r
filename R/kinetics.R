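# Methylation kinetics: Michaelis-Menten rates, competitive SAH product
# inhibition, Ki inversion from apparent-Km shifts, initial-rate fitting,
# and synthetic rate data.
#
# Concentrations are in uM throughout; time is hours externally and in the
# cascade simulator, with kcat given in s^-1 and converted internally.

#' Michaelis-Menten rate
#'
#' @param s substrate concentration(s), uM
#' @param vmax maximal rate
#' @param km Michaelis constant, uM
#' @return rate(s), \code{vmax * s / (km + s)}
#' @examples
#' mmRate(51.7, vmax = 1, km = 51.7) # vmax / 2 at s = Km
#' @export
mmRate <- function(s, vmax, km) {
  stopifnot(all(s >= 0), vmax > 0, km > 0)
  vmax * s / (km + s)
}

#' Apparent Km under competitive inhibition
#'
#' Competitive inhibition leaves Vmax unchanged and scales the Michaelis
#' constant: \code{Km,app = Km * (1 + I / Ki)}.
#'
#' @param km uninhibited Michaelis constant, uM
#' @param ki inhibition constant, uM
#' @param inhibitorConc inhibitor concentration, uM
#' @return apparent Km, uM
#' @export
apparentKm <- function(km, ki, inhibitorConc) {
  stopifnot(km > 0, ki > 0, inhibitorConc >= 0)
  km * (1 + inhibitorConc / ki)
}

#' Invert a printed Km shift to an inhibition constant
#'
#' Given the uninhibited Km, the apparent Km measured at a known inhibitor
#' concentration, and that concentration, solves the competitive model for
#' Ki: \code{Ki = I / (Km,app / Km - 1)}. Exact inverse of
#' [apparentKm()].
#'
#' @param km uninhibited Km, uM
#' @param kmApp apparent Km at the inhibitor concentration, uM; must
#'   exceed \code{km}
#' @param inhibitorConc inhibitor concentration, uM
#' @return Ki, uM
#' @examples
#' inferKi(km = 51.7, kmApp = 2794, inhibitorConc = 1500) # ~28.3 uM
#' @export
inferKi <- function(km, kmApp, inhibitorConc) {
  stopifnot(km > 0, inhibitorConc > 0)
  if (kmApp <= km)
    stop("no inhibition: apparent Km must exceed the uninhibited Km",
         call. = FALSE)
  inhibitorConc / (kmApp / km - 1)
}

#' Simulate noisy initial-rate data
#'
#' Rates follow the Michaelis-Menten model (competitive-inhibition form
#' when \code{ki} and inhibitor concentrations are supplied) with
#' multiplicative Gaussian noise: \code{v = model(s) * (1 + eps)},
#' \code{eps ~ Normal(0, noiseCv)}. Negative draws are clipped at 0 and
#' flagged. Deterministic per seed.
#'
#' @param vmax,km model parameters
#' @param ki inhibition constant, uM (NULL for no-inhibitor data)
#' @param sGrid substrate concentrations, uM
#' @param inhibitorConc scalar or vector of inhibitor concentrations, uM;
#'   one data block is generated per value (default 0)
#' @param replicates replicates per (s, I) combination
#' @param noiseCv coefficient of variation of the multiplicative noise
#' @param seed integer seed
#' @return data.frame with columns \code{s_uM}, \code{inhibitor_uM},
#'   \code{v}, \code{clipped}
#' @export
synthRateData <- function(vmax, km, ki = NULL, sGrid,
                          inhibitorConc = 0, replicates = 1,
                          noiseCv = 0, seed = 1) {
  stopifnot(noiseCv >= 0, replicates >= 1)
  if (is.null(ki) && any(inhibitorConc > 0))
    stop("inhibitor concentrations given but ki is NULL", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  grid <- expand.grid(rep = seq_len(replicates), s_uM = sGrid,
                      inhibitor_uM = inhibitorConc)
  kmEff <- if (is.null(ki)) km else km * (1 + grid$inhibitor_uM / ki)
  v0 <- vmax * grid$s_uM / (kmEff + grid$s_uM)
  v <- v0 * (1 + rnorm(nrow(grid), 0, noiseCv))
  clipped <- v < 0
  v[clipped] <- 0
  data.frame(s_uM = grid$s_uM, inhibitor_uM = grid$inhibitor_uM,
             v = v, clipped = clipped)
}

#' Fit Michaelis-Menten (optionally competitive-inhibition) parameters
#'
#' Nonlinear least squares on untransformed rates (no Lineweaver-Burk),
#' via Levenberg-Marquardt with heuristic multi-starts (three (vmax, km)
#' starts, crossed with three ki starts spanning the inhibitor-concentration
#' scale when an inhibitor is present); the fit with the lowest SSE wins. When the data contain rows at nonzero inhibitor
#' concentration, a joint competitive model
#' \code{v = vmax * s / (km * (1 + I/ki) + s)} is fitted and \code{ki} is
#' estimated alongside \code{vmax} and \code{km}.
#'
#' @param data data.frame with columns \code{s_uM}, \code{v}, and
#'   optionally \code{inhibitor_uM}
#' @return list with \code{estimates} (named vector), \code{se} (asymptotic
#'   standard errors), \code{converged}, \code{sse}, \code{model}
#'   ("mm" or "mm_competitive"), and the underlying \code{fit} object
#' @export
fitMM <- function(data) {
  stopifnot(all(c("s_uM", "v") %in% names(data)))
  s <- data$s_uM
  v <- data$v
  if (length(unique(s)) < 4L)
    stop("need at least 4 distinct substrate concentrations", call. = FALSE)
  inh <- if ("inhibitor_uM" %in% names(data)) data$inhibitor_uM else rep(0, length(s))
  with_ki <- any(inh > 0)
  vmax0 <- max(v) * 1.1
  base <- s[which.min(abs(v - vmax0 / 2))]
  starts <- list(
    c(vmax = vmax0, km = max(base, min(s[s > 0]))),
    c(vmax = max(v), km = stats::median(s)),
    c(vmax = 2 * max(v), km = max(s) / 2)
  )
  if (with_ki) {
    # the inhibition constant can sit orders of magnitude below the applied
    # inhibitor concentration, so spread its starts over that range too
    imax <- max(inh[inh > 0])
    starts <- unlist(lapply(starts, function(st) lapply(
      c(imax / 2, imax / 50, imax / 1000),
      function(k0) c(st, ki = k0))), recursive = FALSE)
  }
  best <- NULL
  for (st in starts) {
    fit <- try({
      if (with_ki) {
        minpack.lm::nlsLM(
          v ~ vmax * s / (km * (1 + inh / ki) + s),
          data = data.frame(s = s, v = v, inh = inh),
          start = as.list(st),
          lower = c(1e-12, 1e-12, 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          v ~ vmax * s / (km + s),
          data = data.frame(s = s, v = v),
          start = as.list(st), lower = c(1e-12, 1e-12),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("Michaelis-Menten fit failed to converge from all starts",
         call. = FALSE)
  if (coef(best$fit)[["km"]] > max(s))
    warning("all substrate concentrations lie below the fitted Km; ",
            "vmax and km are weakly identifiable", call. = FALSE)
  sm <- summary(best$fit)
  list(estimates = coef(best$fit),
       se = sm$coefficients[, "Std. Error"],
       converged = best$fit$convInfo$isConv,
       sse = best$sse,
       model = if (with_ki) "mm_competitive" else "mm",
       fit = best$fit)
}
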