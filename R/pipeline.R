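# Configuration-driven orchestration of the four analysis arms.
#
# Each runner takes a config (YAML path or list), writes its artifact
# files plus a manifest (config echo, seed, package version) into an
# output directory, and returns the file list invisibly alongside its
# in-memory results. Runs are deterministic given (config, seed); on error
# partial outputs are removed. A thin command-line wrapper over
# runPipeline() ships in inst/scripts/methylnac.R.

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config-error: config file '%s' does not exist", config),
           call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

.require_file <- function(path, what) {
  if (is.null(path) || !is.character(path) || !file.exists(path))
    stop(sprintf("validation-error: %s file '%s' does not exist",
                 what, if (is.null(path)) "<missing>" else path),
         call. = FALSE)
  path
}

.num6 <- function(df) {
  # CSV convention: '.' decimal, floats at 6 significant digits
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

.write_outputs <- function(outDir, writer) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(name, fun) {
    path <- file.path(outDir, name)
    fun(path)
    written <<- c(written, path)
    path
  }
  res <- writer(emit)
  ok <- TRUE
  res$files <- written
  res
}

.write_manifest <- function(emit, config, seed) {
  emit("manifest.json", function(p) jsonlite::write_json(
    list(config = config, seed = seed,
         tool = "MethylNAC", version = as.character(packageVersion("MethylNAC"))),
    p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
}

#' Build a Selector from a config list
#'
#' @param x list with any of \code{chain}, \code{resseq}, \code{resname},
#'   \code{name} (scalar or vector of atom names)
#' @return a [Selector-class]
#' @export
selectorFromConfig <- function(x) {
  selector(chain = x$chain %||% NA, resseq = x$resseq %||% NA,
           resname = x$resname %||% NA,
           atomNames = unlist(x$name) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build SiteSpec objects from a config list
#'
#' Expected shape (one entry per site): \code{label}, \code{o}, \code{n}
#' (one selector map or a list of them), \code{c1}, \code{s}, each a
#' selector map as accepted by [selectorFromConfig()].
#'
#' @param x list of site config entries (or a YAML file path)
#' @return named list of [SiteSpec-class]
#' @export
sitesFromConfig <- function(x) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  sites <- lapply(x, function(s) {
    nlist <- if (!is.null(s$n$name) || !is.null(s$n$resseq) ||
                 !is.null(s$n$chain) || !is.null(s$n$resname))
      list(s$n) else s$n
    siteSpec(label = s$label,
             oSel = selectorFromConfig(s$o),
             nSels = lapply(nlist, selectorFromConfig),
             c1Sel = selectorFromConfig(s$c1),
             sSel = selectorFromConfig(s$s))
  })
  setNames(sites, vapply(sites, function(s) s@label, character(1)))
}

.region_from_config <- function(cfg) {
  reactiveRegion(dMax = cfg$dmax %||% 3.5,
                 thetaMin = cfg$theta_min %||% 125,
                 thetaMax = cfg$theta_max %||% 170)
}

#' Run the NAC regioselectivity arm
#'
#' Reads a multi-model PDB ensemble and a site config, measures the
#' reaction coordinates, classifies frames, and writes per-frame geometry
#' (CSV), per-site statistics (JSON), KDE grids (CSV) and the site ranking
#' (CSV), plus a manifest.
#'
#' @param config YAML path or list with \code{ensemble} (PDB path),
#'   \code{sites} (path or list), optional \code{dmax}, \code{theta_min},
#'   \code{theta_max}
#' @param outDir output directory
#' @return (invisibly) list with \code{stats}, \code{ranking},
#'   \code{records}, \code{files}
#' @export
runNac <- function(config, outDir) {
  cfg <- .load_config(config)
  ens <- parsePDB(.require_file(cfg$ensemble, "ensemble PDB"))
  sites <- if (is.character(cfg$sites))
    sitesFromConfig(.require_file(cfg$sites, "site config")) else
    sitesFromConfig(cfg$sites)
  region <- .region_from_config(cfg)
  stats <- lapply(sites, function(s) siteStats(ens, s, region))
  records <- do.call(rbind, lapply(stats, function(s) s@records))
  rownames(records) <- NULL
  ranking <- rankSites(stats)
  res <- .write_outputs(outDir, function(emit) {
    .write_manifest(emit, cfg, cfg$seed %||% NA)
    emit("geometry.csv", function(p) write.csv(.num6(records), p, row.names = FALSE))
    emit("ranking.csv", function(p) write.csv(.num6(ranking), p, row.names = FALSE))
    emit("site_stats.json", function(p) jsonlite::write_json(
      lapply(stats, function(s) list(
        site = s@siteLabel, n_frames = s@nFrames, n_reactive = s@nReactive,
        fraction = s@fraction,
        region = list(dmax = s@region@dMax, theta_min = s@region@thetaMin,
                      theta_max = s@region@thetaMax))),
      p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
    for (s in stats) {
      lab <- gsub("[^A-Za-z0-9]+", "_", s@siteLabel)
      z <- s@kde$z
      dimnames(z) <- list(signif(s@kde$d, 6), signif(s@kde$theta, 6))
      local({
        zz <- z
        emit(paste0("kde_", lab, ".csv"),
             function(p) write.csv(signif(zz, 6), p))
      })
    }
    list(stats = stats, ranking = ranking, records = records)
  })
  invisible(res)
}

#' Run the synthetic-ensemble arm
#'
#' Generates an ensemble from per-site (d, theta) distributions, writes it
#' as a multi-model PDB with its ground-truth table and a config echo.
#'
#' @param config YAML path or list with \code{n}, \code{seed} and
#'   \code{sites}: entries with \code{label}, \code{d_mean}, \code{d_sd},
#'   \code{theta_mean}, \code{theta_sd}, optional \code{rho}; optional
#'   region overrides \code{dmax}/\code{theta_min}/\code{theta_max}
#' @param outDir output directory
#' @param seed overrides \code{config$seed} when non-NULL
#' @return (invisibly) list with \code{ensemble}, \code{truth},
#'   \code{sites}, \code{files}
#' @export
runSynth <- function(config, outDir, seed = NULL) {
  cfg <- .load_config(config)
  seed <- seed %||% cfg$seed %||% 1L
  dists <- lapply(cfg$sites, function(s)
    siteDistribution(s$label, s$d_mean, s$d_sd, s$theta_mean, s$theta_sd,
                     rho = s$rho %||% 0))
  region <- .region_from_config(cfg)
  gen <- generateEnsemble(dists, n = cfg$n, seed = seed, region = region)
  res <- .write_outputs(outDir, function(emit) {
    .write_manifest(emit, cfg, seed)
    emit("ensemble.pdb", function(p) writePDB(gen$ensemble, p))
    emit("truth.csv", function(p) write.csv(.num6(gen$truth), p, row.names = FALSE))
    emit("config_echo.yaml", function(p) yaml::write_yaml(cfg, p))
    gen
  })
  invisible(res)
}

#' Run the fusion-descriptor arm
#'
#' Computes the inter-tunnel centroid distance D_IC and inter-segment
#' angle O_IC on a structure, from an anchor config.
#'
#' @param config YAML path or list with \code{structure} (PDB path),
#'   \code{construct} (label), \code{tunnel_a}/\code{tunnel_b} (lists of
#'   selector maps), \code{seg_x}/\code{seg_y} (each with \code{start} and
#'   \code{end} lists of selector maps)
#' @param outDir output directory
#' @return (invisibly) list with \code{d_ic}, \code{o_ic}, \code{files}
#' @export
runFusion <- function(config, outDir) {
  cfg <- .load_config(config)
  ens <- parsePDB(.require_file(cfg$structure, "structure PDB"))
  mk_anchor <- function(label, x)
    anchorSet(label, lapply(x, selectorFromConfig))
  ta <- mk_anchor("tunnel_a", cfg$tunnel_a)
  tb <- mk_anchor("tunnel_b", cfg$tunnel_b)
  sx <- segmentSpec("X", mk_anchor("x_start", cfg$seg_x$start),
                    mk_anchor("x_end", cfg$seg_x$end))
  sy <- segmentSpec("Y", mk_anchor("y_start", cfg$seg_y$start),
                    mk_anchor("y_end", cfg$seg_y$end))
  d <- dIC(ens, ta, tb)
  o <- oIC(ens, sx, sy)
  res <- .write_outputs(outDir, function(emit) {
    .write_manifest(emit, cfg, NA)
    emit("fusion.json", function(p) jsonlite::write_json(
      list(construct = cfg$construct %||% "construct",
           D_IC_angstrom = d, O_IC_deg = o),
      p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
    list(d_ic = d, o_ic = o)
  })
  invisible(res)
}

#' Run the kinetics arm
#'
#' Subtasks: \code{"fit"} (initial-rate CSV -> fitted parameters JSON),
#' \code{"simulate"} (cascade parameters -> trajectory CSV),
#' \code{"synth"} (model parameters -> synthetic rate table CSV).
#'
#' @param config YAML path or list with \code{subtask} and
#'   subtask-specific fields: fit: \code{data} (CSV with s_uM, v,
#'   optional inhibitor_uM); simulate: \code{params} (arguments to
#'   [cascadeParams()]), \code{t_end}, optional \code{t_eval};
#'   synth: \code{vmax}, \code{km}, optional \code{ki},
#'   \code{s_grid}, \code{inhibitor}, \code{replicates}, \code{noise_cv}
#' @param outDir output directory
#' @param seed overrides \code{config$seed} when non-NULL
#' @return (invisibly) subtask-dependent result list with \code{files}
#' @export
runKinetics <- function(config, outDir, seed = NULL) {
  cfg <- .load_config(config)
  seed <- seed %||% cfg$seed %||% 1L
  sub <- cfg$subtask %||% "fit"
  if (sub == "fit") {
    dat <- read.csv(.require_file(cfg$data, "rate data"))
    fit <- fitMM(dat)
    res <- .write_outputs(outDir, function(emit) {
      .write_manifest(emit, cfg, seed)
      emit("fit.json", function(p) jsonlite::write_json(
        list(model = fit$model, converged = fit$converged, sse = fit$sse,
             estimates = as.list(fit$estimates), se = as.list(fit$se)),
        p, auto_unbox = TRUE, pretty = TRUE, digits = NA))
      list(fit = fit)
    })
  } else if (sub == "simulate") {
    p <- do.call(cascadeParams, cfg$params %||% list())
    traj <- simulateCascade(p, tEnd = cfg$t_end %||% 12,
                            tEval = unlist(cfg$t_eval))
    res <- .write_outputs(outDir, function(emit) {
      .write_manifest(emit, cfg, seed)
      emit("trajectory.csv", function(p_) write.csv(.num6(traj), p_, row.names = FALSE))
      list(trajectory = traj, params = p)
    })
  } else if (sub == "synth") {
    tab <- synthRateData(vmax = cfg$vmax, km = cfg$km, ki = cfg$ki,
                         sGrid = unlist(cfg$s_grid),
                         inhibitorConc = unlist(cfg$inhibitor) %||% 0,
                         replicates = cfg$replicates %||% 1,
                         noiseCv = cfg$noise_cv %||% 0, seed = seed)
    res <- .write_outputs(outDir, function(emit) {
      .write_manifest(emit, cfg, seed)
      emit("rates.csv", function(p) write.csv(.num6(tab), p, row.names = FALSE))
      list(rates = tab)
    })
  } else stop(sprintf("config-error: unknown kinetics subtask '%s'", sub),
              call. = FALSE)
  invisible(res)
}

#' Dispatch a pipeline run
#'
#' Single entry point over the four arms; \code{config$task} selects one
#' of \code{"nac"}, \code{"synth"}, \code{"fusion"}, \code{"kinetics"}.
#'
#' @param config YAML path or list (must contain \code{task})
#' @param outDir output directory
#' @param seed optional seed override for stochastic arms
#' @return (invisibly) the arm's result list
#' @export
runPipeline <- function(config, outDir, seed = NULL) {
  cfg <- .load_config(config)
  task <- cfg$task %||% stop("config-error: missing 'task'", call. = FALSE)
  switch(task,
    nac = runNac(cfg, outDir),
    synth = runSynth(cfg, outDir, seed),
    fusion = runFusion(cfg, outDir),
    kinetics = runKinetics(cfg, outDir, seed),
    stop(sprintf("config-error: unknown task '%s'", task), call. = FALSE)
  )
}
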