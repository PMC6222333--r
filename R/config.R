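#' @include AllClasses.R io.R sampler.R string.R
NULL

.samplerDefaults <- function()
  list(temperature = 0.5925, friction = 1, timestep = 5e-4,
       n_steps = 2000L, burnin = 500L, stride = 1L)

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Construct a run configuration
#'
#' Collects every setting of a string optimization run.  Defaults follow
#' the standard protocol: 25 images, 100 cycles, descent step 0.001,
#' smoothing 0.01, restraint force constant 100.
#'
#' @param surface list(name, parameters) (see \code{\link{buildSurface}}).
#' @param cvs list of CV declarations: each a list(kind, indices, label,
#'   weight) (label and weight optional).
#' @param endpoints list(a, b) of CV vectors for the initial string.
#' @param monitors optional monitored-coordinate declarations (like cvs).
#' @param images,cycles,descentStep,smoothing,forceConstant protocol
#'   settings.
#' @param endpointMode "free" or "fixed".
#' @param sampler named list overriding the sampler defaults
#'   (temperature, friction, timestep, n_steps, burnin, stride).
#' @param masterSeed master RNG seed.
#' @param outputDir destination for archives.
#' @return a \code{\linkS4class{RunConfig}}.
#' @export
runConfig <- function(surface, cvs, endpoints, monitors = list(),
                      images = 25L, cycles = 100L, descentStep = 0.001,
                      smoothing = 0.01, forceConstant = 100,
                      endpointMode = "free", sampler = list(),
                      masterSeed = 1L, outputDir = ".") {
  .checkKeys(surface, c("name", "parameters"), "surface")
  sampler <- modifyList(.samplerDefaults(), sampler)
  .checkKeys(sampler, names(.samplerDefaults()), "sampler")
  if (smoothing < 0 || smoothing >= 0.5)
    stop("smoothing must be in [0, 0.5)")
  new("RunConfig", surface = surface, cvs = cvs, monitors = monitors,
      endpoints = endpoints, images = as.integer(images),
      cycles = as.integer(cycles), descentStep = descentStep,
      smoothing = smoothing, forceConstant = forceConstant,
      endpointMode = endpointMode, sampler = sampler,
      masterSeed = as.integer(masterSeed), outputDir = outputDir)
}

.configKeys <- c("surface", "cvs", "monitors", "endpoints", "images",
                 "cycles", "descent_step", "smoothing", "force_constant",
                 "endpoint_mode", "sampler", "master_seed", "output_dir")

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected (fail-closed); omitted keys resolve to the
#' standard protocol defaults (25 images, 100 cycles, descent step 0.001,
#' smoothing 0.01).  \code{writeRunConfig} is its lossless inverse.
#'
#' @param path YAML file.
#' @return a validated \code{\linkS4class{RunConfig}}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  .checkKeys(y, .configKeys, "configuration")
  for (req in c("surface", "cvs", "endpoints"))
    if (is.null(y[[req]])) stop("configuration is missing '", req, "'")
  for (cv in y$cvs) .checkKeys(cv, c("kind", "indices", "label", "weight"),
                               "cvs entry")
  for (cv in y$monitors) .checkKeys(cv, c("kind", "indices", "label",
                                          "weight"), "monitors entry")
  .checkKeys(y$endpoints, c("a", "b"), "endpoints")
  runConfig(surface = list(name = y$surface$name,
                           parameters = if (is.null(y$surface$parameters))
                             list() else y$surface$parameters),
            cvs = y$cvs,
            endpoints = lapply(y$endpoints, as.numeric),
            monitors = if (is.null(y$monitors)) list() else y$monitors,
            images = y$images %||% 25L,
            cycles = y$cycles %||% 100L,
            descentStep = y$descent_step %||% 0.001,
            smoothing = y$smoothing %||% 0.01,
            forceConstant = y$force_constant %||% 100,
            endpointMode = y$endpoint_mode %||% "free",
            sampler = y$sampler %||% list(),
            masterSeed = y$master_seed %||% 1L,
            outputDir = y$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readRunConfig
#' @param config a \code{\linkS4class{RunConfig}}.
#' @param path destination YAML file.
#' @export
writeRunConfig <- function(config, path) {
  y <- list(surface = config@surface,
            cvs = config@cvs,
            endpoints = config@endpoints,
            images = config@images,
            cycles = config@cycles,
            descent_step = config@descentStep,
            smoothing = config@smoothing,
            force_constant = config@forceConstant,
            endpoint_mode = config@endpointMode,
            sampler = config@sampler,
            master_seed = config@masterSeed,
            output_dir = config@outputDir)
  if (!length(config@monitors)) y$monitors <- NULL
  else y <- append(y, list(monitors = config@monitors), after = 2)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Content hash of a run configuration
#'
#' Hash over the scientific settings only; the output directory does not
#' participate, so runs of one configuration written to different places
#' hash identically.
#'
#' @param config a \code{\linkS4class{RunConfig}}.
#' @return md5 string, stable across sessions.
#' @export
configHash <- function(config) {
  stripped <- config
  stripped@outputDir <- "."
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeRunConfig(stripped, tmp)
  unname(md5sum(tmp))
}

.cvFromSpec <- function(s) {
  s$weight <- s$weight %||% 1
  # YAML 1.1 parses bare y/n as booleans; restore the intended label
  if (is.logical(s$label)) s$label <- if (isTRUE(s$label)) "y" else "n"
  switch(s$kind,
    distance = cvDistance(s$indices[1], s$indices[2],
                          label = s$label %||%
                            sprintf("d_%d_%d", s$indices[1], s$indices[2]),
                          weight = s$weight),
    dihedral = cvDihedral(s$indices[1], s$indices[2], s$indices[3],
                          s$indices[4],
                          label = s$label %||%
                            paste0("phi_", paste(s$indices, collapse = "_")),
                          weight = s$weight),
    identity = cvIdentity(s$indices[1],
                          label = s$label %||% sprintf("x_%d", s$indices[1]),
                          weight = s$weight),
    stop("unknown CV kind: ", s$kind))
}

#' Materialize the CV set declared in a run configuration
#' @param config a \code{\linkS4class{RunConfig}}.
#' @param what "cvs" (default) or "monitors".
#' @return a \code{\linkS4class{CVSet}} (or NULL for empty monitors).
#' @export
configCVSet <- function(config, what = c("cvs", "monitors")) {
  what <- match.arg(what)
  specs <- slot(config, what)
  if (!length(specs)) return(NULL)
  cvSet(lapply(specs, .cvFromSpec))
}

#' Execute the string optimization described by a run configuration
#'
#' Builds the surface and CV sets, initializes the string between the
#' configured endpoints, runs \code{\link{optimizeString}}, and (when
#' \code{write = TRUE}) writes the path archive to the configured output
#' directory.
#'
#' @param config a \code{\linkS4class{RunConfig}}.
#' @param write write \code{paths.tsv} into \code{outputDir}.
#' @param verbose per-cycle progress logging.
#' @return a \code{\linkS4class{StringOptimization}}.
#' @export
runFromConfig <- function(config, write = FALSE, verbose = FALSE) {
  surface <- buildSurface(config@surface$name,
                          config@surface$parameters %||% list())
  cvs <- configCVSet(config, "cvs")
  monitors <- configCVSet(config, "monitors")
  s <- config@sampler
  sched <- optimizationSchedule(
    nCycles = config@cycles, descentStep = config@descentStep,
    smoothing = config@smoothing,
    sampler = samplerConfig(temperature = s$temperature,
                            friction = s$friction, timestep = s$timestep,
                            nStepsTotal = s$n_steps, nStepsBurnin = s$burnin,
                            stride = s$stride),
    endpointMode = config@endpointMode)
  init <- initString(config@endpoints$a, config@endpoints$b,
                     R = config@images)
  opt <- optimizeString(init, surface, cvs, k = config@forceConstant,
                        schedule = sched, masterSeed = config@masterSeed,
                        monitors = monitors, verbose = verbose)
  if (write) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    writePathArchive(opt@cyclePaths,
                     file.path(config@outputDir, "paths.tsv"),
                     cvLabels = cvLabels(cvs),
                     masterSeed = config@masterSeed,
                     configHash = configHash(config))
  }
  opt
}
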