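#' Full run configuration
#'
#' Bundles everything a simulation run needs — kinetics, stimulus, wheal
#' readout, solver settings, physical scales, seed and output directory —
#' so that a run can be serialized to YAML and reproduced exactly.
#'
#' @param kinetics a \code{\link{kineticParams}}.
#' @param stimulus a \code{\link{stimulusSpec}}.
#' @param wheal a \code{\link{whealParams}}.
#' @param solver a \code{\link{solverConfig}}.
#' @param scales a \code{\link{scaleSet}}.
#' @param seed run seed (overrides the stimulus seed when given).
#' @param output_dir where artifacts are written.
#' @return An object of class \code{"runConfig"}.
#' @export
runConfig <- function(kinetics = kineticParams(),
                      stimulus = stimulusSpec(r = 0.5, seed = 1L),
                      wheal = whealParams(),
                      solver = solverConfig(),
                      scales = scaleSet(),
                      seed = NULL, output_dir = ".") {
  if (!is.null(seed)) stimulus$seed <- as.integer(seed)
  structure(list(kinetics = kinetics, stimulus = stimulus, wheal = wheal,
                 solver = solver, scales = scales,
                 seed = stimulus$seed, output_dir = output_dir),
            class = "runConfig")
}

#' Write a run configuration to a YAML file
#'
#' The file round-trips losslessly through \code{\link{readRunConfig}};
#' every run writes its resolved configuration next to its outputs.
#'
#' @param cfg a \code{\link{runConfig}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "runConfig"))
  plain <- list(kinetics = unclass(cfg$kinetics),
                stimulus = unclass(cfg$stimulus),
                wheal = unclass(cfg$wheal),
                solver = unclass(cfg$solver),
                scales = unclass(cfg$scales),
                seed = cfg$seed,
                output_dir = cfg$output_dir)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Fields are passed back through the package constructors, so invalid
#' configurations fail with an error naming the offending field.
#'
#' @param path YAML file written by \code{\link{writeRunConfig}} (or by
#'   hand, same structure).
#' @return A \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("kinetics", "stimulus", "wheal", "solver", "scales")
  for (nm in need)
    if (is.null(y[[nm]]))
      stop("readRunConfig: missing required section '", nm, "'")
  solver <- y$solver
  solver$radial_mode <- isTRUE(solver$radial_mode)
  runConfig(kinetics = do.call(kineticParams, y$kinetics),
            stimulus = do.call(stimulusSpec, y$stimulus),
            wheal = do.call(whealParams, y$wheal),
            solver = do.call(solverConfig, solver),
            scales = do.call(scaleSet, y$scales),
            seed = y$seed,
            output_dir = if (is.null(y$output_dir)) "." else y$output_dir)
}
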