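#' Assemble and serialize a run configuration
#'
#' A run configuration bundles everything needed to reproduce an encoding
#' run: the device calibration, the pulse program, the thresholding current
#' and the root seed. It serializes to human-readable JSON; a run is
#' reproducible from its config alone.
#'
#' @param device A [device_params()] object.
#' @param program A [pulse_program()].
#' @param i_st Thresholding current (A).
#' @param seed Root seed (defaults to the program seed).
#' @param path File path for read/write.
#' @param config A `run_config` object.
#' @return A list of class `run_config`; `write_run_config()` returns `path`
#'   invisibly and `read_run_config()` returns the reconstructed object.
#' @export
run_config <- function(device = device_params(),
                       program = pulse_program(),
                       i_st = 5e-10,
                       seed = program$seed) {
  structure(
    list(device = device, program = program, i_st = i_st,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- list(
    version = as.character(utils::packageVersion("spikecoder")),
    device = unclass(config$device),
    program = Filter(Negate(is.null), unclass(config$program)),
    i_st = config$i_st,
    seed = config$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  prog_fields <- p$program[setdiff(names(p$program), "mode")]
  run_config(
    device = do.call(device_params, p$device),
    program = do.call(pulse_program, c(list(mode = p$program$mode),
                                       prog_fields)),
    i_st = p$i_st,
    seed = p$seed
  )
}

#' Stamp output tables with provenance metadata
#'
#' Writes a CSV with leading comment lines recording the package version,
#' the seed and a short config digest, so every output file carries enough
#' context to be reproduced.
#'
#' @param data A data frame.
#' @param path Output path.
#' @param seed Root seed used for the run.
#' @param config_digest Optional short string describing the configuration.
#' @return `path`, invisibly.
#' @export
write_stamped_csv <- function(data, path, seed = NA_integer_,
                              config_digest = "") {
  header <- c(
    sprintf("# spikecoder %s", utils::packageVersion("spikecoder")),
    sprintf("# seed: %s", seed),
    if (nzchar(config_digest)) sprintf("# config: %s", config_digest)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(data, con, row.names = FALSE)
  invisible(path)
}
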