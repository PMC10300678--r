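#' Default run configuration
#'
#' @return Named list of the package-wide defaults: `alpha = 0.77` (the
#'   experimental gravity ratio used throughout), `beta = -0.3` (weak
#'   pusher), unit radius/speed/viscosity, `dt = 0.01`, `eta = 0.05`,
#'   `t_max = 1000`, `n_replicates = 3`, `seed = 1`.
#' @export
default_config <- function() {
  list(alpha = 0.77, beta = -0.3, v0 = 1, R = 1, mu = 1,
       dt = 0.01, eta = 0.05, t_max = 1000, n_replicates = 3, seed = 1)
}

#' Load a run configuration from a YAML file
#'
#' Reads key-value pairs, fills in the defaults of [default_config()], and
#' rejects unknown keys. An empty file yields the full default set.
#'
#' @param path YAML file.
#' @return Named list of parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop("could not parse config file ", path, ": ",
                         conditionMessage(e))
                  })
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config file must contain key-value pairs")
  defaults <- default_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, cfg)
  if (!(out$alpha > 0)) stop("alpha must be positive")
  if (out$dt <= 0) stop("dt must be positive")
  out
}

#' Write records as CSV (with optional JSON mirror)
#'
#' Deterministic column order, full double precision, explicit `NA`
#' serialisation.
#'
#' @param records data frame.
#' @param path output CSV path.
#' @param json also write a JSON mirror next to the CSV.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, json = FALSE) {
  records <- as.data.frame(records)
  readr::write_csv(records, path, na = "NA")
  if (json) {
    jsonlite::write_json(records, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, na = "string")
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the command, full parameter set, seed, package version and
#' timestamp next to a command's outputs, so any run can be reproduced
#' bit-for-bit from its manifest.
#'
#' @param command command name.
#' @param params named list of parameters (must include any seed used).
#' @param outputs character vector of output paths.
#' @param path manifest path (default: first output + `.manifest.json`).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(command, params, outputs,
                           path = paste0(outputs[1], ".manifest.json")) {
  manifest <- list(command = command, parameters = params,
                   outputs = outputs,
                   package_version = as.character(utils::packageVersion("squirmers")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
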