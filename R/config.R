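# Run configuration: a flat YAML or JSON file with circuit and generator
# settings. Unknown keys are rejected so typos never silently fall back to
# defaults.

#' Documented default run configuration
#'
#' @return named list of all configuration keys with their defaults
#' @export
default_config <- function() {
  list(
    n_glomeruli = 400L, n_cortical = 5000L,
    log_affinity_sd = 3, activation_prob = 0.2,
    density = 0.1, scale = 0.5,
    w_inh = 1, beta = 2, v_thr = 2000,
    tau = 1, dt = 0.01, duration = 20,
    n_interneurons = 1L, jitter_sd = 0,
    seed = 1L
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (\code{.yml}/\code{.yaml}) or JSON configuration file,
#' fills in documented defaults for absent keys, and rejects unknown keys
#' by name.
#'
#' @param path configuration file
#' @return a named list of class \code{run_config}
#' @export
#' @examples
#' cfg <- file.path(tempdir(), "cfg.yaml")
#' writeLines("seed: 42", cfg)
#' load_config(cfg)$seed
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("configuration must be .yaml, .yml or .json", call. = FALSE)
  }
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, raw)
  structure(cfg, class = "run_config")
}

#' Write a configuration to file
#'
#' @param config a \code{run_config} or plain named list
#' @param path output file (.yaml/.yml or .json)
#' @return \code{path}, invisibly
#' @export
write_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(config)
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stop("configuration must be .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

#' Build a circuit specification from a configuration
#'
#' Expands the flat configuration into the panel, projection and
#' interneuron objects, deriving independent named seed streams from the
#' single configured seed.
#'
#' @param config a \code{run_config} (see \code{\link{load_config}})
#' @return a \code{circuit_spec}
#' @export
circuit_from_config <- function(config) {
  panel <- sample_glomerular_panel(
    config$n_glomeruli, config$log_affinity_sd, config$activation_prob,
    seed = derive_seed(config$seed, "panel")
  )
  projection <- sample_projection(
    config$n_cortical, config$n_glomeruli, config$density, config$scale,
    seed = derive_seed(config$seed, "projection")
  )
  interneurons <- if (config$n_interneurons > 1L || config$jitter_sd > 0) {
    make_heterogeneous_interneurons(
      c(w_inh = config$w_inh, beta = config$beta, v_thr = config$v_thr),
      config$n_interneurons, config$jitter_sd,
      seed = derive_seed(config$seed, "interneurons")
    )
  } else {
    interneuron_population(config$w_inh, config$beta, config$v_thr)
  }
  circuit_spec(panel, projection, interneurons,
               dt = config$dt, duration = config$duration)
}
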