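# Pipeline configuration: one nested list holding every tunable, with
# documented defaults, YAML (de)serialization, and strict unknown-key
# rejection.

#' Default pipeline configuration
#'
#' Returns the full configuration tree: widefield preprocessing and
#' segmentation parameters, narrowfield parameters, metric thresholds, stain
#' matrix and field-of-view dimensions. Every field can be overridden from a
#' YAML file via \code{\link{loadConfig}}; unknown keys are rejected.
#'
#' @return nested list of class "pipelineConfig".
#' @export
pipelineConfig <- function() {
  structure(list(
    widefield = list(
      fovMm = c(2, 3),
      connectivity = 8,
      preprocess = preprocessParams(),
      inflammation = inflammationParams(),
      veins = veinParams()
    ),
    narrowfield = list(
      fovMm = c(0.8, 1.2),
      params = narrowfieldParams()
    ),
    metrics = list(
      validityThreshold = 0.8,
      recallThreshold = 0.5,
      connectivity = 8,
      bootstrapReps = 1000
    ),
    stains = list(
      matrix = defaultStainMatrix(),
      whiteRef = "auto"
    )
  ), class = "pipelineConfig")
}

# Recursively overlay `user` onto `defaults`, rejecting unknown keys.
.mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      .stopConfig(paste0("unknown configuration key: ", full))
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv)) && is.list(uv)) {
      merged <- .mergeConfig(dv, uv, full)
      attributes(merged) <- attributes(dv)
      defaults[[key]] <- merged
    } else {
      defaults[[key]] <- uv
    }
  }
  defaults
}

# Make the config YAML-representable (matrices -> row lists).
.configToPlain <- function(x) {
  if (is.matrix(x)) {
    return(lapply(seq_len(nrow(x)), function(i) as.numeric(x[i, ])))
  }
  if (is.list(x)) return(lapply(x, .configToPlain))
  x
}

#' Write a configuration to a YAML file
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(.configToPlain(unclass(config)), path, precision = 12)
  invisible(path)
}

#' Load a configuration, overlaying a YAML file onto the defaults
#'
#' Missing fields keep their documented defaults; unknown keys raise a
#' configuration error. The stain matrix may be given as three rows of three
#' optical-density components (H, E, U order); rows are re-normalized.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return a \code{\link{pipelineConfig}}.
#' @export
loadConfig <- function(path = NULL) {
  cfg <- pipelineConfig()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) .stopIO(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  if (!is.null(user$stains$matrix)) {
    rows <- user$stains$matrix
    if (length(rows) != 3L || any(lengths(rows) != 3L))
      .stopConfig("stains.matrix must be three rows of three OD components")
    user$stains$matrix <- stainMatrix(h = as.numeric(rows[[1]]),
                                      e = as.numeric(rows[[2]]),
                                      u = as.numeric(rows[[3]]))
  }
  out <- .mergeConfig(unclass(cfg), user)
  structure(out, class = "pipelineConfig")
}
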