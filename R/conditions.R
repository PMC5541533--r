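# Classed error conditions so callers (and the CLI) can map failures to
# exit codes: configuration (2), I/O (3), validation (4).

.stopClassed <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

.stopConfig <- function(msg) .stopClassed("hesegConfigError", msg)
.stopIO <- function(msg) .stopClassed("hesegIOError", msg)
.stopValidation <- function(msg) .stopClassed("hesegValidationError", msg)
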