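# Classed conditions so the CLI can map failures to exit codes:
# input errors -> 2, stage failures -> 3, degenerate geometry -> 4.

abort_input <- function(msg, ...) {
  stop(structure(list(message = sprintf(msg, ...), call = NULL),
                 class = c("plantrecon_input_error", "plantrecon_error",
                           "error", "condition")))
}

abort_stage <- function(msg, ..., data = NULL) {
  stop(structure(list(message = sprintf(msg, ...), call = NULL, data = data),
                 class = c("plantrecon_stage_error", "plantrecon_error",
                           "error", "condition")))
}

abort_degenerate <- function(msg, ...) {
  stop(structure(list(message = sprintf(msg, ...), call = NULL),
                 class = c("plantrecon_degenerate_error", "plantrecon_error",
                           "error", "condition")))
}
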