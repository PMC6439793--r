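# Structured conditions so callers can distinguish bad arguments from bad
# data files from incompatible sketch parameters.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sketchoverlap_validation_error", "sketchoverlap_error")))
}

stop_invalid_arg <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sketchoverlap_invalid_argument", "sketchoverlap_error")))
}

stop_incompatible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sketchoverlap_incompatible_params", "sketchoverlap_error")))
}

stop_empty_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sketchoverlap_empty_input", "sketchoverlap_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sketchoverlap_config_error", "sketchoverlap_error")))
}
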