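# Structured conditions used across the pipeline. Each maps to a CLI exit
# code: validation_error -> 2, data_error -> 3, fit_error -> 4.

stop_validation <- function(msg, ...) {
  stop(structure(class = c("anap_validation_error", "anap_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("anap_data_error", "anap_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_fit <- function(msg, ...) {
  stop(structure(class = c("anap_fit_error", "anap_error",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

exit_code_for <- function(cond) {
  if (inherits(cond, "anap_validation_error")) return(2L)
  if (inherits(cond, "anap_data_error")) return(3L)
  if (inherits(cond, "anap_fit_error")) return(4L)
  1L
}
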