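# Classed conditions so callers (and the CLI) can distinguish usage errors
# from data errors.

cpo_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cpo_error")))
}

stop_alphabet  <- function(msg) cpo_stop(msg, "cpo_alphabet_error")
stop_frame     <- function(msg) cpo_stop(msg, "cpo_frame_error")
stop_premature <- function(msg) cpo_stop(msg, "cpo_premature_stop_error")
stop_parameter <- function(msg) cpo_stop(msg, "cpo_parameter_error")
stop_parse     <- function(msg) cpo_stop(msg, "cpo_parse_error")
stop_conflict  <- function(msg) cpo_stop(msg, "cpo_conflict_error")
stop_incomplete<- function(msg) cpo_stop(msg, "cpo_incomplete_table_error")
stop_input     <- function(msg) cpo_stop(msg, "cpo_input_error")
stop_size      <- function(msg) cpo_stop(msg, "cpo_size_error")
stop_usage     <- function(msg) cpo_stop(msg, "cpo_usage_error")
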