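# Structured conditions so callers (and the CLI exit-code contract) can
# distinguish usage problems, malformed data, and numerical failure.

ir_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ir_error", "error", "condition")))
}

# class groups used by the CLI:
#   ir_usage_error                          -> exit 2
#   ir_parse_error / ir_shape_error /
#   ir_axis_error / ir_range_error /
#   ir_integrity_error / ir_io_error /
#   ir_unmatched_error / ir_collision_error -> exit 3
#   ir_numeric_error / ir_contract_error    -> exit 4
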