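# Classed conditions so callers can distinguish failure modes
# (invalid_shape_spec, invalid_parameter, empty_foreground, degenerate_input,
#  no_crossing, invalid_mesh, unsupported).

acx_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "alphacomplexity_error"),
                      call = call))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
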