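# Classed error conditions so callers (and tests) can distinguish failure modes
# without parsing messages. All classes are prefixed "metadeg_".

md_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("metadeg_", class), "metadeg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

md_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("metadeg_", class), "metadeg_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
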