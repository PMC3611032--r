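# Classed conditions so callers (and the CLI) can branch on failure kind
# without matching message text. Every ahpdx error carries class
# c("ahpdx_<kind>", "ahpdx_error", "error", "condition").

stop_ahpdx <- function(kind, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("ahpdx_", kind), "ahpdx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
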