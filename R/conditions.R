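# Classed conditions so callers can distinguish degenerate inputs
# (empty documents, short documents, all-one-category ratings) from
# programming errors.

stop_pemread <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pemread_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

warn_pemread <- function(msg, class) {
  warning(structure(
    class = c(class, "pemread_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# package-local cache for the bundled easy-word list / syllable lexicon
.pemread_cache <- new.env(parent = emptyenv())
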