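# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers (and the command wrappers) can distinguish
# configuration mistakes from data problems
stop_config <- function(...) {
  stop(structure(
    class = c("iev_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_data <- function(...) {
  stop(structure(
    class = c("iev_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Shannon entropy (bits) of a nonnegative count or probability table,
# with the 0 * log2(0) = 0 convention. Input need not be normalized.
entropy_from_counts <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop_data("entropy undefined for an empty count table")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}
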